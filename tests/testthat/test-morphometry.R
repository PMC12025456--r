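# Flattening, segmentation, pore detection, porosity, deformability.

make_pore_map <- function(diameter, pixel_size, membrane = 300, n = 64) {
  # binary pit of the given diameter centred in a flat membrane
  xs <- (seq_len(n) - 0.5) * pixel_size
  c0 <- n * pixel_size / 2
  d <- sqrt(outer(xs - c0, xs - c0, function(a, b) a^2 + b^2))
  h <- matrix(membrane, n, n)
  h[d <= diameter / 2] <- 0
  height_map(h, pixel_size = pixel_size, load_force = 170)
}

fake_pore_table <- function(x, y, diameter = 200, nuclear = FALSE, ps = 100) {
  n <- length(x)
  structure(
    data.frame(pore_id = seq_len(n), x_nm = x, y_nm = y,
               diameter_fast_axis_nm = rep_len(diameter, n),
               depth_nm = 150, area_nm2 = pi * (diameter / 2)^2,
               circularity = 1, in_nuclear_region = rep_len(nuclear, n),
               sieve_plate_id = 1L),
    class = c("pore_table", "data.frame"), pixel_size = ps, load_force = 170)
}

test_that("flattening leaves flat maps unchanged and removes per-line tilt without touching pores", {
  sim <- noiseless_sim()
  hm <- reconstruct_height_at_force(sim$fvmap, 170)
  f0 <- flatten_map(hm)
  f0b <- flatten_map(f0)
  # re-flattening changes nothing beyond the poorly constrained lines that
  # cross the nucleus apex (few background pixels there)
  expect_lt(median(abs(f0b$heights - f0$heights)), 0.1)
  expect_lt(max(abs(f0b$heights - f0$heights)), 5)

  tilted <- hm
  tilt <- outer(rep(1, nrow(hm$heights)), seq_len(ncol(hm$heights))) * 0.4 + 25
  tilted$heights <- hm$heights + tilt
  f1 <- flatten_map(tilted)
  expect_lt(median(abs(f1$heights - f0$heights)), 0.1)
  expect_lt(max(abs(f1$heights - f0$heights)), 5)

  seg <- segment_cell(f0)
  p0 <- detect_pores(f0, seg$mask, smooth_sigma = 0)
  p1 <- detect_pores(f1, segment_cell(f1)$mask, smooth_sigma = 0)
  expect_equal(nrow(p1), nrow(p0))
  expect_lt(max(abs(sort(p1$depth_nm) - sort(p0$depth_nm))), 3)
})

test_that("pore detection is robust to imprint-like streaks across scan lines", {
  sim <- noiseless_sim()
  hm <- reconstruct_height_at_force(sim$fvmap, 170)
  p0 <- detect_pores(flatten_map(hm), segment_cell(flatten_map(hm))$mask,
                     smooth_sigma = 0)
  streaked <- hm
  streaked$heights[c(10, 30, 50), ] <- streaked$heights[c(10, 30, 50), ] +
    c(40, -35, 30)
  fs <- flatten_map(streaked)
  ps_tab <- detect_pores(fs, segment_cell(fs)$mask, smooth_sigma = 0)
  expect_equal(nrow(ps_tab), nrow(p0))
})

test_that("cell segmentation returns the projected area with holes filled", {
  sim <- noiseless_sim()
  m <- analyze_phantom_morphometry(sim, targets = 170)
  expect_equal(m$seg$area_um2, sim$truth$cell_area_um2, tolerance = 0.03)
  # a full-frame cell covers the whole scan area
  full <- height_map(matrix(300, 32, 32) + matrix(rnorm(1024, 0, 2), 32),
                     pixel_size = 100, load_force = 170)
  seg <- segment_cell(full, height_threshold = 100)
  expect_equal(seg$area_um2, 32 * 32 * 100^2 / 1e6)
  expect_error(segment_cell(full, height_threshold = 1e5), "empty")
})

test_that("nuclear bulge detection overlaps the true nucleus and is empty for flat cells", {
  sim <- default_sim()
  m <- analyze_phantom_morphometry(sim, targets = 170)
  jac <- sum(m$nuc & sim$truth$nuclear_mask) / sum(m$nuc | sim$truth$nuclear_mask)
  expect_gte(jac, 0.8)
  flat <- height_map(matrix(c(0, 150)[1 + (matrix(seq_len(32^2), 32) %% 2)], 32),
                     pixel_size = 100, load_force = 170)
  expect_true(!any(detect_nuclear_region(flat, bulge_threshold = 400)))
})

test_that("single-pore diameters are measured within one pixel across the fenestration range", {
  for (ps in c(20, 27)) {
    for (d_true in c(60, 100, 150, 200, 250, 300, 350)) {
      hm <- make_pore_map(d_true, ps)
      pores <- detect_pores(hm, matrix(TRUE, 64, 64), smooth_sigma = 0,
                            d_range = c(40, 400))
      expect_equal(nrow(pores), 1L)
      expect_lt(abs(pores$diameter_fast_axis_nm - d_true), ps + 1e-9)
    }
  }
})

test_that("an empty cell yields an empty pore table", {
  flat <- height_map(matrix(300, 32, 32), pixel_size = 25, load_force = 170)
  pores <- detect_pores(flat, matrix(TRUE, 32, 32), depth_threshold = 150,
                        smooth_sigma = 0)
  expect_equal(nrow(pores), 0L)
})

test_that("porosity arithmetic, nuclear exclusion and the exclusion inequality hold", {
  mask10 <- matrix(TRUE, 10, 100)                    # 1000 px @ 100 nm = 10 um^2
  pores <- fake_pore_table(x = seq(500, 5000, length.out = 10),
                           y = rep(500, 10))
  por <- compute_porosity(pores, mask10, NULL, 100)
  expect_equal(por$porosity, 1.0)
  expect_equal(por$cell_area_um2, 10)

  # all pores nuclear: porosity zero, all excluded
  pores_nuc <- fake_pore_table(x = seq(500, 5000, length.out = 10),
                               y = rep(500, 10), nuclear = TRUE)
  por0 <- compute_porosity(pores_nuc, mask10, NULL, 100)
  expect_equal(por0$porosity, 0)
  expect_equal(por0$n_excluded_nuclear, 10L)

  # exclusion can only lower porosity
  sim <- default_sim()
  m <- analyze_phantom_morphometry(sim, targets = 170)
  with_nuc <- compute_porosity(m$pores[[1]], m$seg$mask, m$nuc, 100)$porosity
  without <- compute_porosity(m$pores[[1]], m$seg$mask, NULL, 100)$porosity
  expect_lte(with_nuc, without)
  expect_error(compute_porosity(pores, matrix(FALSE, 4, 4), NULL, 100), "zero cell area")
})

test_that("pores placed only over the nucleus give zero porosity after exclusion", {
  sp <- phantom_spec(grid_nx = 48L, grid_ny = 48L, n_sieve_plates = 0L,
                     pores_per_plate = 0L, nuclear_pores = 3L,
                     nucleus_radius = 1500, seed = 9L)
  sim <- generate_phantom(sp)
  expect_equal(sim$truth$true_porosity, 0)
  expect_true(all(sim$truth$pore_table$in_nuclear_region))
})

test_that("greedy matching is one-to-one, distance-capped and conserves counts", {
  a <- fake_pore_table(x = c(1000, 2000, 3000), y = c(1000, 1000, 1000),
                       diameter = c(100, 150, 200))
  m_same <- match_pores(a, a)
  expect_equal(nrow(m_same$pairs), 3L)
  expect_equal(m_same$pairs$dist_nm, rep(0, 3))
  expect_equal(m_same$pairs$fold_change, rep(1, 3))

  b <- a; b$x_nm <- b$x_nm + 5000                  # shifted beyond the cap
  m_off <- match_pores(a, b, max_centroid_dist = 300)
  expect_equal(nrow(m_off$pairs), 0L)
  expect_equal(sort(m_off$unmatched_low), a$pore_id)

  sim <- default_sim()
  m <- analyze_phantom_morphometry(sim)
  mm <- m$matching
  expect_equal(nrow(mm$pairs) + length(mm$unmatched_low), nrow(m$pores[[1]]))
  expect_equal(nrow(mm$pairs) + length(mm$unmatched_high), nrow(m$pores[[2]]))
})

test_that("deformability summary reports fold changes with the expected symmetries", {
  rigid <- deformability_summary(rep(1, 20))
  expect_equal(rigid$mean_fold, 1)
  expect_equal(rigid$percent_enlargement, 0)
  a <- fake_pore_table(x = c(1000, 2000), y = c(500, 500), diameter = c(100, 200))
  b <- fake_pore_table(x = c(1000, 2000), y = c(500, 500), diameter = c(120, 260))
  fwd <- match_pores(a, b)$pairs$fold_change
  rev <- match_pores(b, a)$pairs$fold_change
  expect_equal(sort(fwd * rev), c(1, 1))
  expect_error(deformability_summary(numeric(0)), "no matched")
})

test_that("most non-edge pores are matched between the 170 and 300 pN reconstructions", {
  sim <- generate_phantom(deformability_spec(seed = 2L))
  m <- analyze_phantom_morphometry(sim)
  n_low <- nrow(m$pores[[1]])
  expect_gte(nrow(m$matching$pairs), ceiling(0.8 * n_low))
})
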