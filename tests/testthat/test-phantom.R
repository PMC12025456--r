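# Synthetic-data generators: determinism, validity, and analytic truth.

test_that("phantom generation is deterministic and validates its spec", {
  sp <- phantom_spec(grid_nx = 24L, grid_ny = 24L, nucleus_height = 0,
                     nucleus_radius = 0, n_sieve_plates = 2L,
                     pores_per_plate = 2L, seed = 7L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$fvmap$force, b$fvmap$force)
  expect_identical(a$truth$pore_table, b$truth$pore_table)
  expect_error(phantom_spec(pore_diameter_max = 40, pore_diameter_min = 50),
               "pore_diameter_max")
  expect_error(phantom_spec(poisson_ratio = 0.7), "poisson_ratio")
  expect_error(phantom_spec(z_range = 500), "z_range")
  expect_error(phantom_spec(substrate_modulus = 0), "substrate_modulus")
})

test_that("a pore-free spec yields zero porosity and a flat spec yields identical curves", {
  sp0 <- phantom_spec(grid_nx = 16L, grid_ny = 16L, pores_per_plate = 0L)
  expect_equal(generate_phantom(sp0)$truth$true_porosity, 0)

  flat <- phantom_spec(grid_nx = 12L, grid_ny = 12L, cell_height = 0,
                       nucleus_height = 0, nucleus_radius = 0,
                       substrate_modulus = 5000, cell_modulus = 5000,
                       n_sieve_plates = 0L, pores_per_plate = 0L,
                       force_noise_sd = 0, z_range = 1500)
  sim <- generate_phantom(flat)
  ref <- sim$fvmap$force[1, 1, ]
  for (r in c(3, 7, 12)) for (cc in c(2, 6, 11)) {
    expect_equal(sim$fvmap$force[r, cc, ], ref)
  }
  hm <- reconstruct_height_at_force(sim$fvmap, 200)
  expect_lt(diff(range(hm$heights)), 1e-6)
})

test_that("simulated forces are zero (plus noise) before contact and non-negative after", {
  sim <- noiseless_sim()
  z <- sim$fvmap$z
  for (i in seq(1, 64, by = 21)) for (j in seq(2, 64, by = 17)) {
    f <- sim$fvmap$force[i, j, ]
    z_c <- sim$fvmap$contact_z[i, j]
    expect_true(all(f[z < z_c] == 0))
    expect_true(all(f >= 0))
    expect_true(all(diff(f[z >= z_c]) >= -1e-9))
  }
  # with noise, the pre-contact mean stays near zero
  simn <- default_sim()
  f <- simn$fvmap$force[5, 5, ]
  pre <- f[z < simn$fvmap$contact_z[5, 5] - 50]
  expect_lt(abs(mean(pre)), 4 * 20 / sqrt(length(pre)))
})

test_that("true enlargement increases strictly with rim compliance and is load-monotone", {
  folds <- vapply(c(0.5, 1, 1.5, 2), function(rc) {
    sp <- phantom_spec(grid_nx = 32L, grid_ny = 32L, rim_compliance = rc,
                       nucleus_height = 0, nucleus_radius = 0,
                       pore_diameter_mean = 150, pore_diameter_sd = 20,
                       n_sieve_plates = 2L, pores_per_plate = 2L, seed = 3L)
    generate_phantom(sp)$truth$true_enlargement
  }, numeric(1))
  expect_true(all(diff(folds) > 0))
  # per-load diameter function is non-decreasing in load
  sim <- noiseless_sim()
  d1 <- true_pore_diameter(sim$truth, 100)
  d2 <- true_pore_diameter(sim$truth, 200)
  d3 <- true_pore_diameter(sim$truth, 340)
  expect_true(all(d2 >= d1) && all(d3 >= d2))
  # rigid pores (zero compliance) do not grow
  sp0 <- phantom_spec(grid_nx = 32L, grid_ny = 32L, rim_compliance = 0,
                      nucleus_height = 0, nucleus_radius = 0,
                      pore_diameter_mean = 150, pore_diameter_sd = 20,
                      n_sieve_plates = 2L, pores_per_plate = 2L, seed = 3L)
  t0 <- generate_phantom(sp0)$truth
  expect_equal(t0$true_enlargement, 1)
})

test_that("ground-truth bookkeeping is conserved and matches noiseless detection", {
  sim <- noiseless_sim()
  truth <- sim$truth
  attempts <- truth$spec$n_sieve_plates * truth$spec$pores_per_plate
  expect_equal(nrow(truth$pore_table) + truth$n_rejected, attempts)
  expect_equal(truth$true_porosity,
               sum(!truth$pore_table$in_nuclear_region) / truth$cell_area_um2)
  # detection on the noiseless phantom recovers every resolvable pore
  # (patent core spans at least one pixel) and invents none
  m <- analyze_phantom_morphometry(sim, targets = 170)
  det <- m$pores[[1]]
  dmat <- sqrt(outer(det$x_nm, truth$pore_table$x_nm, "-")^2 +
                 outer(det$y_nm, truth$pore_table$y_nm, "-")^2)
  nearest_truth <- apply(dmat, 1, min)
  expect_true(all(nearest_truth < 2 * truth$spec$pixel_size))  # no spurious pores
  resolvable <- which(!truth$pore_table$in_nuclear_region &
                        2 * truth$pore_table$r0_nm >= truth$spec$pixel_size)
  hit <- apply(dmat[, resolvable, drop = FALSE], 2, min) < 2 * truth$spec$pixel_size
  expect_true(all(hit))                                        # no missed resolvable pore
})

test_that("diameters honour the truncation range and drawn reference diameters", {
  sim <- default_sim()
  pt <- sim$truth$pore_table
  expect_true(all(pt$diameter_ref_nm >= 50 & pt$diameter_ref_nm <= 350))
  # the reference force is 170 pN, so the 170 pN truth equals the draw
  expect_equal(pt$diameter_170_nm, pt$diameter_ref_nm, tolerance = 1e-10)
})

test_that("amplitude-sweep generator encodes plateau, loss factor and yield by construction", {
  sw <- generate_amplitude_sweep(390, loss_factor = 0.08, yield_strain = 1,
                                 decay_exponent = 1, noise_rel = 0)
  expect_equal(sw$g_double_prime / sw$g_prime, rep(0.08, length(sw$strain)))
  expect_equal(max(sw$g_prime), 390)
  lv <- find_lver(sw)
  expect_equal(mean_storage_modulus(sw, lv)$mean, 390)
  expect_error(generate_amplitude_sweep(390, strain_grid = numeric(0)), "strain_grid")
  # recovered plateau over 100 noisy seeds stays within 2 %
  g <- vapply(1:100, function(s) {
    swn <- generate_amplitude_sweep(390, loss_factor = 0.08, yield_strain = 1,
                                    decay_exponent = 1, noise_rel = 0.05, seed = s)
    mean_storage_modulus(swn, find_lver(swn))$mean
  }, numeric(1))
  expect_equal(mean(g), 390, tolerance = 0.02)
})

test_that("nuclei-image generator places the requested nuclei reproducibly or fails loudly", {
  blank <- generate_nuclei_image(0, image_size = 64L, seed = 1L)
  expect_equal(blank$true_count, 0L)
  expect_true(all(abs(blank$image - 20) < 30))
  a <- generate_nuclei_image(12, image_size = 128L, seed = 5L)
  b <- generate_nuclei_image(12, image_size = 128L, seed = 5L)
  expect_identical(a$image, b$image)
  expect_equal(a$true_count, 12L)
  # pairwise non-overlap
  dmat <- as.matrix(dist(a$centers))
  expect_true(all(dmat[upper.tri(dmat)] > 2 * 6))
  expect_error(generate_nuclei_image(500, image_size = 48L, nucleus_radius_px = 6),
               "reduce")
})

test_that("endocytosis tables have the replicate layout and exact noiseless arithmetic", {
  tab <- generate_endocytosis_table(6L, cells_per_well = 5,
                                    cell_associated_mean = 2, degraded_mean = 3)
  expect_equal(nrow(tab), 6L)   # 3 bioreplicates x 2 technical replicates
  norm <- normalize_endocytosis(tab)
  expect_equal(norm$wells$normalized_total, rep(1, 6))
  tab0 <- generate_endocytosis_table(4L, cells_per_well = 10,
                                     cell_associated_mean = 7, degraded_mean = 0)
  expect_equal(normalize_endocytosis(tab0)$wells$total, rep(7, 4))
  expect_error(generate_endocytosis_table(4L, cells_per_well = 0,
                                          cell_associated_mean = 1,
                                          degraded_mean = 1), "cells_per_well")
})
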