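# Contact models, contact-point estimation and apparent-modulus fitting.

test_that("contact models obey their closed forms and scaling laws", {
  # zero indentation gives zero force; doubling E doubles force
  expect_equal(hertz_force_sphere(0, 800, 0.5, 20), 0)
  expect_equal(sneddon_force_pyramid(0, 5000, 0.5, 20), 0)
  d <- c(10, 50, 200, 600)
  expect_equal(hertz_force_sphere(d, 1600, 0.5, 20),
               2 * hertz_force_sphere(d, 800, 0.5, 20))
  expect_equal(sneddon_force_pyramid(2 * d, 5000, 0.5, 20),
               4 * sneddon_force_pyramid(d, 5000, 0.5, 20))
  expect_error(hertz_force_sphere(-1, 800, 0.5, 20), "non-negative")
  expect_error(sneddon_force_pyramid(10, 5000, 0.5, 95), "half_angle")

  # power-law exponents recovered by log-log regression on noiseless curves
  dd <- 10^seq(0.5, 3, length.out = 50)
  slope <- function(f) unname(coef(lm(log(f) ~ log(dd)))[2])
  expect_equal(slope(hertz_force_sphere(dd, 800, 0.5, 20)), 1.5, tolerance = 0.01 / 1.5)
  expect_equal(slope(sneddon_force_pyramid(dd, 5000, 0.5, 20)), 2.0, tolerance = 0.01 / 2)
})

test_that("indentation inversion reproduces the soft-gel worked example and is an exact inverse", {
  # 100 pN on a 0.8 kPa gel with a 20 nm tip indents by ~0.6 um
  d <- invert_indentation(100, 800, 0.5, 20)
  expect_equal(d / 1000, 0.6, tolerance = 0.05 / 0.6)  # ~0.63 um
  expect_equal(round(d / 1000, 1), 0.6)
  expect_equal(invert_indentation(0, 800, 0.5, 20), 0)
  # inverse identity over a grid of indentations
  dd <- seq(1, 1500, length.out = 40)
  expect_equal(invert_indentation(hertz_force_sphere(dd, 2500, 0.5, 25), 2500, 0.5, 25),
               dd, tolerance = 1e-10)
  expect_error(invert_indentation(100, -5, 0.5, 20), "E")
})

test_that("baseline correction removes linear drift and leaves clean curves unchanged", {
  z <- seq(0, 1000, length.out = 128)
  f0 <- ifelse(z > 600, 0.05 * (z - 600)^1.5, 0)
  cv0 <- force_curve(z, f0, 0.1)
  expect_equal(correct_baseline(cv0)$force, f0, tolerance = 1e-10)
  drift <- 3 + 0.02 * z
  cvd <- force_curve(z, f0 + drift, 0.1)
  expect_equal(correct_baseline(cvd)$force, f0, tolerance = 1e-8)
  expect_error(force_curve(z[1:10], f0[1:10], 0.1), "16 samples")
})

test_that("modulus fitting on a drifted phantom-like curve recovers E after baseline correction", {
  model <- indenter_model("sphere", tip_radius = 25)
  cv <- make_hertz_curve(5000, model)
  cv$force <- cv$force + 8 - 0.01 * cv$z          # inject offset + drift
  fit <- fit_apparent_modulus(correct_baseline(cv, 0.2), model,
                              fit_window = c(50, 1200))
  expect_equal(fit$E_app, 5000, tolerance = 0.03)
})

test_that("contact-point estimators locate the contact of noiseless curves", {
  model <- indenter_model("sphere", tip_radius = 25)
  cv <- make_hertz_curve(5000, model, z_c = 500)
  dz <- cv$z[2] - cv$z[1]
  z_rs <- estimate_contact_point(cv, "residual_search", model = model)
  expect_lt(abs(z_rs - 500), dz + 1e-9)
  z_thr <- estimate_contact_point(cv, "threshold", model = model)
  expect_lt(abs(z_thr - 500), 2 * dz)
  # all-zero force has no contact
  flat <- force_curve(cv$z, rep(0, length(cv$z)), 0.1)
  expect_error(estimate_contact_point(flat, "threshold"), "no contact")
})

test_that("indentation respects the rigid-surface and free-cantilever limits", {
  z <- seq(0, 1000, length.out = 64)
  k <- 0.1                                    # 100 pN/nm
  z_c <- 400
  rigid <- force_curve(z, pmax(z - z_c, 0) * 100, k)
  expect_equal(compute_indentation(rigid, z_c), rep(0, 64), tolerance = 1e-12)
  free <- force_curve(z, rep(0, 64), k)
  expect_equal(compute_indentation(free, z_c), pmax(z - z_c, 0))
  expect_error(compute_indentation(rigid, 5000), "z_c")
})

test_that("noiseless round-trip fits recover the generating modulus for both indenters", {
  for (case in list(list(model = indenter_model("sphere", tip_radius = 25), E = 5000),
                    list(model = indenter_model("sphere", tip_radius = 5000), E = 800),
                    list(model = indenter_model("pyramid", half_angle = 20), E = 52000),
                    list(model = indenter_model("pyramid", half_angle = 35), E = 800))) {
    cv <- make_hertz_curve(case$E, case$model, z_c = 500)
    dz <- cv$z[2] - cv$z[1]
    fit <- fit_apparent_modulus(cv, case$model, fit_window = c(10, 1400))
    expect_equal(fit$E_app, case$E, tolerance = 0.005)
    expect_lt(abs(fit$contact_point - 500), dz + 1e-9)
  }
})

test_that("consistent force/spring rescaling leaves indentation unchanged and scales the fit linearly", {
  model <- indenter_model("sphere", tip_radius = 25)
  cv <- make_hertz_curve(5000, model, k = 0.1)
  d1 <- compute_indentation(cv, 500)
  # doubling force and spring constant together: same deflection, same
  # indentation, and a modulus exactly twice as large (linearity in force)
  cv2 <- force_curve(cv$z, cv$force * 2, cv$spring_constant * 2)
  expect_equal(compute_indentation(cv2, 500), d1)
  f1 <- fit_apparent_modulus(cv, model, fit_window = c(10, 1200), z_c = 500,
                             refine_contact = FALSE)
  f2 <- fit_apparent_modulus(cv2, model, fit_window = c(10, 1200), z_c = 500,
                             refine_contact = FALSE)
  expect_equal(f2$E_app, 2 * f1$E_app, tolerance = 1e-9)
})

test_that("phantom curves reproduce the closed-form soft-substrate indentation at 100 pN", {
  # flat 800 Pa substrate probed with a 20 nm tip, no noise: the indentation
  # at 100 pN must match a numerical root-find on the forward model
  sp <- phantom_spec(grid_nx = 8L, grid_ny = 8L, curve_n_samples = 512L,
                     substrate_modulus = 800, cell_modulus = 800,
                     cell_height = 0, nucleus_height = 0, nucleus_radius = 0,
                     n_sieve_plates = 0L, pores_per_plate = 0L,
                     tip_radius = 20, force_noise_sd = 0, z_range = 2000)
  sim <- generate_phantom(sp)
  cv <- fv_curve(sim$fvmap, 4, 4)
  z_c <- sim$fvmap$contact_z[4, 4]
  delta <- compute_indentation(cv, z_c)
  i <- which(cv$force >= 100)[1]
  t <- (100 - cv$force[i - 1]) / (cv$force[i] - cv$force[i - 1])
  delta_100 <- delta[i - 1] + t * (delta[i] - delta[i - 1])
  # independent oracle: root-find the forward model at 100 pN
  oracle <- uniroot(function(d) hertz_force_sphere(d, 800, 0.5, 20) - 100,
                    c(1, 1500), tol = 1e-9)$root
  expect_equal(delta_100, oracle, tolerance = 2 / oracle)
  expect_equal(oracle, invert_indentation(100, 800, 0.5, 20), tolerance = 1e-6)
})

test_that("per-map modulus fitting returns a complete fit table", {
  sim <- noiseless_sim()
  tab <- fit_force_volume(sim$fvmap, indenter_model("sphere", tip_radius = 25),
                          fit_window = c(50, 900), stride = 16L)
  expect_true(all(c("px_x", "px_y", "E_app_Pa", "z_c_nm", "residual_rms_pN") %in% names(tab)))
  truthE <- sim$truth$modulus_map[cbind(tab$px_y, tab$px_x)]
  expect_lt(median(abs(tab$E_app_Pa / truthE - 1), na.rm = TRUE), 0.01)
})
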