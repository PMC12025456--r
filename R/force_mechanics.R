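# Contact mechanics: force curves, contact-point estimation and
# Hertz-Sneddon apparent-modulus fitting.
#
# Internal unit convention: z and indentation in nm, force in pN, moduli in
# Pa, spring constant stored in N/m (1 N/m == 1000 pN/nm). The mixed-unit
# Hertz prefactors therefore carry a factor 1e-6:
#   F[pN] = (4/3) E/(1-nu^2) sqrt(R[nm]) delta[nm]^(3/2) * 1e-6     (sphere)
#   F[pN] = 0.7453 E/(1-nu^2) tan(theta) delta[nm]^2      * 1e-6     (pyramid)

#' Construct a force-distance curve
#'
#' A single AFM approach (or retract) curve: piezo extension `z` increasing
#' toward the sample and the measured cantilever force.
#'
#' @param z Numeric vector, piezo extension in nm, strictly monotonic.
#' @param force Numeric vector of forces in pN, same length as `z`.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param direction `"approach"` or `"retract"`.
#' @param temperature Optional acquisition temperature in degrees Celsius
#'   (metadata only).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, force, spring_constant,
                        direction = c("approach", "retract"),
                        temperature = NA_real_) {
  direction <- match.arg(direction)
  if (!is.numeric(z) || !is.numeric(force) || length(z) != length(force)) {
    stop_field("z/force", "must be numeric vectors of equal length")
  }
  if (length(z) < 16L) stop_field("z", "curve must contain at least 16 samples")
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0))) stop_field("z", "must be strictly monotonic")
  check_num(spring_constant, "spring_constant", lower = 0, strict_lower = TRUE)
  structure(
    list(z = as.numeric(z), force = as.numeric(force),
         spring_constant = spring_constant, direction = direction,
         temperature = temperature),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, z %.0f..%.0f nm, k = %.3g N/m (%s)\n",
              length(x$z), min(x$z), max(x$z), x$spring_constant, x$direction))
  invisible(x)
}

#' Describe the indenter geometry used for contact-model fitting
#'
#' @param kind `"sphere"` (parabolic Hertz contact, requires `tip_radius`) or
#'   `"pyramid"` (four-sided pyramidal Sneddon-type contact, requires
#'   `half_angle`).
#' @param tip_radius Sphere tip radius in nm.
#' @param half_angle Pyramid face half-opening angle in degrees.
#' @param poisson_ratio Sample Poisson ratio, in `[0, 0.5]`; 0.5 (an
#'   incompressible sample) is the conventional choice for cells and
#'   hydrated hydrogels.
#' @return An object of class `indenter_model`.
#' @export
indenter_model <- function(kind = c("sphere", "pyramid"), tip_radius = NULL,
                           half_angle = NULL, poisson_ratio = 0.5) {
  kind <- match.arg(kind)
  check_num(poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5)
  if (kind == "sphere") {
    if (is.null(tip_radius)) stop_field("tip_radius", "required for a spherical tip")
    check_num(tip_radius, "tip_radius", lower = 0, strict_lower = TRUE)
    if (!is.null(half_angle)) stop_field("half_angle", "not a field of a spherical tip")
  } else {
    if (is.null(half_angle)) stop_field("half_angle", "required for a pyramidal tip")
    check_num(half_angle, "half_angle", lower = 0, upper = 90,
              strict_lower = TRUE, strict_upper = TRUE)
    if (!is.null(tip_radius)) stop_field("tip_radius", "not a field of a pyramidal tip")
  }
  structure(list(kind = kind, tip_radius = tip_radius, half_angle = half_angle,
                 poisson_ratio = poisson_ratio),
            class = "indenter_model")
}

# Prefactor C and exponent m such that F[pN] = C * E[Pa] * delta[nm]^m.
# The four-sided pyramid constant 0.7453 is recorded in fit results.
.pyramid_prefactor_constant <- 0.7453

.contact_coef <- function(model) {
  nu2 <- 1 - model$poisson_ratio^2
  if (model$kind == "sphere") {
    list(C = (4 / 3) * sqrt(model$tip_radius) * 1e-6 / nu2, m = 1.5)
  } else {
    theta <- model$half_angle * pi / 180
    list(C = .pyramid_prefactor_constant * tan(theta) * 1e-6 / nu2, m = 2)
  }
}

#' Hertz force for a spherical indenter
#'
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)`, the parabolic
#' approximation of sphere-on-halfspace contact.
#'
#' @param delta Indentation depth(s) in nm, non-negative.
#' @param E Young's modulus in Pa.
#' @param nu Poisson ratio.
#' @param R Tip radius in nm.
#' @return Force(s) in pN.
#' @export
hertz_force_sphere <- function(delta, E, nu = 0.5, R) {
  if (any(delta < 0)) stop_field("delta", "indentation must be non-negative")
  check_num(E, "E", lower = 0, strict_lower = TRUE)
  check_num(R, "R", lower = 0, strict_lower = TRUE)
  check_num(nu, "nu", lower = 0, upper = 0.5)
  cf <- .contact_coef(indenter_model("sphere", tip_radius = R, poisson_ratio = nu))
  cf$C * E * delta^cf$m
}

#' Sneddon-type force for a four-sided pyramidal indenter
#'
#' `F = 0.7453 (E / (1 - nu^2)) tan(theta) delta^2`, with the four-sided
#' pyramid geometric constant.
#'
#' @inheritParams hertz_force_sphere
#' @param half_angle Face half-opening angle in degrees, in (0, 90).
#' @return Force(s) in pN.
#' @export
sneddon_force_pyramid <- function(delta, E, nu = 0.5, half_angle) {
  if (any(delta < 0)) stop_field("delta", "indentation must be non-negative")
  check_num(E, "E", lower = 0, strict_lower = TRUE)
  cf <- .contact_coef(indenter_model("pyramid", half_angle = half_angle,
                                     poisson_ratio = nu))
  cf$C * E * delta^cf$m
}

#' Closed-form indentation for a spherical indenter at a given load
#'
#' Inverts the sphere contact model:
#' `delta = (3 F (1 - nu^2) / (4 E sqrt(R)))^(2/3)`. For example, a 100 pN
#' load on a 0.8 kPa substrate probed with a 20 nm tip (nu = 0.5) indents by
#' about 0.63 micrometres, which is why nanometre-resolution imaging of very
#' soft gels at such loads reflects a strongly deformed surface.
#'
#' @param F Load force(s) in pN, non-negative.
#' @param E Young's modulus in Pa.
#' @param nu Poisson ratio.
#' @param R Tip radius in nm.
#' @return Indentation(s) in nm.
#' @export
invert_indentation <- function(F, E, nu = 0.5, R) {
  if (any(F < 0)) stop_field("F", "load must be non-negative")
  check_num(E, "E", lower = 0, strict_lower = TRUE)
  check_num(R, "R", lower = 0, strict_lower = TRUE)
  check_num(nu, "nu", lower = 0, upper = 0.5)
  cf <- .contact_coef(indenter_model("sphere", tip_radius = R, poisson_ratio = nu))
  (F / (cf$C * E))^(1 / cf$m)
}

#' Subtract a linear baseline from the non-contact region of a curve
#'
#' Fits a straight line to the leading `baseline_fraction` of the approach
#' (assumed free of contact) and subtracts it from the whole curve, removing
#' offset and linear drift.
#'
#' @param curve A [force_curve()].
#' @param baseline_fraction Fraction of leading samples treated as
#'   non-contact, in (0, 0.9).
#' @return The corrected `force_curve`.
#' @export
correct_baseline <- function(curve, baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  check_num(baseline_fraction, "baseline_fraction", lower = 0, upper = 0.9,
            strict_lower = TRUE, strict_upper = TRUE)
  n <- length(curve$z)
  nb <- max(4L, floor(baseline_fraction * n))
  fit <- stats::lm.fit(cbind(1, curve$z[seq_len(nb)]),
                       curve$force[seq_len(nb)])
  curve$force <- curve$force - (fit$coefficients[1] + fit$coefficients[2] * curve$z)
  curve
}

#' Estimate the tip-sample contact point of an approach curve
#'
#' Two estimators are provided. `"threshold"` finds the first crossing of
#' `n_sigma` times the baseline noise that persists for `m_consecutive`
#' samples, then refines the estimate by back-extrapolating the linearized
#' contact regime (`F^(2/3)` for a sphere, `F^(1/2)` for a pyramid) to zero
#' force, which removes the systematic late bias of a raw threshold crossing.
#' `"residual_search"` performs a brute-force grid search over candidate
#' contact points, refitting the contact model at each and minimizing the
#' force residual; it is slower but makes no local approximation and serves
#' as the reference estimator.
#'
#' @param curve A baseline-corrected approach [force_curve()].
#' @param method `"threshold"` or `"residual_search"`.
#' @param n_sigma Threshold in multiples of the baseline noise SD.
#' @param m_consecutive Number of consecutive samples that must stay above
#'   threshold for a crossing to count.
#' @param model An [indenter_model()]; required for `"residual_search"` and
#'   used by `"threshold"` only to pick the linearization exponent (defaults
#'   to the sphere exponent when omitted).
#' @param baseline_fraction Leading fraction of the curve used to measure the
#'   baseline noise SD.
#' @return Estimated contact point `z_c` in nm.
#' @export
estimate_contact_point <- function(curve,
                                   method = c("threshold", "residual_search"),
                                   n_sigma = 3, m_consecutive = 5,
                                   model = NULL, baseline_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  method <- match.arg(method)
  if (method == "threshold") {
    .contact_point_threshold(curve, n_sigma, m_consecutive, model,
                             baseline_fraction)
  } else {
    if (is.null(model)) stop_field("model", "required for residual_search")
    .contact_point_residual_search(curve, model)
  }
}

.contact_point_threshold <- function(curve, n_sigma, m_consecutive, model,
                                     baseline_fraction) {
  z <- curve$z
  f <- curve$force
  n <- length(z)
  nb <- max(8L, floor(baseline_fraction * n))
  sigma <- stats::sd(f[seq_len(nb)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- max(abs(f)) * 1e-9 + 1e-12
  thr <- n_sigma * sigma
  above <- f > thr
  runlen <- stats::filter(as.numeric(above), rep(1, m_consecutive), sides = 1)
  hit <- which(runlen == m_consecutive)
  if (length(hit) == 0L) stop("no contact: force never exceeds threshold", call. = FALSE)
  start <- hit[1] - m_consecutive + 1L
  z_raw <- z[start]
  # refine: extrapolate the linearized contact regime back to zero force
  m <- if (is.null(model)) 1.5 else .contact_coef(model)$m
  upper <- max(25 * sigma, f[min(start + 5L, n)])
  sel <- seq.int(start, min(n, start + 59L))
  sel <- sel[f[sel] > 0 & f[sel] <= upper]
  if (length(sel) >= 4L) {
    y <- f[sel]^(1 / m)
    fit <- stats::lm.fit(cbind(1, z[sel]), y)
    b <- fit$coefficients
    if (is.finite(b[2]) && b[2] > 0) {
      z_c <- -b[1] / b[2]
      if (z_c > min(z) && z_c <= z_raw + (z[2] - z[1])) return(unname(z_c))
    }
  }
  z_raw
}

# Closed-form least-squares modulus for a fixed candidate contact point.
# Returns E (Pa) and the residual RMS (pN) over the selected samples.
.ls_modulus <- function(z, f, z_c, k_pn, cf, fit_window) {
  delta <- (z - z_c) - f / k_pn
  delta[z < z_c] <- 0
  delta <- pmax(delta, 0)
  sel <- which(delta > fit_window[1] & delta <= fit_window[2] & z >= z_c)
  if (length(sel) < 8L) return(NULL)
  phi <- cf$C * delta[sel]^cf$m
  ss <- sum(phi^2)
  if (ss <= 0) return(NULL)
  E <- sum(f[sel] * phi) / ss
  if (!is.finite(E) || E <= 0) return(NULL)
  res <- f[sel] - E * phi
  list(E = E, rms = sqrt(mean(res^2)), n = length(sel),
       delta_max = max(delta[sel]))
}

.contact_point_residual_search <- function(curve, model, fit_window = c(0, Inf),
                                           candidates = NULL) {
  z <- curve$z
  f <- curve$force
  k_pn <- k_pn_per_nm(curve$spring_constant)
  cf <- .contact_coef(model)
  if (is.null(candidates)) {
    candidates <- z[seq_len(length(z) - 8L)]
  }
  best <- NULL
  best_z <- NA_real_
  for (zc in candidates) {
    ls <- .ls_modulus(z, f, zc, k_pn, cf, fit_window)
    if (is.null(ls)) next
    if (is.null(best) || ls$rms < best$rms) {
      best <- ls
      best_z <- zc
    }
  }
  if (is.null(best)) stop("no contact: residual search found no admissible contact point",
                          call. = FALSE)
  best_z
}

#' Compute indentation from a curve and a contact point
#'
#' The sample indentation is the piezo travel past contact minus the
#' cantilever deflection: `delta = (z - z_c) - F / k`, clipped at zero.
#'
#' @param curve A [force_curve()].
#' @param z_c Contact point in nm, inside the curve's z range.
#' @return Indentation vector in nm (zero before contact).
#' @export
compute_indentation <- function(curve, z_c) {
  stopifnot(inherits(curve, "force_curve"))
  if (curve$spring_constant <= 0) stop_field("spring_constant", "must be > 0")
  if (z_c < min(curve$z) || z_c > max(curve$z)) {
    stop_field("z_c", "must lie inside the curve z range")
  }
  k_pn <- k_pn_per_nm(curve$spring_constant)
  delta <- (curve$z - z_c) - curve$force / k_pn
  delta[curve$z < z_c] <- 0
  pmax(delta, 0)
}

#' Fit the apparent Young's modulus of a force curve
#'
#' Least-squares fit of the selected contact model to a baseline-corrected
#' approach curve over an indentation window. The modulus enters the model
#' linearly, so for a fixed contact point the fit is closed-form; the contact
#' point itself is estimated by the threshold detector and, by default,
#' refined by a local residual-minimizing search (a small grid around the
#' initial estimate), which removes the residual contact-point bias that
#' would otherwise inflate the modulus.
#'
#' @param curve A baseline-corrected approach [force_curve()].
#' @param model An [indenter_model()].
#' @param fit_window Indentation window `c(min, max)` in nm over which
#'   samples enter the fit.
#' @param z_c Optional fixed contact point in nm; when `NULL` it is
#'   estimated from the curve.
#' @param refine_contact Refine the contact point by local residual search
#'   (default `TRUE`).
#' @param n_sigma,m_consecutive Passed to the threshold contact detector.
#' @return An object of class `hertz_fit` with fields `E_app` (Pa),
#'   `contact_point` (nm), `indentation_max` (nm), `residual_rms` (pN),
#'   `n_points`, `model`, and `fit_window`.
#' @export
fit_apparent_modulus <- function(curve, model, fit_window = c(0, Inf),
                                 z_c = NULL, refine_contact = TRUE,
                                 n_sigma = 3, m_consecutive = 5) {
  stopifnot(inherits(curve, "force_curve"), inherits(model, "indenter_model"))
  if (!is.numeric(fit_window) || length(fit_window) != 2L ||
      fit_window[1] < 0 || fit_window[2] <= fit_window[1]) {
    stop_field("fit_window", "must be an increasing non-negative range c(min, max)")
  }
  z <- curve$z
  dz <- abs(z[2] - z[1])
  if (is.null(z_c)) {
    z_c <- .contact_point_threshold(curve, n_sigma, m_consecutive, model, 0.3)
  }
  if (refine_contact) {
    cand <- seq(z_c - 12 * dz, z_c + 12 * dz, by = dz / 4)
    cand <- cand[cand > min(z) & cand < max(z)]
    z_c <- tryCatch(
      .contact_point_residual_search(curve, model, fit_window, candidates = cand),
      error = function(e) z_c
    )
  }
  k_pn <- k_pn_per_nm(curve$spring_constant)
  cf <- .contact_coef(model)
  ls <- .ls_modulus(z, curve$force, z_c, k_pn, cf, fit_window)
  if (is.null(ls)) {
    nin <- sum((z - z_c) > fit_window[1] & (z - z_c) <= fit_window[2])
    stop(sprintf(paste0("modulus fit failed: fewer than 8 usable samples or ",
                        "non-positive modulus (z_c = %.1f nm, %d samples in window)"),
                 z_c, nin), call. = FALSE)
  }
  structure(
    list(E_app = ls$E, contact_point = z_c, indentation_max = ls$delta_max,
         residual_rms = ls$rms, n_points = ls$n, model = model,
         fit_window = fit_window,
         pyramid_prefactor = if (model$kind == "pyramid") .pyramid_prefactor_constant else NA_real_),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E_app = %.3g Pa (%s), z_c = %.1f nm, delta_max = %.0f nm, rms = %.2g pN (n = %d)\n",
              x$E_app, x$model$kind, x$contact_point, x$indentation_max,
              x$residual_rms, x$n_points))
  invisible(x)
}

#' Extract one pixel of a force-volume map as a force curve
#'
#' @param fvmap A `force_volume` object (see [generate_phantom()]).
#' @param row,col Pixel indices (row = slow axis, col = fast axis).
#' @return A [force_curve()].
#' @export
fv_curve <- function(fvmap, row, col) {
  stopifnot(inherits(fvmap, "force_volume"))
  force_curve(fvmap$z, fvmap$force[row, col, ], fvmap$spring_constant)
}

#' Fit apparent moduli across a force-volume map
#'
#' Fits every `stride`-th pixel of the map and returns a per-curve table.
#'
#' @param fvmap A `force_volume` object.
#' @param model An [indenter_model()].
#' @param fit_window Indentation window in nm.
#' @param stride Pixel stride (1 fits every pixel).
#' @param baseline_fraction Leading fraction used for baseline correction, or
#'   `NULL` to skip correction when curves are already baseline-flat.
#' @param ... Passed to [fit_apparent_modulus()].
#' @return A data.frame with columns `px_x`, `px_y`, `E_app_Pa`, `z_c_nm`,
#'   `residual_rms_pN`, `n_points`, `model`, `window_lo_nm`, `window_hi_nm`.
#' @export
fit_force_volume <- function(fvmap, model, fit_window = c(0, 1000), stride = 1L,
                             baseline_fraction = NULL, ...) {
  stopifnot(inherits(fvmap, "force_volume"))
  dims <- dim(fvmap$force)
  rows <- seq(1L, dims[1], by = stride)
  cols <- seq(1L, dims[2], by = stride)
  out <- vector("list", length(rows) * length(cols))
  i <- 0L
  for (r in rows) {
    for (cc in cols) {
      i <- i + 1L
      curve <- fv_curve(fvmap, r, cc)
      if (!is.null(baseline_fraction)) {
        curve <- correct_baseline(curve, baseline_fraction)
      }
      fit <- tryCatch(
        fit_apparent_modulus(curve, model, fit_window = fit_window, ...),
        error = function(e) NULL
      )
      out[[i]] <- data.frame(
        px_x = cc, px_y = r,
        E_app_Pa = if (is.null(fit)) NA_real_ else fit$E_app,
        z_c_nm = if (is.null(fit)) NA_real_ else fit$contact_point,
        residual_rms_pN = if (is.null(fit)) NA_real_ else fit$residual_rms,
        n_points = if (is.null(fit)) NA_integer_ else fit$n_points
      )
    }
  }
  tab <- do.call(rbind, out)
  tab$model <- model$kind
  tab$window_lo_nm <- fit_window[1]
  tab$window_hi_nm <- fit_window[2]
  tab
}
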