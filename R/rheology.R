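# Amplitude-sweep rheology: linear viscoelastic range (LVER), storage-
# modulus averaging, shear-to-Young conversion, loss factor.

#' Construct an amplitude sweep
#'
#' @param strain Shear strain values in percent, positive increasing.
#' @param g_prime Storage moduli G' in Pa.
#' @param g_double_prime Loss moduli G'' in Pa.
#' @param angular_frequency Angular frequency in rad/s (metadata).
#' @param temperature Temperature in degrees Celsius (metadata).
#' @return An object of class `amplitude_sweep`.
#' @export
amplitude_sweep <- function(strain, g_prime, g_double_prime,
                            angular_frequency = 1, temperature = 37) {
  if (!is.numeric(strain) || length(strain) < 8L) {
    stop_field("strain", "must be a numeric vector of at least 8 points")
  }
  if (length(g_prime) != length(strain) || length(g_double_prime) != length(strain)) {
    stop_field("g_prime/g_double_prime", "must match the length of `strain`")
  }
  if (any(strain <= 0) || any(diff(strain) <= 0)) {
    stop_field("strain", "must be positive and strictly increasing")
  }
  if (any(g_prime <= 0) || any(g_double_prime <= 0)) {
    stop_field("g_prime/g_double_prime", "moduli must be positive")
  }
  structure(list(strain = as.numeric(strain), g_prime = as.numeric(g_prime),
                 g_double_prime = as.numeric(g_double_prime),
                 angular_frequency = angular_frequency,
                 temperature = temperature),
            class = "amplitude_sweep")
}

#' Read an amplitude sweep from CSV
#'
#' Expects a header row with columns `strain_percent`, `G_prime_Pa`,
#' `G_doubleprime_Pa`.
#'
#' @param path CSV file path.
#' @param ... Passed to [amplitude_sweep()].
#' @return An [amplitude_sweep()].
#' @export
read_amplitude_sweep <- function(path, ...) {
  df <- utils::read.csv(path)
  need <- c("strain_percent", "G_prime_Pa", "G_doubleprime_Pa")
  if (!all(need %in% names(df))) {
    stop(sprintf("amplitude-sweep CSV must contain columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  amplitude_sweep(df$strain_percent, df$G_prime_Pa, df$G_doubleprime_Pa, ...)
}

#' Write an amplitude sweep to CSV
#'
#' @param sweep An [amplitude_sweep()].
#' @param path Output CSV path.
#' @export
write_amplitude_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "amplitude_sweep"))
  utils::write.csv(data.frame(strain_percent = sweep$strain,
                              G_prime_Pa = sweep$g_prime,
                              G_doubleprime_Pa = sweep$g_double_prime),
                   path, row.names = FALSE)
  invisible(path)
}

#' Find the linear viscoelastic range of an amplitude sweep
#'
#' The plateau level is estimated robustly (median of the leading quarter of
#' points, refined by averaging all points within `deviation` of that
#' median). The LVER is the leading contiguous run of strains whose G'
#' stays at or above `(1 - deviation)` times the plateau - i.e. it ends
#' where the storage modulus first deviates by more than 10 % (by default)
#' from its plateau value.
#'
#' @param sweep An [amplitude_sweep()].
#' @param deviation Allowed relative deviation from the plateau, in (0, 0.5).
#' @param report_slope Also fit a straight line to G' over the LVER and
#'   report its relative slope (per decade of strain), as a check that the
#'   "plateau" really is flat.
#' @return A list of class `lver`: `interval` (strain range in percent),
#'   `idx` (indices in the sweep), `plateau` (Pa), `n_points`, `deviation`,
#'   and optionally `rel_slope_per_decade`.
#' @export
find_lver <- function(sweep, deviation = 0.10, report_slope = TRUE) {
  stopifnot(inherits(sweep, "amplitude_sweep"))
  check_num(deviation, "deviation", lower = 0, upper = 0.5,
            strict_lower = TRUE, strict_upper = TRUE)
  gp <- sweep$g_prime
  n <- length(gp)
  lead <- seq_len(max(2L, ceiling(0.25 * n)))
  plateau0 <- stats::median(gp[lead])
  inl <- abs(gp / plateau0 - 1) <= deviation
  plateau <- if (any(inl)) mean(gp[inl]) else plateau0
  # no flat region: the sweep decays from its very first point, so the
  # leading window spans far more than the deviation band
  if (sum(inl) < 3L || sum(inl[lead]) < 3L) {
    stop("no LVER: the storage modulus decays from the first point with no plateau",
         call. = FALSE)
  }
  ok <- gp >= (1 - deviation) * plateau
  if (!any(ok)) {
    stop("no LVER: no strain stays within the plateau deviation band", call. = FALSE)
  }
  end <- max(which(ok))
  idx <- seq_len(end)
  out <- list(interval = c(sweep$strain[1], sweep$strain[end]), idx = idx,
              plateau = plateau, n_points = end, deviation = deviation)
  if (report_slope && end >= 2L) {
    fit <- stats::lm.fit(cbind(1, log10(sweep$strain[idx])), gp[idx])
    out$rel_slope_per_decade <- unname(fit$coefficients[2]) / plateau
  }
  structure(out, class = "lver")
}

#' Mean storage modulus over the LVER
#'
#' @param sweep An [amplitude_sweep()].
#' @param lver An `lver` from [find_lver()].
#' @return A list with `mean` (Pa), `sd` (Pa, 0 for a single point), `n`.
#' @export
mean_storage_modulus <- function(sweep, lver) {
  stopifnot(inherits(sweep, "amplitude_sweep"), inherits(lver, "lver"))
  if (length(lver$idx) == 0L) stop("empty LVER interval", call. = FALSE)
  g <- sweep$g_prime[lver$idx]
  list(mean = mean(g), sd = if (length(g) > 1) stats::sd(g) else 0,
       n = length(g))
}

#' Convert a shear modulus to a Young's modulus
#'
#' For a linear elastic isotropic material `E = 2 G (1 + nu)`; with the
#' incompressibility assumption `nu = 0.5` this is exactly `E = 3 G`.
#'
#' @param G_prime Shear (storage) modulus in Pa.
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @return Young's modulus in Pa.
#' @export
youngs_from_shear <- function(G_prime, nu = 0.5) {
  if (any(G_prime <= 0)) stop_field("G_prime", "must be positive")
  check_num(nu, "nu", lower = 0, upper = 0.5)
  2 * G_prime * (1 + nu)
}

#' Loss factor over the LVER
#'
#' Mean of the pointwise ratio G''/G' over the LVER points; values below 1
#' indicate solid-like behaviour.
#'
#' @param sweep An [amplitude_sweep()].
#' @param lver An `lver` from [find_lver()].
#' @return The dimensionless loss factor.
#' @export
loss_factor <- function(sweep, lver) {
  stopifnot(inherits(sweep, "amplitude_sweep"), inherits(lver, "lver"))
  if (length(lver$idx) == 0L) stop("empty LVER interval", call. = FALSE)
  mean(sweep$g_double_prime[lver$idx] / sweep$g_prime[lver$idx])
}

#' Full LVER analysis of one amplitude sweep
#'
#' Finds the LVER, averages G' over it, converts to a Young's modulus
#' (`E = 3 G'` at `nu = 0.5`) and computes the loss factor.
#'
#' @param sweep An [amplitude_sweep()].
#' @param deviation Plateau deviation defining the LVER.
#' @param nu Poisson ratio for the shear-to-Young conversion.
#' @return A list of class `lver_result`: `lver_range` (%), `mean_G_prime`,
#'   `sd_G_prime`, `youngs_modulus` (Pa), `loss_factor`, `n_points_in_lver`,
#'   `nu`, `rel_slope_per_decade`.
#' @export
analyze_sweep <- function(sweep, deviation = 0.10, nu = 0.5) {
  lv <- find_lver(sweep, deviation)
  ms <- mean_storage_modulus(sweep, lv)
  structure(list(lver_range = lv$interval, mean_G_prime = ms$mean,
                 sd_G_prime = ms$sd,
                 youngs_modulus = youngs_from_shear(ms$mean, nu),
                 loss_factor = loss_factor(sweep, lv),
                 n_points_in_lver = ms$n, nu = nu,
                 rel_slope_per_decade = lv$rel_slope_per_decade %||% NA_real_),
            class = "lver_result")
}

#' @export
print.lver_result <- function(x, ...) {
  cat(sprintf(paste0("<lver_result> LVER %.3g-%.3g%%, G' = %.4g +/- %.2g Pa, ",
                     "E = %.4g Pa (nu = %g), loss factor %.3g (n = %d)\n"),
              x$lver_range[1], x$lver_range[2], x$mean_G_prime, x$sd_G_prime,
              x$youngs_modulus, x$nu, x$loss_factor, x$n_points_in_lver))
  invisible(x)
}

#' Average LVER results over replicate sweeps
#'
#' Independent replicate measurements are analyzed sweep by sweep and the
#' sweep-level results averaged (mean and SD across replicates, not pooled
#' points).
#'
#' @param sweeps A list of [amplitude_sweep()]s.
#' @param ... Passed to [analyze_sweep()].
#' @return A list with per-replicate `results` and `summary` (mean and sd of
#'   `mean_G_prime`, `youngs_modulus`, `loss_factor` across replicates).
#' @export
analyze_replicates <- function(sweeps, ...) {
  stopifnot(length(sweeps) >= 1L)
  res <- lapply(sweeps, analyze_sweep, ...)
  g <- vapply(res, `[[`, numeric(1), "mean_G_prime")
  e <- vapply(res, `[[`, numeric(1), "youngs_modulus")
  lf <- vapply(res, `[[`, numeric(1), "loss_factor")
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  list(results = res,
       summary = list(n = length(res),
                      mean_G_prime = mean(g), sd_G_prime = sd0(g),
                      youngs_modulus = mean(e), sd_youngs = sd0(e),
                      loss_factor = mean(lf), sd_loss_factor = sd0(lf)))
}
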