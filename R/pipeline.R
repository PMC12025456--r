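# Statistics helpers and the end-to-end phantom analysis pipeline.

#' Two-sample comparison with star annotation
#'
#' Unpaired two-sample t-test, equal-variance (Student) by default with
#' Welch's correction behind a flag, annotated with the conventional
#' significance stars (one per alpha level crossed).
#'
#' @param a,b Numeric vectors (each `n >= 2`).
#' @param alpha_levels Decreasing significance thresholds for the stars.
#' @param welch Use Welch's unequal-variance test instead of Student's.
#' @return A list of class `group_comparison`: `statistic`, `df`, `p_value`,
#'   `stars` (`""`, `"*"`, `"**"`, `"***"`), `mean_a`, `mean_b`, `method`.
#' @export
compare_groups <- function(a, b, alpha_levels = c(0.05, 0.01, 0.001),
                           welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_field("a/b", "each group needs at least 2 observations")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
               parameter = length(a) + length(b) - 2,
               p.value = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
  }
  p <- tt$p.value
  stars <- paste(rep("*", sum(p < alpha_levels)), collapse = "")
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = p, stars = stars, mean_a = mean(a), mean_b = mean(b),
                 method = if (welch) "Welch two-sample t-test"
                          else "Student two-sample t-test (equal variance)"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> t = %.3g (df = %.3g), p = %.3g %s [%s]\n",
              x$statistic, x$df, x$p_value, x$stars, x$method))
  invisible(x)
}

#' Summarize a group of values for box-chart reporting
#'
#' Mean, SD (reported as 0 with a flag for a single observation), and the
#' 5th/95th percentiles computed with linear interpolation between order
#' statistics (R quantile type 7; the convention is recorded in the output).
#'
#' @param values Numeric vector, `n >= 1`.
#' @param label Optional group label.
#' @return A list of class `group_summary`: `label`, `n`, `mean`, `sd`,
#'   `percentile_5`, `percentile_95`, `flag`, `percentile_method`.
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop_field("values", "must be a non-empty numeric vector without NAs")
  }
  q <- stats::quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
  structure(list(label = label, n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 percentile_5 = q[1], percentile_95 = q[2],
                 flag = if (length(values) == 1) "single observation: sd set to 0" else NULL,
                 percentile_method = "linear interpolation between order statistics (type 7)"),
            class = "group_summary")
}

#' Build a pipeline run configuration
#'
#' @param phantom A [phantom_spec()] describing the input to simulate, or a
#'   directory containing a force-volume container written by
#'   [write_force_volume()].
#' @param targets Reconstruction load forces in pN, sorted ascending; the
#'   first and last are used for the deformability pairing.
#' @param fit_model An [indenter_model()] for modulus fitting.
#' @param fit_window Indentation window in nm.
#' @param fit_stride Pixel stride for modulus fitting.
#' @param depth_threshold,d_range,min_circularity,smooth_sigma Morphometry
#'   settings (see [detect_pores()]).
#' @param cell_threshold,bulge_threshold Segmentation heights in nm (`NULL`
#'   for automatic choices).
#' @param alpha_levels Significance thresholds for reported comparisons.
#' @param out_dir Output directory (`NULL` for no file output).
#' @param seed Seed for the phantom simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), targets = c(170, 300),
                       fit_model = NULL, fit_window = c(50, 900),
                       fit_stride = 2L, depth_threshold = NULL,
                       d_range = c(50, 350), min_circularity = 0.2,
                       smooth_sigma = NULL, cell_threshold = NULL,
                       bulge_threshold = NULL,
                       alpha_levels = c(0.05, 0.01, 0.001),
                       out_dir = NULL, seed = NULL) {
  if (any(targets <= 0) || is.unsorted(targets)) {
    stop_field("targets", "must be positive and sorted ascending")
  }
  if (is.character(phantom) && !dir.exists(phantom)) {
    stop_field("phantom", "input directory does not exist")
  }
  structure(list(phantom = phantom, targets = targets, fit_model = fit_model,
                 fit_window = fit_window, fit_stride = as.integer(fit_stride),
                 depth_threshold = depth_threshold, d_range = d_range,
                 min_circularity = min_circularity, smooth_sigma = smooth_sigma,
                 cell_threshold = cell_threshold, bulge_threshold = bulge_threshold,
                 alpha_levels = alpha_levels, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the end-to-end phantom analysis pipeline
#'
#' Phantom simulation (or loading), per-pixel modulus fitting, topography
#' reconstruction at each target force, flattening, cell and nuclear
#' segmentation, pore detection, porosity with nuclear exclusion, and - when
#' at least two targets are given - one-to-one pore matching and the
#' deformability summary. All thresholds and the seed are echoed in the
#' returned provenance block; a fixed configuration gives identical output.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report` with elements `moduli`
#'   (fit table and summary), `reconstructions`, `porosity`,
#'   `deformability`, `truth` (when simulated), and `provenance`. When
#'   `out_dir` is set, tables are written as CSV, maps as TIFF and the
#'   report as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (inherits(config$phantom, "phantom_spec")) {
    spec <- config$phantom
    if (!is.null(config$seed)) {
      spec$seed <- as.integer(config$seed)
    }
    sim <- generate_phantom(spec)
    truth <- sim$truth
    fvmap <- sim$fvmap
  } else {
    fvmap <- read_force_volume(config$phantom)
  }

  model <- config$fit_model %||%
    indenter_model("sphere",
                   tip_radius = if (!is.null(truth)) truth$spec$tip_radius else 25)
  fits <- fit_force_volume(fvmap, model, fit_window = config$fit_window,
                           stride = config$fit_stride)
  moduli <- list(table = fits,
                 median_E_Pa = stats::median(fits$E_app_Pa, na.rm = TRUE),
                 n_failed = sum(is.na(fits$E_app_Pa)))

  stack <- reconstruct_stack(fvmap, config$targets)
  flat <- lapply(stack, flatten_map)
  base <- flat[[1]]
  seg <- segment_cell(base, config$cell_threshold)
  bulge_thr <- config$bulge_threshold
  if (is.null(bulge_thr)) {
    hv <- base$heights[seg$mask]
    bulge_thr <- stats::quantile(hv, 0.5, na.rm = TRUE) +
      0.25 * (max(hv, na.rm = TRUE) - stats::quantile(hv, 0.5, na.rm = TRUE))
  }
  nuc <- detect_nuclear_region(base, bulge_thr)
  pores <- lapply(flat, detect_pores, cell_mask = seg$mask,
                  depth_threshold = config$depth_threshold,
                  d_range = config$d_range,
                  min_circularity = config$min_circularity,
                  smooth_sigma = config$smooth_sigma, nuclear_mask = nuc)
  porosity <- compute_porosity(pores[[1]], seg$mask, nuc, fvmap$pixel_size)

  deform <- NULL
  matching <- NULL
  if (length(config$targets) >= 2L) {
    matching <- match_pores(pores[[1]], pores[[length(pores)]])
    if (nrow(matching$pairs) > 0) deform <- deformability_summary(matching)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("fenestra")),
    seed = config$seed %||% (if (!is.null(truth)) truth$spec$seed else NA),
    targets_pN = config$targets, fit_model = model$kind,
    fit_window_nm = config$fit_window, fit_stride = config$fit_stride,
    cell_threshold_nm = seg$threshold_nm, bulge_threshold_nm = unname(bulge_thr),
    depth_threshold_nm = attr(pores[[1]], "depth_threshold_nm"),
    diameter_criterion = attr(pores[[1]], "criterion"),
    d_range_nm = config$d_range, min_circularity = config$min_circularity,
    smooth_sigma_px = attr(pores[[1]], "smooth_sigma_px"),
    match_max_dist_nm = if (!is.null(matching)) matching$max_centroid_dist_nm else NA,
    alpha_levels = config$alpha_levels,
    percentile_method = "linear interpolation between order statistics (type 7)",
    pixel_size_nm = fvmap$pixel_size,
    spring_constant_N_per_m = fvmap$spring_constant)

  report <- structure(list(moduli = moduli, reconstructions = flat,
                           cell = seg, nuclear_mask = nuc, pores = pores,
                           porosity = porosity, matching = matching,
                           deformability = deform, truth = truth,
                           provenance = provenance),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$moduli$table, file.path(out_dir, "modulus_fits.csv"),
                   row.names = FALSE)
  for (nm in names(report$reconstructions)) {
    write_height_map(report$reconstructions[[nm]],
                     file.path(out_dir, sprintf("height_%spN.tif", nm)))
    utils::write.csv(as.data.frame(report$pores[[nm]]),
                     file.path(out_dir, sprintf("pores_%spN.csv", nm)),
                     row.names = FALSE)
  }
  if (!is.null(report$matching)) {
    utils::write.csv(report$matching$pairs,
                     file.path(out_dir, "deformability_pairs.csv"),
                     row.names = FALSE)
  }
  summary_json <- list(
    porosity = unclass(report$porosity),
    deformability = if (!is.null(report$deformability)) unclass(report$deformability),
    median_E_Pa = report$moduli$median_E_Pa,
    provenance = report$provenance)
  jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  median apparent modulus: %.3g Pa (%d curves, %d failed)\n",
              x$moduli$median_E_Pa, nrow(x$moduli$table), x$moduli$n_failed))
  cat(sprintf("  porosity: %.3g fen./um^2 (%d fenestrations, %d nuclear excluded)\n",
              x$porosity$porosity, x$porosity$n_fenestrations,
              x$porosity$n_excluded_nuclear))
  if (!is.null(x$deformability)) {
    cat(sprintf("  deformability (%s/%s pN): mean fold %.3g, enlargement %.1f%% (n = %d)\n",
                x$matching$force_high, x$matching$force_low,
                x$deformability$mean_fold, x$deformability$percent_enlargement,
                x$deformability$n_pairs))
  }
  invisible(x)
}
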