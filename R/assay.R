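# Assay quantification: threshold-based nuclei counting, area measurement,
# and per-cell endocytosis normalization.

#' Count nuclei by threshold segmentation
#'
#' Global threshold, connected components, size filter - the simple
#' threshold-based counting used to normalize per-well assays to cell
#' number. Touching nuclei merge into one component; this is a documented
#' limitation of the method, not corrected by watershed splitting.
#'
#' @param image Single-channel intensity matrix, or a path to a TIFF file.
#' @param threshold Global intensity threshold; `NULL` chooses one
#'   automatically by Otsu's method.
#' @param min_area_px Minimum component area in pixels.
#' @return Integer count. A `flag` attribute is set (with a warning) for
#'   blank or saturated images.
#' @export
count_nuclei <- function(image, threshold = NULL, min_area_px = 9L) {
  if (is.character(image)) image <- read_intensity_tiff(image)
  stopifnot(is.matrix(image))
  rng <- range(image)
  flag <- NULL
  if (diff(rng) < 1e-9) {
    warning("image is blank (constant intensity); returning a count of 0",
            call. = FALSE)
    return(structure(0L, flag = "blank"))
  }
  if (mean(image >= rng[2] - 1e-9) > 0.5) {
    flag <- "saturated"
    warning("image looks saturated; the count may be unreliable", call. = FALSE)
  }
  if (is.null(threshold)) {
    sc <- (image - rng[1]) / diff(rng)
    threshold <- rng[1] + diff(rng) *
      EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  }
  m <- image > threshold
  if (!any(m)) return(structure(0L, flag = flag, threshold = threshold))
  lab <- EBImage::bwlabel(m * 1)
  sizes <- tabulate(lab[lab > 0])
  structure(sum(sizes >= min_area_px), flag = flag, threshold = threshold)
}

#' Measure cell and nucleus areas from masks
#'
#' @param cell_mask,nucleus_mask Logical matrices on the same grid.
#' @param pixel_size Pixel size in nm.
#' @return A list with `cell_area_um2`, `nucleus_area_um2`, and a `flag`
#'   field set to `"empty"` when either mask is empty.
#' @export
measure_areas <- function(cell_mask, nucleus_mask, pixel_size) {
  stopifnot(is.logical(cell_mask), is.logical(nucleus_mask),
            all(dim(cell_mask) == dim(nucleus_mask)))
  check_num(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  f <- pixel_size^2 / 1e6
  list(cell_area_um2 = sum(cell_mask) * f,
       nucleus_area_um2 = sum(nucleus_mask) * f,
       flag = if (!any(cell_mask) || !any(nucleus_mask)) "empty" else NULL)
}

#' Normalize endocytosis totals to cell number
#'
#' Total endocytosis per well is the sum of the cell-associated and degraded
#' fractions, normalized to the number of cells in that well. Wells with a
#' non-positive cell count are excluded with a warning. Group summaries
#' (mean and SD of the per-cell total) are computed by `substrate_label`.
#'
#' @param wells A data.frame with columns `cell_associated`, `degraded`,
#'   `n_cells`, and optionally `substrate_label`.
#' @return A list with `wells` (the input plus `total` and
#'   `normalized_total` columns) and `groups` (per-label `n`, `mean`, `sd`).
#' @export
normalize_endocytosis <- function(wells) {
  stopifnot(is.data.frame(wells))
  need <- c("cell_associated", "degraded", "n_cells")
  if (!all(need %in% names(wells))) {
    stop(sprintf("wells must contain columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (any(wells$cell_associated < 0) || any(wells$degraded < 0)) {
    stop_field("cell_associated/degraded", "activities must be non-negative")
  }
  if (is.null(wells$substrate_label)) wells$substrate_label <- "all"
  bad <- wells$n_cells <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d well(s) with non-positive cell counts", sum(bad)),
            call. = FALSE)
    wells <- wells[!bad, , drop = FALSE]
  }
  wells$total <- wells$cell_associated + wells$degraded
  wells$normalized_total <- wells$total / wells$n_cells
  groups <- do.call(rbind, lapply(split(wells, wells$substrate_label), function(g) {
    data.frame(substrate_label = g$substrate_label[1], n = nrow(g),
               mean_normalized = mean(g$normalized_total),
               sd_normalized = if (nrow(g) > 1) stats::sd(g$normalized_total) else 0)
  }))
  rownames(groups) <- NULL
  list(wells = wells, groups = groups)
}
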