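# Fenestration morphometry: flattening, cell and nuclear segmentation, pore
# detection, porosity (fenestrations per square micrometre) and the
# load-dependent deformability fold change.

#' Flatten a height map line by line
#'
#' Masked per-scan-line polynomial flattening. The dominant background level
#' of the map is first identified (the larger of two height clusters, with
#' the tail above the 75th percentile clipped so a tall nuclear bulge cannot
#' capture a cluster). Each scan line's polynomial (order 0, 1 or 2) is then
#' fitted only to pixels near that background level, with iterative residual
#' clipping so pores, cell edges and streaks do not bias it; lines that
#' contain no background pixels (e.g. lines crossing only the cell interior)
#' receive coefficients interpolated from neighbouring lines, which
#' preserves height steps such as the cell-substrate edge. Finally the map
#' is shifted so the substrate (lower-cluster) median sits at zero.
#'
#' @param map A [height_map()].
#' @param order Polynomial order per line: 0 (offset), 1 (tilt) or 2 (bow).
#' @param n_iter Clipping iterations.
#' @param clip Residual clip factor in robust SDs.
#' @return The flattened [height_map()].
#' @export
flatten_map <- function(map, order = 1L, n_iter = 3L, clip = 2.5) {
  stopifnot(inherits(map, "height_map"))
  if (!order %in% 0:2) stop_field("order", "must be 0, 1 or 2")
  h <- map$heights
  if (!any(map$valid_mask & !is.na(h))) {
    stop("cannot flatten: map has no valid pixels", call. = FALSE)
  }
  nx <- ncol(h); nyr <- nrow(h)
  v <- h[map$valid_mask & !is.na(h)]
  vc <- pmin(v, stats::quantile(v, 0.75))
  init <- unname(stats::quantile(vc, c(0.05, 0.95)))
  if (diff(init) < 1e-9) {
    centers <- c(init[1], init[1])
    sizes <- c(length(vc), 0)
  } else {
    km <- stats::kmeans(vc, centers = matrix(init, 2, 1))
    ord <- order(km$centers[, 1])
    centers <- km$centers[ord, 1]
    sizes <- km$size[ord]
  }
  dominant <- centers[which.max(sizes)]
  sep <- abs(diff(centers))
  band <- if (sep > 1e-9) 0.5 * sep else max(3 * stats::mad(v), 1e-9)

  x <- seq_len(nx)
  X <- cbind(1, stats::poly(x, degree = max(order, 1L),
                            raw = TRUE))[, seq_len(order + 1L), drop = FALSE]
  coefs <- matrix(NA_real_, nyr, order + 1L)
  for (r in seq_len(nyr)) {
    y <- h[r, ]
    use <- !is.na(y) & abs(y - dominant) < band
    if (sum(use) < order + 2L) next
    for (it in seq_len(n_iter)) {
      fit <- stats::lm.fit(X[use, , drop = FALSE], y[use])
      res <- y - as.vector(X %*% fit$coefficients)
      s <- stats::mad(res[use], center = 0)
      if (!is.finite(s) || s <= 0) break
      new_use <- !is.na(y) & abs(y - dominant) < band & abs(res) < clip * s
      if (sum(new_use) < order + 2L || identical(new_use, use)) break
      use <- new_use
    }
    coefs[r, ] <- fit$coefficients
  }
  have <- which(!is.na(coefs[, 1]))
  if (length(have) == 0L) stop("cannot flatten: no background pixels found", call. = FALSE)
  for (j in seq_len(ncol(coefs))) {
    coefs[, j] <- stats::approx(have, coefs[have, j], xout = seq_len(nyr),
                                rule = 2)$y
  }
  h <- h - coefs %*% t(X)
  # after flattening the clusters sit near (centers - dominant); reference
  # the substrate (lower-cluster) median to zero
  v2 <- h[map$valid_mask & !is.na(h)]
  if (sep > 1e-9) {
    mid <- mean(centers - dominant)
    lower <- v2[v2 <= mid]
    sub_level <- if (length(lower)) stats::median(lower) else stats::median(v2)
  } else {
    sub_level <- stats::median(v2)
  }
  h <- h - sub_level
  height_map(h, map$valid_mask, map$pixel_size, map$load_force, map$fast_axis)
}

#' Segment the cell body of a flattened height map
#'
#' Thresholds the map, keeps the largest connected component and fills its
#' holes (pores count toward the projected cell area).
#'
#' @param map A flattened [height_map()].
#' @param height_threshold Height above substrate (nm) separating cell from
#'   substrate; `NULL` chooses it automatically as the midpoint between the
#'   substrate and cell-body height clusters (2-means on heights clipped at
#'   their 75th percentile, so a tall nuclear bulge cannot dominate).
#' @return A list with `mask` (logical matrix, holes filled), `area_um2`,
#'   and the `threshold_nm` used.
#' @export
segment_cell <- function(map, height_threshold = NULL) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  if (is.null(height_threshold)) {
    v <- h[map$valid_mask & !is.na(h)]
    vc <- pmin(v, stats::quantile(v, 0.75))
    init <- stats::quantile(vc, c(0.05, 0.95))
    if (diff(init) < 1e-9) {
      height_threshold <- unname(init[1]) - 1    # flat map: keep everything
    } else {
      km <- stats::kmeans(vc, centers = matrix(init, 2, 1))
      height_threshold <- mean(km$centers)
    }
  }
  m <- (!is.na(h)) & (h > height_threshold)
  if (!any(m)) stop("cell segmentation produced an empty mask", call. = FALSE)
  lab <- EBImage::bwlabel(m * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask * 1) > 0
  list(mask = mask, area_um2 = sum(mask) * map$pixel_size^2 / 1e6,
       threshold_nm = height_threshold)
}

#' Detect the nuclear bulge region of a flattened height map
#'
#' Pores over the nucleus ("fenestrae labyrinths") are not transcellular and
#' must be excluded from porosity; this returns the high contiguous region
#' above `bulge_threshold`, morphologically closed. An empty mask is a valid
#' result (flat cell, no bulge).
#'
#' @param map A flattened [height_map()].
#' @param bulge_threshold Height above substrate (nm) above which pixels are
#'   considered part of the nuclear bulge.
#' @param close_px Diameter (px) of the disc used for morphological closing.
#' @return Logical matrix.
#' @export
detect_nuclear_region <- function(map, bulge_threshold, close_px = 7L) {
  stopifnot(inherits(map, "height_map"))
  check_num(bulge_threshold, "bulge_threshold", lower = 0)
  h <- map$heights
  m <- (!is.na(h)) & (h > bulge_threshold)
  if (!any(m)) return(matrix(FALSE, nrow(h), ncol(h)))
  brush <- EBImage::makeBrush(max(3L, close_px - (close_px + 1L) %% 2L), "disc")
  m <- EBImage::closing(m * 1, brush) > 0
  lab <- EBImage::bwlabel(m * 1)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  EBImage::fillHull(mask * 1) > 0
}

# fast-axis width of one pore at a depth criterion, with sub-pixel
# interpolation along the centroid scan line
.fast_axis_diameter <- function(hs, comp_mask, cy_px, cx_px, level, pixel_size) {
  row <- hs[cy_px, ]
  nx <- length(row)
  j0 <- cx_px
  # walk right from the centroid until the profile rises through `level`
  jr <- j0
  while (jr < nx && !is.na(row[jr + 1]) && row[jr + 1] < level) jr <- jr + 1
  xr <- if (jr < nx && !is.na(row[jr + 1]) && row[jr + 1] >= level) {
    jr + (level - row[jr]) / (row[jr + 1] - row[jr])
  } else jr + 0.5
  jl <- j0
  while (jl > 1 && !is.na(row[jl - 1]) && row[jl - 1] < level) jl <- jl - 1
  xl <- if (jl > 1 && !is.na(row[jl - 1]) && row[jl - 1] >= level) {
    jl - (level - row[jl]) / (row[jl - 1] - row[jl])
  } else jl - 0.5
  (xr - xl) * pixel_size
}

#' Detect pores in a flattened height map
#'
#' Pore pixels are those deeper than `depth_threshold` below the local cell
#' surface (the median height of the cell mask), inside the cell mask.
#' Connected components are filtered by fast-axis diameter range and
#' circularity. The diameter of each pore is measured on the raw
#' (unsmoothed) map along the fast scan axis through its centroid, with
#' sub-pixel linear interpolation, at a configurable depth criterion
#' (default: halfway between the local cell surface and the substrate,
#' which is stable under noise and does not depend on a per-pore depth
#' estimate).
#'
#' @param map A flattened [height_map()].
#' @param cell_mask Logical matrix from [segment_cell()].
#' @param depth_threshold Depth (nm) below the local cell surface defining a
#'   pore pixel; `NULL` uses half the apparent membrane height (cell surface
#'   minus substrate level).
#' @param d_range Admissible fast-axis diameter range in nm; the
#'   physiological fenestration range `c(50, 350)` by default (widen for
#'   micron-scale hydrogel pores).
#' @param min_circularity Minimum circularity `4 pi A / P^2` (capped at 1).
#' @param smooth_sigma Gaussian pre-smoothing SD in pixels; `NULL` (the
#'   default) uses a physical smoothing length of 25 nm - half the smallest
#'   fenestration diameter - converted to pixels (minimum 0.25 px), so maps
#'   recorded at different pixel sizes are smoothed comparably. 0 disables.
#' @param nuclear_mask Optional logical matrix; pores whose centroid falls
#'   inside are flagged `in_nuclear_region`.
#' @param criterion Depth criterion for the diameter measurement:
#'   `"half_depth"` (level halfway between local surface and pore bottom),
#'   `"fixed_depth"` (level = surface - `depth_threshold`), or
#'   `"full_width"` (level just below the surface, width of the whole
#'   depression). Recorded in the output attributes.
#' @return A data.frame of class `pore_table` with one row per pore:
#'   `pore_id`, `x_nm`, `y_nm`, `diameter_fast_axis_nm`, `depth_nm`,
#'   `area_nm2`, `circularity`, `in_nuclear_region`, `sieve_plate_id`.
#'   Attributes record the thresholds, criterion, pixel size and load force.
#' @export
detect_pores <- function(map, cell_mask, depth_threshold = NULL,
                         d_range = c(50, 350), min_circularity = 0.2,
                         smooth_sigma = NULL, nuclear_mask = NULL,
                         criterion = c("half_depth", "fixed_depth", "full_width")) {
  stopifnot(inherits(map, "height_map"))
  criterion <- match.arg(criterion)
  ps <- map$pixel_size
  if (is.null(smooth_sigma)) smooth_sigma <- max(0.25, 25 / ps)
  h <- map$heights
  h[is.na(h)] <- stats::median(h, na.rm = TRUE)
  hs <- if (smooth_sigma > 0) {
    as.matrix(EBImage::gblur(h, sigma = smooth_sigma))
  } else h
  if (!any(cell_mask)) {
    return(.empty_pore_table(map, depth_threshold, criterion))
  }
  surface <- stats::median(hs[cell_mask])
  substrate <- if (any(!cell_mask)) stats::median(hs[!cell_mask]) else 0
  membrane <- surface - substrate
  if (is.null(depth_threshold)) depth_threshold <- 0.5 * membrane
  if (depth_threshold <= 0) {
    warning("depth_threshold is at or below the noise floor; detection may be unreliable",
            call. = FALSE)
  }
  cand <- cell_mask & (hs < surface - depth_threshold)
  lab <- EBImage::bwlabel(cand * 1)
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(.empty_pore_table(map, depth_threshold, criterion))
  }
  # components and depths come from the smoothed map (stable under noise);
  # the diameter is measured on the raw map so smoothing does not widen it
  level <- switch(criterion,
    half_depth = surface - 0.5 * membrane,
    fixed_depth = surface - depth_threshold,
    full_width = surface - max(depth_threshold * 0.25, 1e-9))
  shp <- EBImage::computeFeatures.shape(lab)
  rows <- vector("list", n_comp)
  for (i in seq_len(n_comp)) {
    idx <- which(lab == i, arr.ind = TRUE)
    depth_i <- surface - min(hs[idx])
    cy <- stats::weighted.mean(idx[, 1], surface - hs[idx])
    cx <- stats::weighted.mean(idx[, 2], surface - hs[idx])
    cy_px <- as.integer(round(cy)); cx_px <- as.integer(round(cx))
    diam <- .fast_axis_diameter(h, lab == i, cy_px, cx_px, level, ps)
    area <- shp[i, "s.area"] * ps^2
    per <- shp[i, "s.perimeter"]
    circ <- if (per > 0) min(4 * pi * shp[i, "s.area"] / per^2, 1) else 1
    rows[[i]] <- data.frame(
      pore_id = i, x_nm = cx * ps - ps / 2, y_nm = cy * ps - ps / 2,
      diameter_fast_axis_nm = diam, depth_nm = depth_i, area_nm2 = area,
      circularity = circ,
      in_nuclear_region = if (!is.null(nuclear_mask)) nuclear_mask[cy_px, cx_px] else FALSE)
  }
  pores <- do.call(rbind, rows)
  keep <- pores$diameter_fast_axis_nm >= max(d_range[1], ps) &
    pores$diameter_fast_axis_nm <= d_range[2] &
    pores$circularity >= min_circularity
  pores <- pores[keep, , drop = FALSE]
  pores$sieve_plate_id <- .group_sieve_plates(pores)
  rownames(pores) <- NULL
  structure(pores,
            class = c("pore_table", "data.frame"),
            depth_threshold_nm = depth_threshold, criterion = criterion,
            d_range_nm = d_range, min_circularity = min_circularity,
            smooth_sigma_px = smooth_sigma, pixel_size = ps,
            load_force = map$load_force, surface_nm = surface,
            membrane_nm = membrane)
}

.empty_pore_table <- function(map, depth_threshold, criterion) {
  structure(
    data.frame(pore_id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               diameter_fast_axis_nm = numeric(0), depth_nm = numeric(0),
               area_nm2 = numeric(0), circularity = numeric(0),
               in_nuclear_region = logical(0), sieve_plate_id = integer(0)),
    class = c("pore_table", "data.frame"),
    depth_threshold_nm = depth_threshold %||% NA_real_, criterion = criterion,
    pixel_size = map$pixel_size, load_force = map$load_force)
}

# density-based grouping of pore centroids into sieve plates (single-linkage
# clustering cut at a multiple of the typical diameter); reporting only
.group_sieve_plates <- function(pores, link_factor = 4) {
  n <- nrow(pores)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  d <- stats::dist(cbind(pores$x_nm, pores$y_nm))
  cut_h <- link_factor * stats::median(pores$diameter_fast_axis_nm)
  as.integer(stats::cutree(stats::hclust(d, method = "single"), h = cut_h))
}

#' Compute porosity (fenestrations per square micrometre)
#'
#' Pores whose centroid lies in the nuclear region are excluded; the
#' remaining count is divided by the projected cell area (holes filled).
#'
#' @param pores A `pore_table` from [detect_pores()].
#' @param cell_mask Logical cell mask (holes filled).
#' @param nuclear_mask Optional logical matrix; when supplied, the
#'   `in_nuclear_region` flags are recomputed from pore centroids.
#' @param pixel_size Pixel size in nm.
#' @return A list of class `porosity_result`: `n_fenestrations`,
#'   `cell_area_um2`, `porosity` (fen./um^2), `n_excluded_nuclear`.
#' @export
compute_porosity <- function(pores, cell_mask, nuclear_mask = NULL, pixel_size) {
  stopifnot(inherits(pores, "pore_table"))
  area <- sum(cell_mask) * pixel_size^2 / 1e6
  if (area <= 0) stop("zero cell area: cannot compute porosity", call. = FALSE)
  nuclear <- pores$in_nuclear_region
  if (!is.null(nuclear_mask) && nrow(pores) > 0) {
    iy <- clamp(as.integer(round(pores$y_nm / pixel_size + 0.5)), 1L, nrow(nuclear_mask))
    ix <- clamp(as.integer(round(pores$x_nm / pixel_size + 0.5)), 1L, ncol(nuclear_mask))
    nuclear <- nuclear_mask[cbind(iy, ix)]
  }
  n_keep <- sum(!nuclear)
  structure(list(n_fenestrations = n_keep, cell_area_um2 = area,
                 porosity = n_keep / area,
                 n_excluded_nuclear = sum(nuclear)),
            class = "porosity_result")
}

#' @export
print.porosity_result <- function(x, ...) {
  cat(sprintf("<porosity> %.3g fen./um^2 (%d fenestrations over %.3g um^2, %d nuclear excluded)\n",
              x$porosity, x$n_fenestrations, x$cell_area_um2, x$n_excluded_nuclear))
  invisible(x)
}

#' Match pores between two reconstructions of the same scan
#'
#' Greedy nearest-centroid one-to-one matching under a distance cap, ordered
#' by distance so the result does not depend on pore ordering.
#'
#' @param pores_low,pores_high `pore_table`s from the low- and high-force
#'   reconstructions of the same scan.
#' @param max_centroid_dist Maximum centroid distance (nm) for a match;
#'   `NULL` uses 3 pixels.
#' @return A list of class `pore_matching` with `pairs` (data.frame:
#'   `id_low`, `id_high`, `dist_nm`, `diameter_low_nm`, `diameter_high_nm`,
#'   `fold_change`), `unmatched_low`, `unmatched_high` (pore ids), and the
#'   forces of both maps.
#' @export
match_pores <- function(pores_low, pores_high, max_centroid_dist = NULL) {
  stopifnot(inherits(pores_low, "pore_table"), inherits(pores_high, "pore_table"))
  ps <- attr(pores_low, "pixel_size")
  if (is.null(max_centroid_dist)) max_centroid_dist <- 3 * ps
  nl <- nrow(pores_low); nh <- nrow(pores_high)
  pairs <- data.frame(id_low = integer(0), id_high = integer(0),
                      dist_nm = numeric(0), diameter_low_nm = numeric(0),
                      diameter_high_nm = numeric(0), fold_change = numeric(0))
  if (nl > 0 && nh > 0) {
    dmat <- sqrt(outer(pores_low$x_nm, pores_high$x_nm, "-")^2 +
                 outer(pores_low$y_nm, pores_high$y_nm, "-")^2)
    cand <- which(dmat <= max_centroid_dist, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_l <- logical(nl); used_h <- logical(nh)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_l[i] || used_h[j]) next
        used_l[i] <- TRUE; used_h[j] <- TRUE
        pairs <- rbind(pairs, data.frame(
          id_low = pores_low$pore_id[i], id_high = pores_high$pore_id[j],
          dist_nm = dmat[i, j],
          diameter_low_nm = pores_low$diameter_fast_axis_nm[i],
          diameter_high_nm = pores_high$diameter_fast_axis_nm[j],
          fold_change = pores_high$diameter_fast_axis_nm[j] /
            pores_low$diameter_fast_axis_nm[i]))
      }
    }
  }
  structure(list(pairs = pairs,
                 unmatched_low = setdiff(pores_low$pore_id, pairs$id_low),
                 unmatched_high = setdiff(pores_high$pore_id, pairs$id_high),
                 force_low = attr(pores_low, "load_force"),
                 force_high = attr(pores_high, "load_force"),
                 max_centroid_dist_nm = max_centroid_dist),
            class = "pore_matching")
}

#' Summarize fenestration deformability
#'
#' Per-pair fold change (high-force diameter over low-force diameter),
#' summarized as mean, SD, and percent enlargement `(mean - 1) * 100`.
#'
#' @param matching A `pore_matching` from [match_pores()], or a numeric
#'   vector of fold changes.
#' @return A list of class `deformability_summary`: `n_pairs`, `mean_fold`,
#'   `sd_fold`, `percent_enlargement`.
#' @export
deformability_summary <- function(matching) {
  folds <- if (inherits(matching, "pore_matching")) matching$pairs$fold_change
           else as.numeric(matching)
  if (length(folds) == 0L) stop("no matched pore pairs to summarize", call. = FALSE)
  structure(list(n_pairs = length(folds), mean_fold = mean(folds),
                 sd_fold = if (length(folds) > 1) stats::sd(folds) else 0,
                 percent_enlargement = (mean(folds) - 1) * 100),
            class = "deformability_summary")
}

#' @export
print.deformability_summary <- function(x, ...) {
  cat(sprintf("<deformability> mean fold %.3g +/- %.2g (n = %d pairs), enlargement %.1f%%\n",
              x$mean_fold, x$sd_fold, x$n_pairs, x$percent_enlargement))
  invisible(x)
}
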