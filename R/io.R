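# On-disk interchange formats. Force-volume maps use a plain directory
# container (JSON metadata + CSV arrays) that is portable and diff-able;
# height maps and masks are written as 32-bit TIFF with a JSON sidecar
# recording the physical scale, since baseline TIFF stores normalized
# values.

#' Write a force-volume map to a directory container
#'
#' Layout: `metadata.json` (grid size, pixel size in nm, spring constant in
#' N/m, fast axis, scan direction), `z.csv` (common z grid, nm), and
#' `force.csv` (one row per pixel: `px_y`, `px_x`, then the force samples in
#' pN).
#'
#' @param fvmap A `force_volume` object.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_force_volume <- function(fvmap, dir) {
  stopifnot(inherits(fvmap, "force_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(fvmap$force)
  meta <- list(ny = d[1], nx = d[2], n_samples = d[3],
               pixel_size_nm = fvmap$pixel_size,
               spring_constant_N_per_m = fvmap$spring_constant,
               fast_axis = fvmap$fast_axis, direction = fvmap$direction,
               force_unit = "pN", z_unit = "nm")
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(z_nm = fvmap$z), file.path(dir, "z.csv"),
                   row.names = FALSE)
  M <- fvmap$force
  dim(M) <- c(d[1] * d[2], d[3])
  px <- expand.grid(px_y = seq_len(d[1]), px_x = seq_len(d[2]))
  utils::write.csv(cbind(px, as.data.frame(M)), file.path(dir, "force.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a force-volume map from a directory container
#'
#' @param dir Directory written by [write_force_volume()].
#' @return A `force_volume` object.
#' @export
read_force_volume <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  z <- utils::read.csv(file.path(dir, "z.csv"))$z_nm
  tab <- utils::read.csv(file.path(dir, "force.csv"))
  M <- as.matrix(tab[, -(1:2), drop = FALSE])
  ord <- order(tab$px_x, tab$px_y)
  M <- M[ord, , drop = FALSE]
  dimnames(M) <- NULL
  structure(list(force = array(M, dim = c(meta$ny, meta$nx, meta$n_samples)),
                 z = z, pixel_size = meta$pixel_size_nm,
                 spring_constant = meta$spring_constant_N_per_m,
                 fast_axis = meta$fast_axis, direction = meta$direction),
            class = "force_volume")
}

#' Write a height map as 32-bit TIFF with a JSON sidecar
#'
#' Heights are normalized to `[0, 1]` for storage (baseline TIFF encodes
#' normalized samples); the sidecar `<path>.json` records the offset and
#' scale in nm, the load force and the pixel size. When the map contains
#' invalid pixels, their mask is written alongside as `<path>.mask.tif`.
#'
#' @param map A [height_map()].
#' @param path Output `.tif` path.
#' @return The path, invisibly.
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  h <- map$heights
  v <- map$valid_mask & !is.na(h)
  rng <- if (any(v)) range(h[v]) else c(0, 1)
  scale <- max(rng[2] - rng[1], 1e-12)
  sc <- (h - rng[1]) / scale
  sc[!v] <- 0
  sc <- clamp(sc, 0, 1)
  tiff::writeTIFF(sc, path, bits.per.sample = 32L)
  has_invalid <- !all(v)
  if (has_invalid) write_mask(v, paste0(path, ".mask.tif"))
  jsonlite::write_json(
    list(offset_nm = rng[1], scale_nm = scale, load_force_pN = map$load_force,
         pixel_size_nm = map$pixel_size, fast_axis = map$fast_axis,
         valid_mask_file = if (has_invalid) basename(paste0(path, ".mask.tif"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a height map written by [write_height_map()]
#'
#' @param path `.tif` path with its `.json` sidecar alongside.
#' @return A [height_map()].
#' @export
read_height_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sc <- tiff::readTIFF(path)
  if (length(dim(sc)) == 3L) sc <- sc[, , 1]
  h <- sc * meta$scale_nm + meta$offset_nm
  v <- if (!is.null(meta$valid_mask_file)) {
    read_mask(file.path(dirname(path), meta$valid_mask_file))
  } else {
    matrix(TRUE, nrow(h), ncol(h))
  }
  h[!v] <- NA_real_
  height_map(h, v, meta$pixel_size_nm, meta$load_force_pN, meta$fast_axis)
}

#' Write a logical mask as 1-bit-style TIFF
#'
#' @param mask Logical matrix.
#' @param path Output `.tif` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a logical mask written by [write_mask()]
#'
#' @param path `.tif` path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Read a single-channel intensity image from TIFF
#'
#' Multi-channel images are reduced to their first channel.
#'
#' @param path `.tif` path.
#' @return Numeric matrix.
#' @export
read_intensity_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write phantom ground truth to a directory
#'
#' The pore table, porosity, enlargement and spec go to `truth.json`; the
#' height and modulus maps and the cell/nuclear masks are written as TIFF
#' (+sidecar) alongside.
#'
#' @param truth A `ground_truth` object.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(pore_table = truth$pore_table, cell_area_um2 = truth$cell_area_um2,
         true_porosity = truth$true_porosity,
         true_enlargement = truth$true_enlargement,
         n_rejected = truth$n_rejected, spec = unclass(truth$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  ps <- truth$spec$pixel_size
  write_height_map(height_map(truth$height_map, pixel_size = ps, load_force = 1),
                   file.path(dir, "true_height.tif"))
  write_height_map(height_map(truth$modulus_map, pixel_size = ps, load_force = 1),
                   file.path(dir, "true_modulus.tif"))
  write_mask(truth$cell_mask, file.path(dir, "cell_mask.tif"))
  write_mask(truth$nuclear_mask, file.path(dir, "nuclear_mask.tif"))
  invisible(dir)
}
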