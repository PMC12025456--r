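# Quantitative-imaging topography reconstruction: rebuild a height map at a
# chosen load force from a force-volume map.

#' Construct a height map
#'
#' @param heights Numeric matrix of heights in nm (`NA` where invalid).
#' @param valid_mask Logical matrix marking pixels with a usable height.
#' @param pixel_size Pixel size in nm.
#' @param load_force Load force (pN) the map was reconstructed at.
#' @param fast_axis Fast scan axis, `"x"` (matrix columns) or `"y"`.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, valid_mask = NULL, pixel_size, load_force,
                       fast_axis = "x") {
  stopifnot(is.matrix(heights))
  if (is.null(valid_mask)) valid_mask <- !is.na(heights)
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(heights)))
  check_num(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_num(load_force, "load_force", lower = 0, strict_lower = TRUE)
  heights[!valid_mask] <- NA_real_
  structure(list(heights = heights, valid_mask = valid_mask,
                 pixel_size = pixel_size, load_force = load_force,
                 fast_axis = fast_axis),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px @ %g nm, load %g pN, %.1f%% valid\n",
              ncol(x$heights), nrow(x$heights), x$pixel_size, x$load_force,
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Reconstruct topography at a chosen load force
#'
#' For every pixel, finds the first crossing of `F_target` on the approach
#' curve that persists for two consecutive samples, interpolates the piezo
#' position linearly between the bracketing samples, and reports the
#' deflection-corrected tip position `-(z_cross - F_target / k)` so that
#' rigid and compliant pixels are directly comparable: at a fixed pixel the
#' reported height can only decrease as the load increases (deeper
#' indentation at higher load). Pixels whose curve never reaches `F_target`
#' are marked invalid; a warning is emitted when more than half the map is
#' invalid.
#'
#' @param fvmap A `force_volume` object.
#' @param F_target Load force in pN (> 0).
#' @return A [height_map()] (heights in nm, relative to an arbitrary common
#'   offset; use [flatten_map()] to reference them to the substrate).
#' @export
reconstruct_height_at_force <- function(fvmap, F_target) {
  stopifnot(inherits(fvmap, "force_volume"))
  check_num(F_target, "F_target", lower = 0, strict_lower = TRUE)
  d <- dim(fvmap$force)
  ny <- d[1]; nx <- d[2]; ns <- d[3]
  z <- fvmap$z
  M <- fvmap$force
  dim(M) <- c(ny * nx, ns)
  # persistent crossing: above target at sample i and i+1
  above <- M >= F_target
  B <- above[, -ns, drop = FALSE] & above[, -1, drop = FALSE]
  has <- rowSums(B) > 0
  idx <- max.col(B * 1, ties.method = "first")  # first TRUE column where any
  z_cross <- rep(NA_real_, ny * nx)
  if (any(has)) {
    i <- idx[has]
    f_hi <- M[cbind(which(has), i)]
    lo_i <- pmax(i - 1L, 1L)
    f_lo <- M[cbind(which(has), lo_i)]
    z_hi <- z[i]
    z_lo <- z[lo_i]
    t <- ifelse(f_hi > f_lo, (F_target - f_lo) / (f_hi - f_lo), 1)
    t <- clamp(t, 0, 1)
    z_cross[has] <- z_lo + t * (z_hi - z_lo)
  }
  k_pn <- k_pn_per_nm(fvmap$spring_constant)
  h <- -(z_cross - F_target / k_pn)
  hm <- matrix(h, ny, nx)
  vm <- matrix(has, ny, nx)
  if (mean(vm) < 0.5) {
    warning(sprintf("reconstruction at %g pN: %.0f%% of pixels never reach the target force",
                    F_target, 100 * (1 - mean(vm))), call. = FALSE)
  }
  height_map(hm, vm, fvmap$pixel_size, F_target, fvmap$fast_axis)
}

#' Reconstruct a stack of height maps at several load forces
#'
#' One reconstruction per target force from the same scan; deterministic.
#'
#' @param fvmap A `force_volume` object.
#' @param targets Positive load forces in pN, sorted ascending.
#' @return A named list of [height_map()]s (names are the forces in pN).
#' @export
reconstruct_stack <- function(fvmap, targets) {
  if (length(targets) == 0L) stop_field("targets", "must contain at least one force")
  if (any(targets <= 0)) stop_field("targets", "must be positive")
  if (is.unsorted(targets)) stop_field("targets", "must be sorted ascending")
  out <- lapply(targets, function(Ft) reconstruct_height_at_force(fvmap, Ft))
  names(out) <- as.character(targets)
  out
}
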