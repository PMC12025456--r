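# Synthetic force-volume phantoms of fenestrated cells on soft substrates,
# plus amplitude-sweep, nuclei-image and endocytosis-table generators.
# Every generator records its ground truth so downstream stages can be
# validated by parameter recovery.

#' Specify a force-volume phantom
#'
#' Describes a fenestrated cell resting on a flat substrate: an elliptical
#' cell body of height `cell_height` with a central nuclear bulge, sieve
#' plates (clusters of transcellular pores) in the peripheral cytoplasm, and
#' per-pixel Hertzian approach curves with additive Gaussian force noise.
#'
#' Pores are modelled as depressions through the cell body down to the
#' substrate. Each pore has an inner (patent) radius and an annular rim over
#' which the contact height rises from the substrate back to the cell
#' surface following a power profile `h(r) = H ((r - r0)/w)^rim_profile_exponent`
#' with rim width `w = rim_compliance * r0`. Because the soft cell body
#' indents more than the stiffer substrate at a given load, the half-depth
#' crossing of the reconstructed (load-dependent) surface moves outward with
#' load, so the apparent pore diameter grows with the imaging force; wider
#' rims (larger `rim_compliance`) grow more. The per-pore apparent diameter
#' at load F has the closed form
#' `d(F) = 2 r0 (1 + rim_compliance * u(F)^(1/p))` with
#' `u(F) = (1 + (delta_cell(F) - delta_substrate(F)) / cell_height) / 2`
#' clamped to `[0, 1]`, which the generator records as ground truth.
#'
#' @param grid_nx,grid_ny Map size in pixels.
#' @param pixel_size Pixel size in nm.
#' @param curve_n_samples Samples per force curve.
#' @param z_range Piezo range per curve in nm; must exceed the total feature
#'   height plus the deepest simulated indentation.
#' @param substrate_modulus,cell_modulus Young's moduli in Pa. The pore-
#'   enlargement model assumes the substrate is stiffer than the cell (the
#'   regime of cells on stiff gels or glass).
#' @param cell_height Peripheral cell body height in nm.
#' @param nucleus_height,nucleus_radius Height (nm) and radius (nm) of the
#'   parabolic nuclear bulge; set both to 0 for a nucleus-free sieve-plate
#'   phantom.
#' @param n_sieve_plates Number of sieve plates placed around the nucleus.
#' @param pores_per_plate Pores attempted per plate (overlapping placements
#'   are rejected).
#' @param pore_diameter_mean,pore_diameter_sd Mean and SD (nm) of the
#'   truncated-normal pore diameter distribution, defined as the apparent
#'   (half-depth) diameter at the reference load `pore_reference_force`.
#' @param pore_diameter_min,pore_diameter_max Truncation range in nm; the
#'   physiological fenestration range 50-350 nm by default.
#' @param rim_compliance Dimensionless rim width factor (>= 0); 0 gives
#'   rigid, load-independent pores.
#' @param rim_profile_exponent Exponent of the rim height profile (0, 1];
#'   values below 1 give a funnel-shaped rim whose apparent diameter is more
#'   sensitive to load.
#' @param pore_reference_force Load (pN) at which drawn pore diameters are
#'   defined.
#' @param nuclear_pores Number of fenestration-like (non-transcellular)
#'   depressions placed over the nuclear bulge ("fenestrae labyrinth");
#'   excluded from true porosity.
#' @param tip_radius Imaging tip radius in nm.
#' @param poisson_ratio Sample Poisson ratio.
#' @param spring_constant Cantilever spring constant in N/m.
#' @param force_noise_sd Additive Gaussian force noise SD in pN.
#' @param seed Integer RNG seed; identical specs generate identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_nx = 64L, grid_ny = 64L, pixel_size = 100,
                         curve_n_samples = 256L, z_range = 3000,
                         substrate_modulus = 52000, cell_modulus = 6000,
                         cell_height = 300, nucleus_height = 1200,
                         nucleus_radius = 1200,
                         n_sieve_plates = 12L, pores_per_plate = 3L,
                         pore_diameter_mean = 200, pore_diameter_sd = 60,
                         pore_diameter_min = 50, pore_diameter_max = 350,
                         rim_compliance = 1, rim_profile_exponent = 0.2,
                         pore_reference_force = 170,
                         nuclear_pores = 0L,
                         tip_radius = 25, poisson_ratio = 0.5,
                         spring_constant = 0.1, force_noise_sd = 20,
                         seed = 42L) {
  spec <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
               pixel_size = pixel_size, curve_n_samples = as.integer(curve_n_samples),
               z_range = z_range, substrate_modulus = substrate_modulus,
               cell_modulus = cell_modulus, cell_height = cell_height,
               nucleus_height = nucleus_height, nucleus_radius = nucleus_radius,
               n_sieve_plates = as.integer(n_sieve_plates),
               pores_per_plate = as.integer(pores_per_plate),
               pore_diameter_mean = pore_diameter_mean,
               pore_diameter_sd = pore_diameter_sd,
               pore_diameter_min = pore_diameter_min,
               pore_diameter_max = pore_diameter_max,
               rim_compliance = rim_compliance,
               rim_profile_exponent = rim_profile_exponent,
               pore_reference_force = pore_reference_force,
               nuclear_pores = as.integer(nuclear_pores),
               tip_radius = tip_radius, poisson_ratio = poisson_ratio,
               spring_constant = spring_constant,
               force_noise_sd = force_noise_sd, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  check_num(spec$grid_nx, "grid_nx", lower = 8)
  check_num(spec$grid_ny, "grid_ny", lower = 8)
  check_num(spec$pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_num(spec$curve_n_samples, "curve_n_samples", lower = 32)
  check_num(spec$substrate_modulus, "substrate_modulus", lower = 0, strict_lower = TRUE)
  check_num(spec$cell_modulus, "cell_modulus", lower = 0, strict_lower = TRUE)
  check_num(spec$poisson_ratio, "poisson_ratio", lower = 0, upper = 0.5)
  check_num(spec$cell_height, "cell_height", lower = 0)
  check_num(spec$nucleus_height, "nucleus_height", lower = 0)
  check_num(spec$nucleus_radius, "nucleus_radius", lower = 0)
  check_num(spec$n_sieve_plates, "n_sieve_plates", lower = 0)
  check_num(spec$pores_per_plate, "pores_per_plate", lower = 0)
  check_num(spec$nuclear_pores, "nuclear_pores", lower = 0)
  check_num(spec$pore_diameter_min, "pore_diameter_min", lower = 0)
  if (spec$pore_diameter_max < spec$pore_diameter_min) {
    stop_field("pore_diameter_max", "must be >= pore_diameter_min")
  }
  check_num(spec$pore_diameter_sd, "pore_diameter_sd", lower = 0)
  check_num(spec$rim_compliance, "rim_compliance", lower = 0)
  check_num(spec$rim_profile_exponent, "rim_profile_exponent", lower = 0,
            upper = 1, strict_lower = TRUE)
  check_num(spec$tip_radius, "tip_radius", lower = 0, strict_lower = TRUE)
  check_num(spec$spring_constant, "spring_constant", lower = 0, strict_lower = TRUE)
  check_num(spec$force_noise_sd, "force_noise_sd", lower = 0)
  check_num(spec$pore_reference_force, "pore_reference_force", lower = 0,
            strict_lower = TRUE)
  # the piezo range must accommodate the tallest feature, the deepest
  # simulated indentation (~1000 nm) and the pre-contact baseline region
  needed <- spec$cell_height + spec$nucleus_height + 800
  if (spec$z_range <= needed) {
    stop_field("z_range", sprintf(
      "must exceed cell_height + nucleus_height + indentation headroom (> %g nm)",
      needed))
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %dx%d px @ %g nm, cell %g Pa / substrate %g Pa, ",
                     "%d plates x %d pores, noise %g pN, seed %d\n"),
              x$grid_nx, x$grid_ny, x$pixel_size, x$cell_modulus,
              x$substrate_modulus, x$n_sieve_plates, x$pores_per_plate,
              x$force_noise_sd, x$seed))
  invisible(x)
}

# Load-transfer function of the rim model: u(F) in [0, 1]; see ?phantom_spec.
.rim_u <- function(F, spec) {
  if (spec$cell_height <= 0) return(rep(0.5, length(F)))
  dc <- invert_indentation(F, spec$cell_modulus, spec$poisson_ratio, spec$tip_radius)
  ds <- invert_indentation(F, spec$substrate_modulus, spec$poisson_ratio, spec$tip_radius)
  clamp(0.5 * (1 + (dc - ds) / spec$cell_height), 0, 1)
}

#' True (generator) apparent pore diameter at a load force
#'
#' Evaluates the closed-form per-load diameter function of the phantom's rim
#' model for every pore in a ground-truth table.
#'
#' @param truth A `ground_truth` object from [generate_phantom()].
#' @param F Load force in pN.
#' @return Numeric vector of apparent half-depth diameters in nm (one per
#'   pore), non-decreasing in `F` while the rim is engaged.
#' @export
true_pore_diameter <- function(truth, F) {
  stopifnot(inherits(truth, "ground_truth"))
  spec <- truth$spec
  u <- .rim_u(F, spec)^(1 / spec$rim_profile_exponent)
  2 * truth$pore_table$r0_nm * (1 + spec$rim_compliance * u)
}

#' Rim compliance needed for a target deformability fold change
#'
#' Solves the phantom's closed-form diameter model for the `rim_compliance`
#' that makes the true fold change `d(F_high)/d(F_low)` equal `target_fold`.
#'
#' @param spec A [phantom_spec()] (its moduli, tip and rim exponent fix the
#'   attainable range).
#' @param target_fold Target diameter ratio, > 1.
#' @param F_low,F_high The two reconstruction loads in pN.
#' @return The required `rim_compliance`.
#' @export
rim_compliance_for_enlargement <- function(spec, target_fold,
                                           F_low = 170, F_high = 300) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_num(target_fold, "target_fold", lower = 1, strict_lower = TRUE)
  p <- spec$rim_profile_exponent
  ul <- .rim_u(F_low, spec)^(1 / p)
  uh <- .rim_u(F_high, spec)^(1 / p)
  denom <- uh - target_fold * ul
  if (denom <= 0) {
    stop(sprintf(paste0("target fold %.3g exceeds the attainable maximum %.3g ",
                        "for these moduli and rim exponent"),
         target_fold, uh / ul), call. = FALSE)
  }
  (target_fold - 1) / denom
}

# truncated-normal diameters by rejection sampling
.draw_diameters <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(clamp(mean, lo, hi), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:1000) {
      d <- stats::rnorm(1, mean, sd)
      if (d >= lo && d <= hi) break
    }
    out[i] <- clamp(d, lo, hi)
  }
  out
}

#' Generate a force-volume phantom with known ground truth
#'
#' Builds the contact-height and modulus maps described by a
#' [phantom_spec()], then simulates one Hertzian approach curve per pixel:
#' zero force before contact, and after contact the force that solves the
#' force-balance `delta + F(delta)/k = z - z_c` (indentation plus cantilever
#' deflection equals piezo travel past contact), plus additive Gaussian
#' noise. Identical specs (including seed) give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `truth` (class `ground_truth`: true height
#'   and modulus maps, cell and nuclear masks, the pore table with per-pore
#'   rim parameters and true per-load diameters, `true_porosity` in
#'   fenestrations per square micrometre, and `true_enlargement` as the mean
#'   fold change between 170 and 300 pN) and `fvmap` (class `force_volume`:
#'   the simulated curves as an `ny x nx x n_samples` array in pN, the
#'   common z grid in nm, and acquisition metadata).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    nx <- spec$grid_nx; ny <- spec$grid_ny; ps <- spec$pixel_size
    xs <- (seq_len(nx) - 0.5) * ps
    ys <- (seq_len(ny) - 0.5) * ps
    cx <- nx * ps / 2; cy <- ny * ps / 2
    X <- matrix(xs, ny, nx, byrow = TRUE)
    Y <- matrix(ys, ny, nx)

    # elliptical cell body with a parabolic nuclear bulge
    ax <- 0.42 * nx * ps; bx <- 0.42 * ny * ps
    ell <- ((X - cx) / ax)^2 + ((Y - cy) / bx)^2
    cell_mask <- ell <= 1
    H <- matrix(0, ny, nx)
    H[cell_mask] <- spec$cell_height
    Rnuc <- matrix(sqrt((X - cx)^2 + (Y - cy)^2), ny, nx)
    nuclear_mask <- matrix(FALSE, ny, nx)
    if (spec$nucleus_radius > 0 && spec$nucleus_height > 0) {
      nuclear_mask <- cell_mask & (Rnuc <= spec$nucleus_radius)
      bump <- spec$nucleus_height * (1 - (Rnuc / spec$nucleus_radius)^2)
      H[nuclear_mask] <- H[nuclear_mask] + bump[nuclear_mask]
    }
    E <- matrix(spec$substrate_modulus, ny, nx)
    E[cell_mask] <- spec$cell_modulus

    # sieve-plate centres on a ring between nucleus and cell edge
    min_ax <- min(ax, bx)
    gap <- min_ax - spec$nucleus_radius
    plate_radius <- 0.4 * gap
    ring_r <- spec$nucleus_radius + 0.5 * gap
    plates <- NULL
    if (spec$n_sieve_plates > 0 && spec$pores_per_plate > 0) {
      if (gap <= 2 * spec$pore_diameter_max) {
        stop_field("nucleus_radius", "leaves no peripheral cytoplasm for sieve plates")
      }
      ang <- 2 * pi * ((seq_len(spec$n_sieve_plates) - 1) / spec$n_sieve_plates) +
        stats::runif(1, 0, 2 * pi)
      plates <- data.frame(id = seq_len(spec$n_sieve_plates),
                           x = cx + ring_r * cos(ang),
                           y = cy + ring_r * sin(ang))
    }

    # pore placement with overlap rejection
    c_rim <- spec$rim_compliance
    p_exp <- spec$rim_profile_exponent
    u_ref <- .rim_u(spec$pore_reference_force, spec)^(1 / p_exp)
    placed <- list()
    n_rejected <- 0L
    try_place <- function(center_fn, d_ref, plate_id, nuclear) {
      r0 <- (d_ref / 2) / (1 + c_rim * u_ref)
      r_out <- r0 * (1 + c_rim)
      for (try in 1:200) {
        pos <- center_fn(r_out)
        if (is.null(pos)) next
        ok <- TRUE
        for (q in placed) {
          if (sqrt((q$x - pos[1])^2 + (q$y - pos[2])^2) <
              (q$r_out + r_out + ps)) { ok <- FALSE; break }
        }
        if (!ok) next
        placed[[length(placed) + 1L]] <<- list(
          x = pos[1], y = pos[2], r0 = r0, r_out = r_out, d_ref = d_ref,
          plate = plate_id, nuclear = nuclear)
        return(TRUE)
      }
      FALSE
    }
    if (!is.null(plates)) {
      for (pl in seq_len(nrow(plates))) {
        dd <- .draw_diameters(spec$pores_per_plate, spec$pore_diameter_mean,
                              spec$pore_diameter_sd, spec$pore_diameter_min,
                              spec$pore_diameter_max)
        for (d_ref in dd) {
          in_plate <- function(r_out) {
            rr <- (plate_radius - r_out - ps) * sqrt(stats::runif(1))
            if (rr <= 0) return(NULL)
            th <- stats::runif(1, 0, 2 * pi)
            pos <- c(plates$x[pl] + rr * cos(th), plates$y[pl] + rr * sin(th))
            # keep the full pore inside the cell, clear of the nucleus
            if (sqrt((pos[1] - cx)^2 + (pos[2] - cy)^2) <
                spec$nucleus_radius + r_out + ps) return(NULL)
            marg <- (r_out + ps) / min_ax
            if (((pos[1] - cx) / ax)^2 + ((pos[2] - cy) / bx)^2 >
                (1 - marg)^2) return(NULL)
            pos
          }
          if (!try_place(in_plate, d_ref, plates$id[pl], FALSE)) {
            n_rejected <- n_rejected + 1L
          }
        }
      }
    }
    if (spec$nuclear_pores > 0 && spec$nucleus_radius > 0) {
      dd <- .draw_diameters(spec$nuclear_pores, spec$pore_diameter_mean,
                            spec$pore_diameter_sd, spec$pore_diameter_min,
                            spec$pore_diameter_max)
      for (d_ref in dd) {
        in_nucleus <- function(r_out) {
          rr <- (0.7 * spec$nucleus_radius - r_out) * sqrt(stats::runif(1))
          if (rr <= 0) return(NULL)
          th <- stats::runif(1, 0, 2 * pi)
          c(cx + rr * cos(th), cy + rr * sin(th))
        }
        if (!try_place(in_nucleus, d_ref, NA_integer_, TRUE)) {
          n_rejected <- n_rejected + 1L
        }
      }
    }

    # carve pore profiles into the height and modulus maps
    for (q in placed) {
      sel <- which(abs(X - q$x) <= q$r_out + ps & abs(Y - q$y) <= q$r_out + ps)
      d <- sqrt((X[sel] - q$x)^2 + (Y[sel] - q$y)^2)
      inside <- d <= q$r_out
      sel <- sel[inside]; d <- d[inside]
      base <- H[sel]           # local surface before carving
      if (q$nuclear) {
        floor_h <- base - spec$cell_height
        floor_E <- spec$cell_modulus
      } else {
        floor_h <- 0
        floor_E <- spec$substrate_modulus
      }
      w <- q$r_out - q$r0
      frac <- if (w > 0) clamp((d - q$r0) / w, 0, 1) else as.numeric(d > q$r0)
      H[sel] <- floor_h + (base - floor_h) * frac^p_exp
      core <- sel[d <= q$r0]
      if (!q$nuclear) E[core] <- floor_E
    }

    # per-pore ground truth table
    u170 <- .rim_u(170, spec)^(1 / p_exp)
    u300 <- .rim_u(300, spec)^(1 / p_exp)
    if (length(placed)) {
      pt <- do.call(rbind, lapply(placed, function(q) {
        data.frame(x_nm = q$x, y_nm = q$y, r0_nm = q$r0, rim_width_nm = q$r_out - q$r0,
                   diameter_ref_nm = q$d_ref, sieve_plate_id = q$plate,
                   in_nuclear_region = q$nuclear)
      }))
      pt$diameter_170_nm <- 2 * pt$r0_nm * (1 + c_rim * u170)
      pt$diameter_300_nm <- 2 * pt$r0_nm * (1 + c_rim * u300)
      pt$fold_change <- pt$diameter_300_nm / pt$diameter_170_nm
    } else {
      pt <- data.frame(x_nm = numeric(0), y_nm = numeric(0), r0_nm = numeric(0),
                       rim_width_nm = numeric(0), diameter_ref_nm = numeric(0),
                       sieve_plate_id = integer(0),
                       in_nuclear_region = logical(0),
                       diameter_170_nm = numeric(0), diameter_300_nm = numeric(0),
                       fold_change = numeric(0))
    }
    cell_area_um2 <- sum(cell_mask) * ps^2 / 1e6
    n_fen <- sum(!pt$in_nuclear_region)
    truth <- structure(list(
      height_map = H, modulus_map = E, cell_mask = cell_mask,
      nuclear_mask = nuclear_mask, pore_table = pt,
      sieve_plates = plates,
      cell_area_um2 = cell_area_um2,
      true_porosity = if (cell_area_um2 > 0) n_fen / cell_area_um2 else 0,
      true_enlargement = if (n_fen > 0) mean(pt$fold_change[!pt$in_nuclear_region]) else NA_real_,
      n_rejected = n_rejected, spec = spec), class = "ground_truth")

    # simulate the curves: force balance delta + F(delta)/k = z - z_c
    ns <- spec$curve_n_samples
    z <- seq(0, spec$z_range, length.out = ns)
    dz <- z[2] - z[1]
    H_max <- max(H)
    z_off <- max(0.1 * spec$z_range, 6 * dz)
    z_c <- z_off + (H_max - as.vector(H))       # per pixel, column-major
    npix <- nx * ny
    k_pn <- k_pn_per_nm(spec$spring_constant)
    cf <- .contact_coef(indenter_model("sphere", tip_radius = spec$tip_radius,
                                       poisson_ratio = spec$poisson_ratio))
    A <- cf$C * as.vector(E)                    # F = A * delta^1.5, pN
    S <- matrix(z, npix, ns, byrow = TRUE) - z_c
    S[S < 0] <- 0
    delta <- S
    for (it in 1:12) {
      g <- delta + (A * delta^1.5) / k_pn - S
      gp <- 1 + 1.5 * (A * sqrt(delta)) / k_pn
      delta <- pmax(delta - g / gp, 0)
    }
    Fm <- A * delta^1.5
    if (spec$force_noise_sd > 0) {
      Fm <- Fm + matrix(stats::rnorm(npix * ns, 0, spec$force_noise_sd), npix, ns)
    }
    fv <- structure(list(
      force = array(Fm, dim = c(ny, nx, ns)), z = z,
      pixel_size = ps, spring_constant = spec$spring_constant,
      fast_axis = "x", direction = "approach",
      contact_z = matrix(z_c, ny, nx)), class = "force_volume")
    list(truth = truth, fvmap = fv)
  })
}

#' @export
print.force_volume <- function(x, ...) {
  d <- dim(x$force)
  cat(sprintf("<force_volume> %d x %d px @ %g nm, %d samples/curve, k = %g N/m\n",
              d[2], d[1], x$pixel_size, d[3], x$spring_constant))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> %d pores (%d nuclear), porosity %.3g fen./um^2, ",
                     "mean 300/170 pN fold %.3g\n"),
              nrow(x$pore_table), sum(x$pore_table$in_nuclear_region),
              x$true_porosity, x$true_enlargement))
  invisible(x)
}

#' Generate a synthetic amplitude sweep
#'
#' Storage modulus: a plateau below `yield_strain`, then power-law decay
#' `G'(gamma) = plateau (gamma/yield_strain)^(-decay_exponent)`. The loss
#' modulus follows the same shape scaled by `loss_factor`. Multiplicative
#' Gaussian noise of relative SD `noise_rel` is applied independently to
#' both moduli.
#'
#' @param plateau_G_prime Plateau storage modulus in Pa.
#' @param loss_factor Ratio G''/G' of the noiseless sweep.
#' @param yield_strain Yield strain in percent.
#' @param decay_exponent Power-law decay exponent past yield (> 0).
#' @param strain_grid Strain values in percent, positive increasing;
#'   defaults to 40 log-spaced points over 0.01-100 %.
#' @param noise_rel Relative multiplicative noise SD.
#' @param seed Optional RNG seed.
#' @return An [amplitude_sweep()] object.
#' @export
generate_amplitude_sweep <- function(plateau_G_prime, loss_factor = 0.1,
                                     yield_strain = 1, decay_exponent = 1,
                                     strain_grid = NULL, noise_rel = 0,
                                     seed = NULL) {
  check_num(plateau_G_prime, "plateau_G_prime", lower = 0, strict_lower = TRUE)
  check_num(loss_factor, "loss_factor", lower = 0, strict_lower = TRUE)
  check_num(yield_strain, "yield_strain", lower = 0, strict_lower = TRUE)
  check_num(decay_exponent, "decay_exponent", lower = 0, strict_lower = TRUE)
  check_num(noise_rel, "noise_rel", lower = 0)
  if (is.null(strain_grid)) strain_grid <- 10^seq(-2, 2, length.out = 40)
  if (length(strain_grid) == 0L) stop_field("strain_grid", "must not be empty")
  if (any(strain_grid <= 0) || any(diff(strain_grid) <= 0)) {
    stop_field("strain_grid", "must be positive and increasing")
  }
  with_seed(seed, {
    shape <- ifelse(strain_grid <= yield_strain, 1,
                    (strain_grid / yield_strain)^(-decay_exponent))
    gp <- plateau_G_prime * shape
    gpp <- loss_factor * plateau_G_prime * shape
    if (noise_rel > 0) {
      gp <- gp * pmax(1 + stats::rnorm(length(gp), 0, noise_rel), 0.01)
      gpp <- gpp * pmax(1 + stats::rnorm(length(gpp), 0, noise_rel), 0.01)
    }
    amplitude_sweep(strain_grid, gp, gpp)
  })
}

#' Generate a synthetic nuclei image
#'
#' Places `n_nuclei` non-overlapping bright discs on a dark background by
#' rejection sampling, then adds Gaussian noise. Intended for validating
#' threshold-based nuclei counting.
#'
#' @param n_nuclei Number of nuclei.
#' @param image_size Image side length in pixels (square image).
#' @param nucleus_radius_px Disc radius in pixels.
#' @param intensity Disc intensity above background.
#' @param background Background level.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Optional RNG seed.
#' @return A list with `image` (matrix), `true_count`, and `centers`.
#' @export
generate_nuclei_image <- function(n_nuclei, image_size = 256L,
                                  nucleus_radius_px = 6, intensity = 200,
                                  background = 20, noise_sd = 5, seed = NULL) {
  check_num(n_nuclei, "n_nuclei", lower = 0)
  check_num(image_size, "image_size", lower = 16)
  check_num(nucleus_radius_px, "nucleus_radius_px", lower = 1)
  with_seed(seed, {
    img <- matrix(background, image_size, image_size)
    centers <- matrix(numeric(0), 0, 2)
    r <- nucleus_radius_px
    max_tries <- max(500L, 500L * n_nuclei)
    tries <- 0L
    while (nrow(centers) < n_nuclei) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(paste0("could not place %d non-overlapping nuclei in a %d px image; ",
                            "reduce n_nuclei or nucleus_radius_px"),
                     n_nuclei, image_size), call. = FALSE)
      }
      cand <- stats::runif(2, r + 1, image_size - r)
      if (nrow(centers) > 0 &&
          any((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 <
              (2 * r + 2)^2)) next
      centers <- rbind(centers, cand)
    }
    if (n_nuclei > 0) {
      ii <- matrix(seq_len(image_size), image_size, image_size)
      jj <- t(ii)
      for (i in seq_len(nrow(centers))) {
        disc <- (ii - centers[i, 1])^2 + (jj - centers[i, 2])^2 <= r^2
        img[disc] <- img[disc] + intensity
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          image_size, image_size)
    }
    list(image = img, true_count = as.integer(n_nuclei), centers = centers)
  })
}

#' Generate a synthetic per-well endocytosis table
#'
#' Emulates a radiolabeled-ligand uptake experiment: per-well cell-associated
#' and degraded activities plus a cell count, the layout being wells =
#' bioreplicates x technical replicates (six wells for three bioreplicates
#' with two technical replicates each).
#'
#' @param n_wells Number of wells.
#' @param cells_per_well Cell count per well (> 0).
#' @param cell_associated_mean,degraded_mean Mean activities per well
#'   (arbitrary units).
#' @param noise Relative Gaussian noise SD applied to both activities.
#' @param substrate_label Label recorded for every well.
#' @param seed Optional RNG seed.
#' @return A data.frame with columns `well`, `substrate_label`,
#'   `cell_associated`, `degraded`, `n_cells`.
#' @export
generate_endocytosis_table <- function(n_wells = 6L, cells_per_well,
                                       cell_associated_mean, degraded_mean,
                                       noise = 0, substrate_label = "substrate",
                                       seed = NULL) {
  check_num(n_wells, "n_wells", lower = 1)
  check_num(cells_per_well, "cells_per_well", lower = 0, strict_lower = TRUE)
  check_num(cell_associated_mean, "cell_associated_mean", lower = 0)
  check_num(degraded_mean, "degraded_mean", lower = 0)
  check_num(noise, "noise", lower = 0)
  with_seed(seed, {
    mult <- function(mu) {
      if (noise > 0) mu * pmax(1 + stats::rnorm(n_wells, 0, noise), 0) else rep(mu, n_wells)
    }
    data.frame(well = seq_len(n_wells), substrate_label = substrate_label,
               cell_associated = mult(cell_associated_mean),
               degraded = mult(degraded_mean),
               n_cells = rep(as.integer(round(cells_per_well)), n_wells))
  })
}
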