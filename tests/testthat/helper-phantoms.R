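# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default study phantom (64x64 @ 100 nm, 20 pN noise)
default_sim <- function() cached("default_sim", generate_phantom(phantom_spec()))

# the same geometry without noise
noiseless_sim <- function() {
  cached("noiseless_sim", generate_phantom(phantom_spec(force_noise_sd = 0)))
}

# homogeneous stiff phantom: flat cell-free surface topography but full
# geometry, used for truth-comparison of reconstructions
stiff_sim <- function() {
  cached("stiff_sim", generate_phantom(phantom_spec(
    substrate_modulus = 60000, cell_modulus = 60000, force_noise_sd = 0,
    curve_n_samples = 512L)))
}

# sieve-plate phantom at the deformability imaging scale (27 nm pixels,
# no nucleus), rim tuned to a 40 % enlargement between 170 and 300 pN
deformability_spec <- function(seed = 1L) {
  base <- phantom_spec(grid_nx = 128L, grid_ny = 128L, pixel_size = 27,
                       nucleus_height = 0, nucleus_radius = 0,
                       n_sieve_plates = 4L, pores_per_plate = 3L, seed = seed)
  rc <- rim_compliance_for_enlargement(base, 1.4)
  phantom_spec(grid_nx = 128L, grid_ny = 128L, pixel_size = 27,
               nucleus_height = 0, nucleus_radius = 0,
               n_sieve_plates = 4L, pores_per_plate = 3L,
               rim_compliance = rc, seed = seed)
}

# porosity phantom at the porosity imaging scale (83 nm pixels);
# control-like ~1.5 fen./um^2 with 18 plates, KO-like ~0.35 with 4
porosity_spec <- function(seed, n_plates) {
  phantom_spec(grid_nx = 96L, grid_ny = 96L, pixel_size = 83,
               n_sieve_plates = n_plates, pores_per_plate = 3L, seed = seed)
}

# full morphometry chain on one phantom: porosity at the low force and the
# matched deformability between the two forces
analyze_phantom_morphometry <- function(sim, targets = c(170, 300),
                                        bulge_threshold = 300) {
  st <- reconstruct_stack(sim$fvmap, targets)
  fl <- lapply(st, flatten_map)
  seg <- segment_cell(fl[[1]])
  nuc <- detect_nuclear_region(fl[[1]], bulge_threshold = bulge_threshold)
  pores <- lapply(fl, detect_pores, cell_mask = seg$mask, nuclear_mask = nuc)
  out <- list(flat = fl, seg = seg, nuc = nuc, pores = pores,
              porosity = compute_porosity(pores[[1]], seg$mask, nuc,
                                          sim$fvmap$pixel_size))
  if (length(targets) >= 2) {
    out$matching <- match_pores(pores[[1]], pores[[length(pores)]])
  }
  out
}

# synthetic noiseless curve with negligible cantilever deflection (stiff
# cantilever), used as an independent round-trip oracle for fitting
make_hertz_curve <- function(E, model, z_c = 500, z_max = 2000, n = 256,
                             k = 1000) {
  z <- seq(0, z_max, length.out = n)
  delta <- pmax(z - z_c, 0)
  f <- if (model$kind == "sphere") {
    hertz_force_sphere(delta, E, model$poisson_ratio, model$tip_radius)
  } else {
    sneddon_force_pyramid(delta, E, model$poisson_ratio, model$half_angle)
  }
  force_curve(z, f, spring_constant = k)
}
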