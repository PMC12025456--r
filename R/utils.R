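# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, lower = -Inf, upper = Inf, len = 1L,
                      strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_field(field, sprintf("must be a numeric of length %d", len))
  }
  if (strict_lower && any(x <= lower)) {
    stop_field(field, sprintf("must be > %g", lower))
  }
  if (!strict_lower && any(x < lower)) {
    stop_field(field, sprintf("must be >= %g", lower))
  }
  if (strict_upper && any(x >= upper)) {
    stop_field(field, sprintf("must be < %g", upper))
  }
  if (!strict_upper && any(x > upper)) {
    stop_field(field, sprintf("must be <= %g", upper))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# spring constant N/m -> pN/nm
k_pn_per_nm <- function(spring_constant) spring_constant * 1000

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
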