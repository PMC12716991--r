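# Internal helpers: seeded RNG scope, unit conversion, argument checks.

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# mN/m <-> N/m, um <-> m. Mechanics are computed in SI and reported in
# bench units; keeping the conversions in one place avoids silent 1e3/1e6
# slips.
mN_per_m_to_si <- function(gamma_mN_per_m) gamma_mN_per_m * 1e-3
si_to_mN_per_m <- function(gamma_N_per_m) gamma_N_per_m * 1e3
um_to_m <- function(x_um) x_um * 1e-6
m_to_um <- function(x_m) x_m * 1e6

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

# Largest-remainder apportionment of n into round(n * fractions) such that
# the parts sum exactly to n. Deterministic: ties in the fractional parts are
# broken by position.
largest_remainder <- function(n, fractions) {
  base <- floor(n * fractions)
  frac <- n * fractions - base
  short <- n - sum(base)
  if (short > 0) {
    take <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1L
  }
  as.integer(base)
}
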