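# Internal helpers.

# Run code with a local RNG state: seeds reproducibly without disturbing the
# caller's random stream. All randomness in the package flows through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Cumulative trapezoidal integral on a uniform grid with step dt.
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  c(0, cumsum(dt * (y[-n] + y[-1L]) / 2))
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
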