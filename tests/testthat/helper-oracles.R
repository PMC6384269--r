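# Independent oracles used to cross-check the implementation paths.

# Stiff-ODE oracle for the irreversible two-tissue compartment model:
# integrates with deSolve::lsoda on a 0.001-min grid and averages the total
# tissue signal over each frame. Shares no code with simulate_tissue_tac().
ode_tac_oracle <- function(ipf, params, schedule, dt = 0.001) {
  cpf <- stats::approxfun(ipf$sample_times, ipf$sample_values, rule = 2)
  a <- params$k2 + params$k3
  deriv <- function(t, y, p) {
    list(c(params$K1 * cpf(t) - a * y[1L], params$k3 * y[1L]))
  }
  times <- seq(0, schedule_duration(schedule), by = dt)
  sol <- deSolve::lsoda(c(C1 = 0, C2 = 0), times, deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-12)
  total <- params$vb * cpf(times) + (1 - params$vb) * (sol[, 2L] + sol[, 3L])
  cum <- c(0, cumsum(dt * (total[-length(total)] + total[-1L]) / 2))
  cum_at <- stats::approxfun(times, cum)
  (cum_at(schedule$end) - cum_at(schedule$start)) / schedule$dur
}

# Brute-force per-label accumulation for regional means.
regional_means_oracle <- function(image, labels, ids) {
  vapply(ids, function(id) {
    vals <- c()
    for (i in seq_along(labels))
      if (!is.na(labels[i]) && labels[i] == id && !is.na(image[i]))
        vals <- c(vals, image[i])
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1L))
}

# Exhaustive-threshold BH oracle: try every observed p-value as the rejection
# threshold and keep the largest one satisfying the step-up condition.
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= q * seq_len(m) / m)
  thr <- if (length(ok) == 0L) -Inf else ps[max(ok)]
  p <= thr
}
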