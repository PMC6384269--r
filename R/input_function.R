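# Analytic plasma input functions and the input-curve operations that feed
# Patlak analysis: linear interpolation, trapezoidal integration and the
# normalized-time transform.

#' Parameters of an analytic tri-exponential plasma input function
#'
#' A Feng-type arterial input model: a linear upslope term damped by the
#' fastest exponential plus two slower washout exponentials,
#' `Cp(t) = (A1*t - A2 - A3) * exp(-l1*t) + A2 * exp(-l2*t) + A3 * exp(-l3*t)`.
#' The form forces `Cp(0) = 0`, rises to a single peak and decays to zero.
#' `A1` is solved numerically so the peak equals `peak_amplitude`; the
#' resulting peak time is stored as a derived diagnostic.
#'
#' @param peak_amplitude Peak plasma activity, kBq/mL.
#' @param decay_rates Three positive exponential rate constants (1/min); the
#'   largest damps the upslope term.
#' @param mixing_coefficients Two non-negative amplitudes (kBq/mL) for the
#'   slower exponentials.
#' @return An object of class `input_function_params` with fields
#'   `peak_time`, `peak_amplitude`, `decay_rates`, `mixing_coefficients` and
#'   the internal amplitudes `A`.
#' @export
input_function_params <- function(peak_amplitude = 100,
                                  decay_rates = c(4, 0.5, 0.01),
                                  mixing_coefficients = c(20, 10)) {
  if (length(decay_rates) != 3L || any(decay_rates <= 0))
    stop("decay_rates must be three positive rate constants (1/min)")
  if (length(mixing_coefficients) != 2L || any(mixing_coefficients < 0))
    stop("mixing_coefficients must be two non-negative amplitudes")
  if (peak_amplitude <= 0) stop("peak_amplitude must be positive")
  l <- sort(decay_rates, decreasing = TRUE)
  A2 <- mixing_coefficients[1L]; A3 <- mixing_coefficients[2L]

  cp_max <- function(A1) {
    tt <- seq(0, 12 / l[2L], length.out = 4096L)
    max((A1 * tt - A2 - A3) * exp(-l[1L] * tt) + A2 * exp(-l[2L] * tt) +
          A3 * exp(-l[3L] * tt))
  }
  # peak height is increasing in A1; bracket then solve
  hi <- peak_amplitude * exp(1) * l[1L]
  while (cp_max(hi) < peak_amplitude) hi <- hi * 2
  A1 <- stats::uniroot(function(a) cp_max(a) - peak_amplitude,
                       lower = 0, upper = hi, tol = 1e-10)$root

  tt <- seq(0, 12 / l[2L], length.out = 8192L)
  cp <- (A1 * tt - A2 - A3) * exp(-l[1L] * tt) + A2 * exp(-l[2L] * tt) +
    A3 * exp(-l[3L] * tt)
  if (min(cp) < -1e-9 * peak_amplitude)
    stop("parameter set yields a negative plasma curve; increase the upslope ",
         "rate or reduce the mixing coefficients")
  structure(list(peak_time = tt[which.max(cp)],
                 peak_amplitude = peak_amplitude,
                 decay_rates = l,
                 mixing_coefficients = c(A2, A3),
                 A = c(A1, A2, A3)),
            class = "input_function_params")
}

# Evaluate the analytic form at arbitrary times.
feng_cp <- function(params, t) {
  A <- params$A; l <- params$decay_rates
  cp <- (A[1L] * t - A[2L] - A[3L]) * exp(-l[1L] * t) +
    A[2L] * exp(-l[2L] * t) + A[3L] * exp(-l[3L] * t)
  cp[t < 0] <- 0
  pmax(cp, 0)
}

#' Sampled plasma input function
#'
#' @param sample_times Strictly increasing times (min) starting at 0.
#' @param sample_values Plasma tracer activity (kBq/mL), non-negative.
#' @param cp_met Plasma concentration of the cold metabolite (glucose or
#'   acetoacetate, umol/mL); required only when converting K to a cerebral
#'   metabolic rate.
#' @return An object of class `plasma_input`.
#' @export
plasma_input <- function(sample_times, sample_values, cp_met = NA_real_) {
  sample_times <- as.numeric(sample_times)
  sample_values <- as.numeric(sample_values)
  if (length(sample_times) != length(sample_values) || length(sample_times) < 2L)
    stop("need at least two (time, value) samples")
  if (sample_times[1L] != 0) stop("sample times must start at 0")
  if (any(diff(sample_times) <= 0)) stop("sample times must be strictly increasing")
  if (any(sample_values < 0)) stop("plasma activity must be non-negative")
  structure(list(sample_times = sample_times, sample_values = sample_values,
                 cp_met = cp_met),
            class = "plasma_input")
}

#' Build a densely sampled plasma input function from analytic parameters
#'
#' @param params An [input_function_params()].
#' @param t_end End of the sampling window (min).
#' @param dt Sampling step (min); the default is fine enough that linear
#'   interpolation error is negligible relative to PET frame averaging.
#' @param cp_met Cold metabolite concentration (umol/mL), stored for CMR
#'   conversion.
#' @return A [plasma_input()].
#' @export
make_input_function <- function(params, t_end = 60, dt = 0.01, cp_met = NA_real_) {
  stopifnot(inherits(params, "input_function_params"))
  if (t_end <= 0 || dt <= 0) stop("t_end and dt must be positive")
  tt <- seq(0, t_end, by = dt)
  if (tt[length(tt)] < t_end) tt <- c(tt, t_end)
  plasma_input(tt, feng_cp(params, tt), cp_met = cp_met)
}

#' Plasma activity at arbitrary times (linear interpolation)
#' @param ipf A [plasma_input()].
#' @param t Times (min) within the sampled range.
#' @return Activity values (kBq/mL).
#' @export
cp_at <- function(ipf, t) {
  stopifnot(inherits(ipf, "plasma_input"))
  rng <- range(ipf$sample_times)
  if (any(t < rng[1L] - 1e-12 | t > rng[2L] + 1e-12))
    stop("time outside the sampled plasma curve; extrapolation is not supported")
  stats::approx(ipf$sample_times, ipf$sample_values, xout = t, rule = 1)$y
}

#' Integral of the plasma curve from injection to time t
#'
#' Trapezoidal integral of the linearly interpolated curve from 0 to `t`;
#' non-decreasing in `t` because the curve is non-negative.
#'
#' @param ipf A [plasma_input()].
#' @param t Upper limits (min), each within `[0, max(sample_times)]`.
#' @return Integral values (kBq.min/mL).
#' @export
integrate_input <- function(ipf, t) {
  stopifnot(inherits(ipf, "plasma_input"))
  tm <- ipf$sample_times; v <- ipf$sample_values
  if (any(t < -1e-12 | t > tm[length(tm)] + 1e-12))
    stop("integration limit outside the sampled plasma curve")
  cum <- c(0, cumsum(diff(tm) * (v[-length(v)] + v[-1L]) / 2))
  vapply(t, function(ti) {
    ti <- min(max(ti, 0), tm[length(tm)])
    i <- findInterval(ti, tm)
    if (i >= length(tm)) return(cum[length(cum)])
    # partial trapezoid within the enclosing sample interval
    dt <- ti - tm[i]
    vi <- v[i] + (v[i + 1L] - v[i]) * dt / (tm[i + 1L] - tm[i])
    cum[i] + dt * (v[i] + vi) / 2
  }, numeric(1L))
}

#' Normalized time (Patlak abscissa)
#'
#' The integral of the plasma input curve from injection divided by the
#' instantaneous plasma activity: `theta(t) = int_0^t Cp / Cp(t)`. Undefined
#' where `Cp(t) <= 0`; such points are returned as `NA` with a warning and
#' excluded from Patlak fits.
#'
#' @param ipf A [plasma_input()].
#' @param t Evaluation times (min).
#' @return Normalized times (min), `NA` where the plasma activity is not positive.
#' @export
normalized_time <- function(ipf, t) {
  cp <- cp_at(ipf, t)
  theta <- rep(NA_real_, length(t))
  ok <- cp > 0
  if (any(!ok))
    warning("plasma activity is not positive at ", sum(!ok),
            " time point(s); normalized time undefined there")
  theta[ok] <- integrate_input(ipf, t[ok]) / cp[ok]
  theta[!ok & t == 0] <- NA_real_
  # at t = 0 with Cp(0+) > 0 the ratio tends to 0
  theta[t == 0 & ok] <- 0
  theta
}
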