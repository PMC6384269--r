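# Patlak graphical analysis: for an irreversibly trapped tracer the plot of
# tissue/plasma activity against normalized time becomes linear once the
# reversible compartments equilibrate, and its slope is the net influx rate
# constant K (1/min).

#' Patlak graphical fit of a tissue time-activity curve
#'
#' Each retained frame contributes one point: abscissa
#' `theta = int_0^t Cp / Cp(t)` and ordinate `tissue(t) / Cp(t)`, both
#' evaluated at the frame midpoint. A least-squares line through the frames
#' whose midpoints are at or after `t_star` gives the rate constant `K`
#' (slope, 1/min) and the effective initial distribution volume (intercept).
#'
#' Negative fitted slopes are retained, never clamped, so downstream
#' statistics see unbiased estimates.
#'
#' @param tac A [tac()].
#' @param ipf A [plasma_input()] covering the schedule.
#' @param t_star Start of the linear phase (min). Conventional defaults are
#'   10 min for the 60-min glucose protocol and 3 min for the 10-min
#'   acetoacetate protocol.
#' @param weighting `"uniform"` (default) or `"duration"` (weights
#'   proportional to frame duration).
#' @return An object of class `patlak_result`: fields `K`, `intercept`,
#'   `r_squared`, `t_star`, `n_points`, and the fitted `points` data frame
#'   (`frame_mid`, `theta`, `ratio`).
#' @export
patlak_fit <- function(tac, ipf, t_star = 10, weighting = c("uniform", "duration")) {
  stopifnot(inherits(tac, "tac"), inherits(ipf, "plasma_input"))
  weighting <- match.arg(weighting)
  sched <- tac$schedule
  mids <- sched$mid
  cp <- cp_at(ipf, mids)
  theta <- suppressWarnings(normalized_time(ipf, mids))
  ratio <- ifelse(cp > 0, tac$values / cp, NA_real_)

  keep <- mids >= t_star & is.finite(theta) & is.finite(ratio)
  if (sum(keep) < 3L)
    stop("fewer than 3 usable frames at or after t_star = ", t_star, " min")
  th <- theta[keep]; ra <- ratio[keep]
  if (stats::var(th) == 0) stop("zero variance in normalized time; cannot fit")

  w <- if (weighting == "duration") sched$dur[keep] else rep(1, sum(keep))
  fit <- stats::lm.wfit(cbind(1, th), ra, w)
  co <- fit$coefficients
  ss_res <- sum(w * fit$residuals^2)
  ss_tot <- sum(w * (ra - stats::weighted.mean(ra, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  structure(list(K = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2, t_star = t_star, n_points = sum(keep),
                 weighting = weighting,
                 points = data.frame(frame_mid = mids[keep], theta = th, ratio = ra)),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf("Patlak fit: K = %.5f 1/min, intercept = %.4f, R^2 = %.4f (%d frames, t* = %g min)\n",
              x$K, x$intercept, x$r_squared, x$n_points, x$t_star))
  invisible(x)
}

#' Convert a Patlak rate constant to a cerebral metabolic rate
#'
#' `CMR = (K * Cp) / LC`, where `Cp` is the plasma concentration of the cold
#' substrate (umol/mL) and `LC` the lumped constant translating tracer-analog
#' uptake into native-substrate metabolism (0.8 for FDG/glucose, 1.0 for
#' acetoacetate). The result is conventionally reported per 100 g of tissue,
#' so the value is scaled by `100 / density`; with the default tissue density
#' of 1.0 g/mL this is a pure unit conversion from umol/mL/min to
#' umol/100 g/min.
#'
#' @param K Patlak rate constant (1/min); negative estimates are propagated.
#' @param cp_met Plasma substrate concentration (umol/mL; numerically equal to
#'   mM).
#' @param lc Lumped constant (> 0).
#' @param density Tissue density (g/mL, > 0).
#' @return An object of class `metabolic_rate` with fields `cmr`
#'   (umol/100 g/min), `lumped_constant` and `tissue_density`.
#' @export
cmr_from_k <- function(K, cp_met, lc, density = 1.0) {
  if (!is.finite(lc) || lc <= 0) stop("lumped constant must be positive")
  if (!is.finite(density) || density <= 0) stop("tissue density must be positive")
  if (any(!is.finite(cp_met)) || any(cp_met <= 0))
    stop("plasma substrate concentration must be positive")
  structure(list(cmr = 100 * K * cp_met / (lc * density),
                 lumped_constant = lc, tissue_density = density),
            class = "metabolic_rate")
}

#' Regional Patlak rate constants from a dynamic image or regional TACs
#'
#' Applies [patlak_fit()] per atlas region. Input is either a 4D dynamic image
#' plus an aligned integer label volume (regional mean TACs are extracted
#' first, ignoring voxels flagged `NA`, e.g. by partial-volume correction) or
#' a named list of [tac()] objects keyed by region name.
#'
#' Regions whose fit fails (too few frames, empty region, degenerate plasma
#' curve) are flagged in the output rather than dropped.
#'
#' @param dynamic A 4D array `(x, y, z, frame)` or a named list of [tac()]s.
#' @param ipf A [plasma_input()].
#' @param atlas A region atlas data frame (see [load_atlas()]).
#' @param labels Integer 3D array of region ids; required with a 4D array.
#' @param schedule A [frame_schedule()]; required with a 4D array.
#' @param t_star,weighting Passed to [patlak_fit()].
#' @return A data frame with one row per atlas region: `region_id`, `region`,
#'   `K_per_min`, `intercept`, `r2`, `n_points`, `t_star`, `ok` (logical flag).
#' @export
fit_regional_k <- function(dynamic, ipf, atlas, labels = NULL, schedule = NULL,
                           t_star = 10, weighting = "uniform") {
  if (is.array(dynamic) && length(dim(dynamic)) == 4L) {
    if (is.null(labels) || is.null(schedule))
      stop("labels and schedule are required with a 4D dynamic image")
    if (!all(dim(labels) == dim(dynamic)[1:3]))
      stop("label volume is not aligned with the dynamic image grid")
    n_fr <- dim(dynamic)[4L]
    if (n_fr != nrow(schedule))
      stop("frame count mismatch between image (", n_fr, ") and schedule (",
           nrow(schedule), ")")
    lab_vec <- as.integer(labels)
    tacs <- lapply(seq_len(nrow(atlas)), function(i) {
      sel <- lab_vec == atlas$id[i]
      if (!any(sel)) return(NULL)
      vals <- vapply(seq_len(n_fr), function(f) {
        v <- as.numeric(dynamic[, , , f])[sel]
        mean(v, na.rm = TRUE)
      }, numeric(1L))
      if (any(!is.finite(vals))) return(NULL)
      tac(schedule, vals)
    })
    names(tacs) <- atlas$name
  } else if (is.list(dynamic)) {
    tacs <- dynamic[match(atlas$name, names(dynamic))]
  } else stop("dynamic must be a 4D array or a named list of TACs")

  rows <- lapply(seq_len(nrow(atlas)), function(i) {
    res <- if (is.null(tacs[[i]])) NULL else
      tryCatch(patlak_fit(tacs[[i]], ipf, t_star = t_star, weighting = weighting),
               error = function(e) NULL)
    if (is.null(res))
      data.frame(region_id = atlas$id[i], region = atlas$name[i],
                 K_per_min = NA_real_, intercept = NA_real_, r2 = NA_real_,
                 n_points = 0L, t_star = t_star, ok = FALSE)
    else
      data.frame(region_id = atlas$id[i], region = atlas$name[i],
                 K_per_min = res$K, intercept = res$intercept, r2 = res$r_squared,
                 n_points = res$n_points, t_star = t_star, ok = TRUE)
  })
  do.call(rbind, rows)
}
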