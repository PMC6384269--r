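# Simulated longitudinal cohort: the 3-visit aging-study design (baseline,
# +2 y, +4 y with N = 25/25/16), per-region tracer rate constants following a
# linear-in-age mixed model, and plasma/cognitive covariates with a built-in
# insulin-resistance dependence.

#' Specification of a simulated longitudinal cohort
#'
#' Defaults reproduce the study design emulated throughout the package:
#' 25 participants at baseline, all 25 at year 2 and 16 at year 4; baseline
#' age Normal(70.9, 5) truncated to 60-85; per-region baseline means and
#' annual slopes taken from the bundled glucose K table; between-subject SD
#' 0.006 and residual SD 0.004 (1/min). Covariates: plasma glucose
#' Normal(5.1, 0.5) mM; insulin log-normal with mean 7.1 uU/mL, coupled to a
#' latent subject-level insulin-resistance factor that also depresses the
#' subject's K intercept (correlation `insulin_k_cor`, default -0.45) and the
#' executive / attention-speed scaled scores; other scaled scores
#' Normal(10, 3) truncated to 1-19.
#'
#' @param n_baseline Participants at baseline.
#' @param visit_years Visit offsets (years), default `c(0, 2, 4)`.
#' @param n_per_visit Non-increasing participant counts per visit,
#'   default `c(25, 25, 16)`.
#' @param region_means Named numeric vector of baseline region means (1/min).
#' @param region_slopes Named numeric vector of annual slopes (1/min/yr),
#'   names matching `region_means`.
#' @param between_subject_sd,residual_sd Random-intercept and residual SD (1/min).
#' @param glucose_mean,glucose_sd Plasma glucose (mM).
#' @param insulin_mean Plasma insulin (uU/mL).
#' @param insulin_k_cor Correlation between the latent insulin-resistance
#'   factor's effect on insulin and the subject K intercept (negative:
#'   more resistant subjects extract less tracer).
#' @param age_mean,age_sd,age_range Baseline age model (years).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec and this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_baseline = 25L,
                        visit_years = c(0, 2, 4),
                        n_per_visit = c(25L, 25L, 16L),
                        region_means = NULL,
                        region_slopes = NULL,
                        between_subject_sd = 0.006,
                        residual_sd = 0.004,
                        glucose_mean = 5.1, glucose_sd = 0.5,
                        insulin_mean = 7.1,
                        insulin_k_cor = -0.45,
                        age_mean = 70.9, age_sd = 5, age_range = c(60, 85),
                        seed = 1L) {
  if (is.null(region_means) || is.null(region_slopes)) {
    kt <- load_k_table("glucose")
    # fixed_effect is the fitted annual change; T0 the baseline mean
    if (is.null(region_means)) region_means <- setNames(kt$T0, kt$region)
    if (is.null(region_slopes)) region_slopes <- setNames(kt$fixed_effect, kt$region)
  }
  if (!identical(names(region_means), names(region_slopes)))
    stop("region_means and region_slopes must cover the same regions")
  if (length(n_per_visit) != length(visit_years))
    stop("n_per_visit must match visit_years")
  if (any(diff(n_per_visit) > 0)) stop("n_per_visit must be non-increasing")
  if (any(n_per_visit > n_baseline))
    stop("visit counts cannot exceed n_baseline")
  if (abs(insulin_k_cor) > 1) stop("insulin_k_cor must be in [-1, 1]")
  structure(list(n_baseline = as.integer(n_baseline), visit_years = visit_years,
                 n_per_visit = as.integer(n_per_visit),
                 region_means = region_means, region_slopes = region_slopes,
                 between_subject_sd = between_subject_sd,
                 residual_sd = residual_sd,
                 glucose_mean = glucose_mean, glucose_sd = glucose_sd,
                 insulin_mean = insulin_mean, insulin_k_cor = insulin_k_cor,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a longitudinal cohort
#'
#' Per subject `s`, region `r` and visit `v`:
#' `K = mean_r + slope_r * (age_sv - mean_age) + u_s + e`, with random
#' intercept `u_s ~ Normal(0, between_subject_sd)` (partially driven by the
#' latent insulin-resistance factor, see [cohort_spec()]) and
#' `e ~ Normal(0, residual_sd)`. Dropout at later visits is random.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per subject-visit: `subject_id`, `visit`
#'   (`T0`, `T2`, ...), `age_yr`, `glucose_mM`, `insulin_uU_per_mL`, one
#'   `K.<region>` column per region, and scaled cognitive scores
#'   (`score_<test>` columns).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  battery <- load_cognitive_battery()
  with_seed(spec$seed, {
    ns <- spec$n_baseline
    nv <- length(spec$visit_years)
    age0 <- rtruncnorm1(ns, spec$age_mean, spec$age_sd,
                        spec$age_range[1L], spec$age_range[2L])
    z_ir <- stats::rnorm(ns)  # latent insulin-resistance factor
    rho <- abs(spec$insulin_k_cor)
    u_dir <- if (spec$insulin_k_cor <= 0) -1 else 1
    u <- spec$between_subject_sd *
      (u_dir * rho * z_ir + sqrt(1 - rho^2) * stats::rnorm(ns))

    # retained subjects per visit (random, non-informative dropout)
    keep <- lapply(seq_len(nv), function(v) sort(sample.int(ns, spec$n_per_visit[v])))

    ages_all <- outer(age0, rep(1, nv)) +
      outer(rep(1, ns), spec$visit_years)
    rows_keep <- do.call(rbind, lapply(seq_len(nv), function(v)
      data.frame(subject = keep[[v]], visit = v)))
    mean_age <- mean(ages_all[cbind(rows_keep$subject, rows_keep$visit)])

    regs <- names(spec$region_means)
    out <- do.call(rbind, lapply(seq_len(nv), function(v) {
      sub <- keep[[v]]
      n <- length(sub)
      age_v <- age0[sub] + spec$visit_years[v]
      kmat <- sapply(regs, function(r) {
        spec$region_means[[r]] + spec$region_slopes[[r]] * (age_v - mean_age) +
          u[sub] + stats::rnorm(n, 0, spec$residual_sd)
      })
      kmat <- matrix(kmat, nrow = n,
                     dimnames = list(NULL, paste0("K.", regs)))
      glucose <- pmax(stats::rnorm(n, spec$glucose_mean, spec$glucose_sd), 2.5)
      insulin <- spec$insulin_mean *
        exp(0.40 * z_ir[sub] + 0.25 * stats::rnorm(n) - 0.5 * (0.40^2 + 0.25^2))
      scores <- sapply(battery$test, function(te) {
        shift <- if (battery$domain[battery$test == te] %in%
                     c("executive", "attention_speed")) -0.9 * z_ir[sub] else 0
        round(pmin(pmax(stats::rnorm(n, 10 + shift, 3), 1), 19))
      })
      scores <- matrix(scores, nrow = n,
                       dimnames = list(NULL, paste0("score_", battery$test)))
      cbind(data.frame(subject_id = sprintf("S%02d", sub),
                       visit = paste0("T", spec$visit_years[v]),
                       age_yr = age_v,
                       glucose_mM = glucose,
                       insulin_uU_per_mL = insulin),
            as.data.frame(kmat), as.data.frame(scores))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Load the cognitive battery domain mapping
#'
#' Maps each scaled-score test to exactly one cognitive domain (global,
#' executive, working_memory, episodic_memory, language, attention_speed).
#'
#' @return Data frame with columns `test`, `domain`.
#' @export
load_cognitive_battery <- function() {
  path <- system.file("extdata", "cognitive_battery.tsv", package = "dualpet")
  read_tsv_checked(path, c("test", "domain"))
}
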