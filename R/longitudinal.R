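# Serial-measures statistics: per-region linear mixed model with age as the
# fixed factor and a random intercept per subject, slope (fixed-effect) tests,
# and Benjamini-Hochberg FDR across regions.

#' Linear mixed model of a longitudinal outcome against age
#'
#' Fits `outcome = b0 + b1 * (age - mean(age)) + u_subject + e` by maximum
#' likelihood with a random intercept per subject (lme4), and tests the slope
#' `b1` two-sidedly. Centering makes the slope invariant to adding a constant
#' to all ages. With three visits per subject, random slopes are barely
#' identifiable at this sample size, so only the intercept is random.
#'
#' When the residual variance is degenerate (e.g. noise-free data) the mixed
#' fit is singular; the slope is then recovered exactly by a fixed
#' subject-intercept least-squares fit and flagged via `converged = FALSE`.
#'
#' @param records Data frame with columns `subject`, `age`, `y` (column names
#'   configurable via `cols`).
#' @param cols Named character vector mapping `subject`, `age`, `y` to columns
#'   of `records`.
#' @param df_method `"normal"` (Wald z test, default) or `"t"` (t reference
#'   with `n_subjects - 1` degrees of freedom).
#' @return An object of class `mixed_fit`: `slope` (per year), `slope_se`,
#'   `intercept`, `p_value`, `n_obs`, `n_subjects`, `converged`, `note`.
#' @export
fit_mixed_linear <- function(records,
                             cols = c(subject = "subject", age = "age", y = "y"),
                             df_method = c("normal", "t")) {
  df_method <- match.arg(df_method)
  d <- data.frame(subject = factor(records[[cols[["subject"]]]]),
                  age = as.numeric(records[[cols[["age"]]]]),
                  y = as.numeric(records[[cols[["y"]]]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_subj <- nlevels(droplevels(d$subject))
  multi <- table(d$subject)
  if (n_subj < 2L || sum(multi >= 2L) < 2L)
    stop("need at least 2 subjects with at least 2 visits each; ",
         "the random intercept is unidentifiable otherwise")
  d$age_c <- d$age - mean(d$age)

  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ age_c + (1 | subject), data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) e)

  singular <- inherits(fit, "merMod") && lme4::isSingular(fit, tol = 1e-6)
  if (inherits(fit, "error") ||
      (singular && stats::sigma(fit) < 1e-8 * max(1e-12, stats::sd(d$y)))) {
    # degenerate residual variance: exact fixed-intercepts least squares
    ls <- stats::lm(y ~ age_c + subject, data = d)
    slope <- unname(stats::coef(ls)["age_c"])
    se <- suppressWarnings(unname(sqrt(diag(stats::vcov(ls)))["age_c"]))
    p <- if (is.finite(se) && se > 0) {
      z <- slope / se
      if (df_method == "t") 2 * stats::pt(-abs(z), df = n_subj - 1L)
      else 2 * stats::pnorm(-abs(z))
    } else 0
    return(structure(list(slope = slope, slope_se = se,
                          intercept = unname(stats::coef(ls)[1L]),
                          p_value = p, n_obs = nrow(d), n_subjects = n_subj,
                          converged = FALSE,
                          note = "degenerate mixed fit; fixed-intercept LS fallback"),
                     class = "mixed_fit"))
  }

  co <- summary(fit)$coefficients
  slope <- co["age_c", "Estimate"]; se <- co["age_c", "Std. Error"]
  z <- slope / se
  p <- if (df_method == "t") 2 * stats::pt(-abs(z), df = n_subj - 1L)
  else 2 * stats::pnorm(-abs(z))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  structure(list(slope = unname(slope), slope_se = unname(se),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 p_value = unname(p), n_obs = nrow(d), n_subjects = n_subj,
                 converged = conv,
                 note = if (singular) "singular random-effects fit" else ""),
            class = "mixed_fit")
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: with `m` ordered p-values, reject all hypotheses up to
#' the largest `k` with `p(k) <= q * k / m`. Adjusted values come from the
#' standard monotone construction (`stats::p.adjust`, method `"BH"`); a
#' hypothesis is rejected exactly when its adjusted value is `<= q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate, default 0.05.
#' @return A list: `reject` (logical), `adjusted` (numeric), `q`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  adjusted <- stats::p.adjust(p, method = "BH")
  list(reject = adjusted <= q, adjusted = adjusted, q = q)
}

#' Per-region longitudinal mixed-model table with FDR flags
#'
#' For each atlas region: visit means, a pooled SEM, the mixed-model slope of
#' K against centred age with its two-sided p-value, and a significance flag
#' after Benjamini-Hochberg correction across all regions of the tracer (the
#' 43 regions of one tracer form one FDR family).
#'
#' The pooled SEM is `sqrt(var_subject + var_residual) / sqrt(n_bar)` with
#' `n_bar` the mean number of subjects per visit: the mixed model's
#' total-variance-based standard error of a visit mean.
#'
#' @param cohort A cohort data frame from [simulate_cohort()] (or any table
#'   with `subject_id`, `visit`, `age_yr` and `K.<region>` columns).
#' @param atlas Atlas data frame; regions missing from `cohort` produce
#'   explicit `NA` gap rows.
#' @param q FDR level, default 0.05.
#' @param df_method Passed to [fit_mixed_linear()].
#' @return A data frame in atlas order: `region`, visit-mean columns (`T0`,
#'   `T2`, `T4`, ...), `SEM`, `fixed_effect`, `p_value`, `fdr_significant`,
#'   `converged`.
#' @export
build_regional_table <- function(cohort, atlas = load_atlas(), q = 0.05,
                                 df_method = "normal") {
  visits <- sort(unique(cohort$visit))
  rows <- lapply(atlas$name, function(rg) {
    col <- paste0("K.", rg)
    if (!col %in% names(cohort)) {
      means <- setNames(rep(NA_real_, length(visits)), visits)
      return(c(list(region = rg), as.list(means),
               list(SEM = NA_real_, fixed_effect = NA_real_,
                    p_value = NA_real_, converged = NA)))
    }
    y <- cohort[[col]]
    means <- vapply(visits, function(v) mean(y[cohort$visit == v]), numeric(1L))
    names(means) <- visits
    fit <- fit_mixed_linear(
      data.frame(subject = cohort$subject_id, age = cohort$age_yr, y = y),
      df_method = df_method)
    n_bar <- mean(table(cohort$visit))
    # total variance around the fitted age trend (subject + residual)
    resid_tot <- stats::sd(y - fit$intercept -
                             fit$slope * (cohort$age_yr - mean(cohort$age_yr)))
    sem <- resid_tot / sqrt(n_bar)
    c(list(region = rg), as.list(means),
      list(SEM = sem, fixed_effect = fit$slope, p_value = fit$p_value,
           converged = fit$converged))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  fdr <- rep(NA, nrow(out))
  has_p <- is.finite(out$p_value)
  if (any(has_p)) fdr[has_p] <- bh_fdr(out$p_value[has_p], q = q)$reject
  out$fdr_significant <- fdr
  rownames(out) <- NULL
  out
}
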