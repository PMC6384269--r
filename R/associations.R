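# Cross-sectional association layer: HOMA-IR, cognitive composite z-scores,
# subject averaging across visits, and Pearson/linear-regression associations.

#' Homeostasis-model insulin-resistance index
#'
#' `HOMA-IR = glucose (mM) * insulin (uU/mL) / 22.5`.
#'
#' @param glucose Fasting plasma glucose (mM, > 0).
#' @param insulin Fasting plasma insulin (uU/mL, >= 0).
#' @return Unitless index.
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose must be positive")
  if (any(!is.finite(insulin)) || any(insulin < 0))
    stop("insulin must be non-negative")
  glucose * insulin / 22.5
}

#' Cognitive composite z-score for one domain
#'
#' Scaled scores are population-normed with mean 10 and SD 3; each test
#' contributes `(scaled - 10) / 3` and the composite is the mean over the
#' domain's available tests. Missing tests are excluded and counted.
#'
#' @param scores Named numeric vector of scaled scores; names must match the
#'   battery's `test` column.
#' @param domain One of the battery domains (e.g. `"executive"`).
#' @param battery Test-to-domain mapping, default [load_cognitive_battery()].
#' @return The composite z-score, with attributes `n_tests` (used) and
#'   `n_missing`.
#' @export
composite_z <- function(scores, domain, battery = load_cognitive_battery()) {
  tests <- battery$test[battery$domain == domain]
  if (length(tests) == 0L) stop("unknown domain: ", domain)
  avail <- tests[tests %in% names(scores)]
  vals <- scores[avail]
  avail <- avail[is.finite(vals)]
  if (length(avail) == 0L) stop("no available tests in domain ", domain)
  z <- mean((as.numeric(scores[avail]) - 10) / 3)
  structure(z, n_tests = length(avail), n_missing = length(tests) - length(avail))
}

#' Per-subject averages across visits
#'
#' Cross-sectional associations are computed on subject means over all
#' available visits, which avoids treating repeated measures as independent.
#'
#' @param records Data frame with a subject identifier column and numeric
#'   variable columns.
#' @param id_col Name of the subject identifier column.
#' @param value_cols Columns to average; default all numeric columns.
#' @return Data frame with one row per subject: the id, `n_visits`, and the
#'   per-variable means.
#' @export
subject_average <- function(records, id_col = "subject_id", value_cols = NULL) {
  if (!id_col %in% names(records)) stop("missing id column ", id_col)
  if (is.null(value_cols))
    value_cols <- names(records)[vapply(records, is.numeric, logical(1L))]
  ids <- factor(records[[id_col]])
  out <- data.frame(id = levels(ids), n_visits = as.integer(table(ids)))
  names(out)[1L] <- id_col
  for (v in value_cols)
    out[[v]] <- as.numeric(tapply(records[[v]], ids, mean, na.rm = TRUE))
  out
}

#' Pearson association between two per-subject variables
#'
#' Pearson r with the two-sided p-value from the t transform on `n - 2`
#' degrees of freedom; equivalent to the slope test of the simple linear
#' regression of `y` on `x`, whose slope and intercept are also returned.
#' Subjects missing either variable are dropped pairwise.
#'
#' @param x,y Numeric vectors of per-subject values.
#' @param x_label,y_label Variable names carried into the result.
#' @return An object of class `association`: `r`, `p_value`, `n`, `slope`,
#'   `intercept`, `x_label`, `y_label`.
#' @export
pearson_association <- function(x, y, x_label = deparse(substitute(x)),
                                y_label = deparse(substitute(y))) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete subject pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  slope <- r * stats::sd(y) / stats::sd(x)
  structure(list(r = r, p_value = p, n = n, slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 x_label = x_label, y_label = y_label),
            class = "association")
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("%s vs %s: r = %+.3f, p = %.4g (n = %d)\n",
              x$x_label, x$y_label, x$r, x$p_value, x$n))
  invisible(x)
}
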