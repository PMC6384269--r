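# Region-level bookkeeping: the 43-region merged AAL atlas, regional mean
# extraction, volume normalization, percent brain-volume change, and the
# percent-decline summary over significant regions.

#' Load the 43-region brain atlas
#'
#' The merged AAL parcellation used throughout: 15 frontal, 9 temporal,
#' 6 parietal, 6 occipital, 4 insula/cingulate and 3 central-structure
#' regions. Two orbital superior frontal subdivisions share a printed label
#' and are disambiguated with a "(medial)" suffix.
#'
#' @return A data frame with columns `id`, `name`, `lobe_group`.
#' @export
load_atlas <- function() {
  path <- system.file("extdata", "aal43_regions.tsv", package = "dualpet")
  read_tsv_checked(path, c("id", "name", "lobe_group"))
}

#' Load a bundled regional longitudinal K table
#'
#' Transcribed regional rate constants from a 4-year longitudinal aging cohort
#' (per-region visit means T0/T2/T4, pooled SEM, mixed-model fixed-effect
#' slope and p-value), one table per tracer.
#'
#' @param tracer `"glucose"` or `"acac"`.
#' @return A data frame with columns `region`, `T0`, `T2`, `T4`, `SEM`,
#'   `fixed_effect`, `p_value`.
#' @export
load_k_table <- function(tracer = c("glucose", "acac")) {
  tracer <- match.arg(tracer)
  fn <- if (tracer == "glucose") "kglc_regional_followup.tsv" else
    "kacac_regional_followup.tsv"
  path <- system.file("extdata", fn, package = "dualpet")
  read_tsv_checked(path, c("region", "T0", "T2", "T4", "SEM", "fixed_effect",
                           "p_value"))
}

#' Regional means of a 3D image over an atlas label volume
#'
#' Arithmetic mean per labelled region, ignoring voxels flagged `NA` (e.g. by
#' partial-volume correction). Regions with no usable voxels get `NA` and
#' `ok = FALSE` rather than being dropped.
#'
#' @param image 3D numeric array.
#' @param labels Aligned 3D integer array of region ids.
#' @param atlas Atlas data frame; default [load_atlas()].
#' @return Data frame: `region_id`, `region`, `mean`, `n_voxels`, `ok`.
#' @export
extract_regional_means <- function(image, labels, atlas = load_atlas()) {
  if (!all(dim(image) == dim(labels)))
    stop("image and label volume must share one grid")
  lab <- as.integer(labels); val <- as.numeric(image)
  usable <- !is.na(val)
  sums <- rowsum(val[usable & lab > 0L], lab[usable & lab > 0L])
  cnts <- rowsum(rep(1L, sum(usable & lab > 0L)), lab[usable & lab > 0L])
  ids <- as.integer(rownames(sums))
  m <- setNames(as.numeric(sums) / as.numeric(cnts), ids)
  n <- setNames(as.integer(cnts), ids)
  out <- data.frame(region_id = atlas$id, region = atlas$name,
                    mean = unname(m[as.character(atlas$id)]),
                    n_voxels = unname(n[as.character(atlas$id)]))
  out$n_voxels[is.na(out$n_voxels)] <- 0L
  out$ok <- out$n_voxels > 0L & is.finite(out$mean)
  out
}

#' Normalize a regional volume to intracranial volume
#' @param region_volume Regional volume (mL).
#' @param icv Intracranial volume (mL, > 0).
#' @return Unitless ratio.
#' @export
normalize_volume <- function(region_volume, icv) {
  if (any(!is.finite(icv)) || any(icv <= 0)) stop("icv must be positive")
  region_volume / icv
}

#' Percent whole-brain volume change between two timepoints
#'
#' `100 * (v1 - v0) / v0`; global atrophy is conventionally expressed as a
#' negative PBVC, so the atrophy magnitude is `-pbvc()`.
#'
#' @param volume_t0 Baseline volume (mL, > 0).
#' @param volume_t1 Follow-up volume (mL).
#' @return Percent change.
#' @export
pbvc <- function(volume_t0, volume_t1) {
  if (any(!is.finite(volume_t0)) || any(volume_t0 <= 0))
    stop("baseline volume must be positive")
  100 * (volume_t1 - volume_t0) / volume_t0
}

#' Percent-decline summary over significantly changing regions
#'
#' For every region whose slope test reaches `p <= alpha`, the baseline to
#' final-visit decline is `100 * (T0 - T4) / T0`. Returns per-region declines,
#' the (min, max) range rounded to the nearest integer percent (half away from
#' zero), and the annualized declines (divided by the follow-up span) with the
#' range rounded to one decimal.
#'
#' @param k_table Data frame with columns `region`, `T0`, `T4`, `p_value`
#'   (e.g. [load_k_table()]).
#' @param alpha Significance level for the slope test, default 0.05.
#' @param followup_years Span between first and last visit, default 4.
#' @return A list: `per_region` (data frame `region`, `decline_pct`,
#'   `annual_pct`, `p_value`), `range_pct` (rounded integer min/max),
#'   `annual_range_pct` (min/max, one decimal).
#' @export
percent_decline_summary <- function(k_table, alpha = 0.05, followup_years = 4) {
  need <- c("region", "T0", "T4", "p_value")
  if (!all(need %in% names(k_table)))
    stop("k_table must have columns ", paste(need, collapse = ", "))
  sig <- k_table[k_table$p_value <= alpha, , drop = FALSE]
  if (nrow(sig) == 0L) stop("no region reaches p <= ", alpha)
  decline <- 100 * (sig$T0 - sig$T4) / sig$T0
  annual <- decline / followup_years
  list(per_region = data.frame(region = sig$region, decline_pct = decline,
                               annual_pct = annual, p_value = sig$p_value),
       range_pct = c(min = round_half_away(min(decline)),
                     max = round_half_away(max(decline))),
       annual_range_pct = c(min = round_half_away(min(annual), 1L),
                            max = round_half_away(max(annual), 1L)))
}
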