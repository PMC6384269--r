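---
title: "Dual-tracer brain PET kinetics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-tracer brain PET kinetics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualpet)
```

## The measurement problem

Dynamic PET with ¹⁸F-FDG and ¹¹C-acetoacetate quantifies the brain's capacity
to extract its two fuels, glucose and ketones, from plasma. After injection,
the scanner records frame-averaged tissue radioactivity (a time–activity
curve, TAC) while blood sampling provides the plasma input function Cp(t).
The quantity of interest per region is the extraction rate constant
K (min⁻¹), and from it the cerebral metabolic rate. In a longitudinal aging
cohort the scientific questions are whether regional K declines with age, and
whether K relates to insulin resistance and cognition across subjects.

## Patlak graphical analysis

For a tracer that is irreversibly trapped (FDG phosphorylation; acetoacetate
oxidation on the 10-min scale), the ratio of tissue to plasma activity plotted
against normalized time

$$\theta(t) = \frac{\int_0^t C_p\,d\tau}{C_p(t)}$$

becomes linear once the reversible exchange equilibrates; the slope is K and
the intercept the effective initial distribution volume. `patlak_fit()`
evaluates both coordinates at frame midpoints (the standard convention for
frame-averaged data), retains frames with midpoint at or after `t_star`, and
fits by least squares (uniform weights by default; frame-duration weights
optional). Points where Cp ≤ 0 are undefined; they are signalled and excluded
rather than silently dropped into the fit.

Assumptions: the tracer is irreversible over the fit window (no
dephosphorylation), the plasma curve is measured without error and covers the
whole scan, and activities are decay-corrected to injection time. Negative
fitted K values are retained and flagged, never clamped, so the longitudinal
statistics downstream see unbiased estimates.

`t_star` defaults to 10 min for the 60-min glucose protocol — the
conventional onset of the linear phase for FDG — and to 3 min for the 10-min
acetoacetate protocol, which leaves the 8 × 30 s and 4-min frames for the
fit. The short acetoacetate window necessarily yields a less settled linear
phase; the kinetics tests therefore assert tight recovery only for the 60-min
schedule and treat the short-schedule bias as a reported quantity.

## From K to metabolic rate

$$\mathrm{CMR} = \frac{K \cdot C_p}{\mathrm{LC}}$$

with Cp the *cold* substrate concentration in plasma (µmol/mL; numerically
equal to mM) — not the tracer activity — and LC the lumped constant: 0.8 for
FDG/glucose and 1.0 for acetoacetate. `cmr_from_k()` multiplies by
100/density (density default 1.0 g/mL) to report the conventional
µmol/100 g/min; that factor is a documented unit convention, since the ratio
form alone yields µmol/mL/min.

## Synthetic data: what it emulates, what it does not

The generator produces every input the pipeline needs, under the study
conditions the package targets:

* **Frame schedules**: 12 × 10 s + 8 × 30 s + 1 × 4 min (10 min,
  acetoacetate) and 12 × 10 s + 8 × 30 s + 6 × 4 min + 6 × 5 min (60 min,
  FDG).
* **Input functions**: a Feng-type tri-exponential with linear upslope,
  Cp(t) = (A₁t − A₂ − A₃)e^(−λ₁t) + A₂e^(−λ₂t) + A₃e^(−λ₃t), which is zero at
  origin, single-peaked, integrable in closed form, and a standard stand-in
  for measured arterialized blood samples. The upslope amplitude is solved
  numerically so the peak equals the requested amplitude.
* **Tissue curves**: the irreversible two-tissue system
  dC₁/dt = K₁Cp − (k₂+k₃)C₁, dC₂/dt = k₃C₁, with fractional blood volume vb,
  frame-averaged. True Patlak slope Ki = K₁k₃/(k₂+k₃) is known in closed
  form. Frame noise is zero-mean Gaussian with SD ∝ value/√(frame duration),
  the usual count-statistics heuristic.
* **Phantoms**: an ellipsoidal brain with a white-matter core, a gray-matter
  shell parcellated into the 43 atlas regions by seeded nearest-seed
  assignment, and a CSF rim; voxels 2 mm isotropic.
* **Cohort**: baseline N = 25 aged Normal(70.9, 5) truncated to 60–85, visits
  at 0/2/4 years with 25/25/16 observations (random, non-informative
  dropout); per-region K follows mean_r + slope_r·(age − mean age) + subject
  intercept + residual, with between-subject SD 0.006 and residual SD
  0.004 min⁻¹; defaults for means and slopes come from the bundled regional
  reference tables. A latent subject-level insulin-resistance factor raises
  insulin (log-normal, mean 7.1 µU/mL), lowers the subject's K intercept
  (correlation −0.45) and depresses executive/attention scaled scores, giving
  the association layer a known signal direction to recover.

Not emulated: scanner physics (attenuation, scatter, randoms,
reconstruction), isotope decay (all activities are assumed decay-corrected),
metabolite correction of the input function, informative dropout, and any
spatial correlation between regions beyond the shared subject intercept.
Passing tests therefore demonstrate correctness of the estimators under the
stated generative model, not robustness to acquisition artefacts.

## Partial-volume correction

`mg_correct()` implements the Müller-Gärtner correction:
corrected = (PET − wm_ref · smooth(WM)) / smooth(GM) at voxels with
GM probability ≥ `gm_threshold`, with CSF assumed activity-free (the classic
formulation). The PSF is an isotropic Gaussian, default FWHM 6 mm (typical
for this scanner class; configurable), applied as separable 1D convolutions
with edge-value padding — phantom tests keep structures away from grid edges
so the padding convention is immaterial. The white-matter reference defaults
to the mean over deep white matter (probability ≥ 0.95, eroded once), which
is unbiased on uniform white matter and slightly contaminated by gray-matter
spill-in on realistic contrast; the recovery tests bound the net effect. The
pipeline applies PVC to each dynamic frame before TAC extraction; correcting
parametric K images instead is possible by running the stages manually.

## Longitudinal statistics

Per region, `fit_mixed_linear()` fits
y = β₀ + β₁(age − mean age) + u_subject + ε by maximum likelihood with a
random intercept per subject (lme4) and tests β₁ two-sidedly with a Wald
normal reference (a t reference with n_subjects − 1 df is available). Random
slopes are deliberately omitted: three visits at N = 25 barely identify them.
When the residual variance degenerates (noise-free data) the mixed fit is
singular and the slope is recovered exactly by fixed-intercept least squares,
flagged via `converged = FALSE`. Age is centred, making the slope invariant
to shifting all ages.

FDR correction is Benjamini–Hochberg at q = 0.05, applied across the
43 regions of one tracer as one family (the two tracers are corrected
separately, mirroring their separate report tables). The report prints raw
p-values plus the FDR flag, since either convention may be wanted downstream.
The pooled SEM column is sqrt(subject + residual variance around the fitted
age trend)/√(mean subjects per visit) — the total-variance standard error of
a visit mean.

The percent-decline summary takes the regions with slope-test p ≤ 0.05 and
computes 100·(T0 − T4)/T0, reporting the min–max range rounded to the nearest
integer percent (half away from zero) and the annualized range (÷ 4 years) to
one decimal. On the bundled glucose reference table this yields 6–12% over
four years and 1.5–3.0% per year, the package's anchor values.

## Associations

Correlations are computed on subject averages across all available visits
(logging the per-visit count), avoiding pseudo-replication from repeated
measures; the paper-level alternative of restricting to complete cases is a
one-line filter upstream. HOMA-IR = glucose·insulin/22.5. Note that the mean
of per-subject HOMA-IR differs from the ratio of cohort means — the worked
value homa_ir(5.1, 7.1) = 1.61 legitimately exceeds a cohort-mean index near
1.1. Scaled cognitive scores convert to z-scores as (s − 10)/3 (population
norm mean 10, SD 3); domain composites average the available tests.
`pearson_association()` returns r with the two-sided t-transform p-value on
n − 2 df, which is identical to the slope test of the simple linear
regression (slope and intercept are also returned, since reports quote
either). Missing subjects are dropped pairwise. No multiplicity correction is
applied across the association matrix.

## Numerical choices

* Input curves are linearly interpolated; integrals are trapezoidal, exact
  for the piecewise-linear representation. The analytic generator samples at
  0.01 min.
* The tissue simulator uses an exact exponential propagator for C₁ with a
  trapezoidal source on a 0.1-s grid (frame boundaries of both standard
  schedules land on grid nodes); the test oracle is an independent
  deSolve::lsoda integration at 1-ms resolution.
* Gaussian kernels are truncated at 4 SD and renormalized, conserving mass to
  well under 0.1%.
* All randomness flows through explicit seeds with local RNG state, so no
  operation disturbs the caller's random stream and the pipeline is
  byte-deterministic for a fixed configuration seed.

## Problem sizes used in the test suite

Phantoms are 32³–40³ voxels at 2 mm (every atlas region receives well over
the guaranteed 8 voxels); Monte-Carlo suites use 200 simulated cohorts for
slope recovery, 300 simulated families for FDR calibration, 200–400
replicates for estimator bias and type-I error, chosen to keep Monte-Carlo
error a few times smaller than the tolerances being asserted.

## Known limitations

* The acetoacetate protocol's 10-min window yields noisier, more biased K
  than the 60-min glucose protocol; the package reports rather than hides
  this.
* Only the Müller-Gärtner PVC variant is provided (no geometric transfer
  matrix or deconvolution methods).
* No reversible-tracer (Logan) analysis; fully reversible kinetics show up as
  Patlak slopes near zero, which is tested, but are not otherwise modelled.
* Volume change is segmentation-volume arithmetic (`pbvc()`), a deliberate
  substitution for registration-based whole-brain atrophy estimation, which
  is out of scope.
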