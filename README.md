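# dualpet

Quantitative dual-tracer brain PET kinetic analysis and longitudinal regional
statistics, for studies of brain energy metabolism in aging: how the brain's
capacity to take up its two fuels — glucose (measured with ¹⁸F-FDG) and the
ketone body acetoacetate (measured with ¹¹C-acetoacetate) — changes over time,
and how that change relates to insulin resistance and cognition.

The package implements the full analysis chain on top of a synthetic-data
layer (analytic input functions, two-tissue-compartment tissue curves, digital
phantoms, a simulated 3-visit cohort), so every stage is testable without
scanner data.

## What it computes

**Patlak graphical analysis.** For an irreversibly trapped tracer, plotting
the tissue/plasma activity ratio against *normalized time*
θ(t) = ∫₀ᵗ Cp dτ / Cp(t) becomes linear once the reversible compartments
equilibrate. The slope of that line is the rate constant for brain extraction
of the tracer, K (min⁻¹). For a two-tissue irreversible system the slope
equals the net influx constant Ki = K₁k₃/(k₂+k₃), which is the package's
ground truth in tests.

**Cerebral metabolic rate.** CMR = (K × Cp) / LC, with Cp the plasma
concentration of the cold substrate (µmol/mL) and LC the lumped constant
(0.8 for FDG/glucose, 1.0 for acetoacetate), scaled to the conventional
µmol/100 g/min.

**Müller-Gärtner partial-volume correction.** At PET resolution, activity
spills between gray matter, white matter and CSF. Using the T1w tissue maps
and the scanner PSF: corrected = (PET − wm_ref·smooth(WM)) / smooth(GM) at
gray-matter voxels.

**Regional longitudinal statistics.** Regional means over a 43-region merged
AAL atlas; per region a linear mixed model of K against age (random intercept
per subject, maximum likelihood, Wald slope test) with Benjamini–Hochberg FDR
across the 43 regions of each tracer; and a percent-decline summary over the
significant regions.

**Associations.** HOMA-IR (glucose·insulin/22.5), cognitive composite
z-scores from population-normed scaled scores ((s−10)/3 averaged per domain),
subject averages across visits, and Pearson/linear-regression associations.

## Worked example

```r
library(dualpet)

# plasma input function (tri-exponential, peak 100 kBq/mL) and a noiseless
# tissue curve with known net influx Ki = 0.102*0.062/(0.13+0.062) = 0.03294
ipf    <- make_input_function(input_function_params(), t_end = 60, cp_met = 5.1)
tissue <- simulate_tissue_tac(ipf, compartment_params(K1 = 0.102, k2 = 0.13,
                                                      k3 = 0.062), fdg_schedule())
patlak_fit(tissue, ipf, t_star = 10)
#> Patlak fit: K = 0.03249 1/min, intercept = 0.4120, R^2 = 0.9998 (11 frames, t* = 10 min)

cmr_from_k(0.03249, cp_met = 5.1, lc = 0.8)$cmr   # glucose, 5.1 mM plasma
#> 20.71 (umol/100 g/min)

# headline decline range over the bundled longitudinal glucose K table:
# regions with a significant slope test decline 6-12% over 4 years,
# i.e. 1.5-3.0% per year
d <- percent_decline_summary(load_k_table("glucose"))
d$range_pct          #> min 6   max 12
d$annual_range_pct   #> min 1.5 max 3.0
```

The estimated K (0.03249 min⁻¹) recovers the closed-form Ki within 1.4%; the
positive intercept is the effective initial distribution volume. The
full pipeline — synthesize, partial-volume correct, fit regional K, convert
to CMR, longitudinal mixed models with FDR, association matrix — runs with

```r
run_pipeline(list(seed = 42), outdir = "out")
```

and writes deterministic TSVs (regional K/CMR per tracer, Table-style
longitudinal reports, decline summary, associations, run log), each stamped
with the resolved configuration hash.

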