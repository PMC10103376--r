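# cytocompart

Quantifying metastatic load and tumor differentiation compartments from
flow cytometry, modelling group trends with AIC evidence ratios, and
fitting signature-stratified cure-fraction survival.

## The problem

In a murine breast-cancer model, GFP-labelled tumor cells metastasize to
the lungs and infiltrate subcutaneous polycaprolactone implants. Flow
cytometry of each tissue yields, per mouse, the **metastatic load** (the
percentage of GFP+ events) and the split of GFP+ cells over four
operational differentiation compartments by Ki67 × activated caspase-3
quadrant:

* **qSC** (Ki67− aCasp3−) quiescent stem-like
* **pSC** (Ki67+ aCasp3−) proliferating stem-like
* **TA** (Ki67+ aCasp3+) transient-amplifying-like
* **TD** (Ki67− aCasp3+) terminally differentiated / apoptotic-like

This package is for analysts who need that whole chain as tested,
reusable code: comparative gating from controls, compartment
classification, trend statistics over ordered treatment groups,
single-sample gene-set signatures, and parametric survival — plus seeded
synthetic-data generators standing in for the (unpublished) raw data, so
everything runs and is verifiable offline.

## The statistics at the core

* **Gating.** FMO controls get a 3% background gate (threshold at the
  control's 97th percentile). Against a biological control, the percent
  positive comes from Overton percentile-by-percentile histogram
  subtraction when the sample's cumulative curve is uniformly shifted
  right, otherwise from the maximum-difference (Kolmogorov–Smirnov
  location) method; `select_gating_method()` encodes the dispatch.
* **Trends.** Ordered groups g = 0, 1, 2, … are modelled as
  y = f(g) + ε, ε ~ N(0, σ²), with f constant (null), linear, quadratic
  or c·e^{kg}. Models are compared by ΔAIC = AIC(null) − AIC(alt), the
  evidence ratio **ER = exp(ΔAIC/2)**, and the extra-sum-of-squares F
  test; with two groups the linear model is exactly the pooled t test.
* **Descriptive fits.** Normal, uniform, triangular, exponential and a
  bounded power law with CDF ((x−μ)/(x_max−μ))^{a+1}; spread as range or
  0.5% trimmed range; SEs by ML or parametric (percentile) bootstrap.
* **Survival.** Actuarial life tables and the plateau-exponential model
  S(t) = π + (1−π)·2^{−t/t½} (plateau π = cure fraction, half-life t½),
  with stratified-versus-pooled comparison (ΔAIC/ER, extra-SS F,
  log-rank).
* **Signatures.** Rank-normalized single-sample gene-set enrichment
  scores, quartile binning across samples, and the quartile-pair logic
  (Q1,Q1)→qSC, (Q1,Q2–4)→pSC, (Q2–4,Q2–4)→TA, (Q2–4,Q1)→TD.

## Worked example

Simulate the default four-group cohort (control surgery, plain implant,
VEGF-enriched implant, tumor-free VEGF arm; 5/5/7/3 mice, 10⁵ events per
sample), gate it, and test the load trend:

```r
library(cytocompart)

spec   <- cohort_spec(events_per_sample = 1e5, seed = 20230413L)
cohort <- generate_flow_cohort(spec)
bio    <- cohort$controls$biological

sel <- gate_set("GFP", max(bio$channels$GFP), "max-difference")
ki  <- fmo_background_gate(cohort$controls$fmo_Ki67,  "Ki67")
ac  <- fmo_background_gate(cohort$controls$fmo_aCasp3, "aCasp3")

profiles <- do.call(rbind, lapply(cohort$samples, function(s) {
  keep <- s$channels$GFP > sel$threshold
  gfp  <- if (any(keep)) event_table(s$channels[keep, , drop = FALSE],
                                     s$sample_id, tissue = s$tissue,
                                     group = s$group, mass = s$mass)
  classify_compartments(gfp, ki, ac,
                        gfp_load = metastatic_load(s, sel))$profile
}))
profiles$group <- cohort$truth$group

means <- tapply(profiles$gfp_load,
                factor(profiles$group, unique(profiles$group)), mean)
round(means, 3)
#>   control       pcl  pcl-vegf vegf-only
#>     0.332     0.143     0.829     0.005

round(relative_difference(means[1:3]), 1)
#>  control      pcl pcl-vegf
#>      0.0    -56.8    149.6

tumor <- profiles[profiles$group != "vegf-only", ]
g <- as.integer(factor(tumor$group, unique(tumor$group))) - 1
compare_models(fit_trend(g, tumor$gfp_load, "quadratic"),
               fit_trend(g, tumor$gfp_load, "constant"))
#> <model_comparison> quadratic vs constant: dAIC=0.9433 ER=1.603 F(2,14)=2.362 p=0.1306
```

Reading the output: the measured group means say the plain implant
lowered the mean lung load of this simulated cohort by 57% while VEGF
enrichment raised it by 150% (at n = 5–7 mice these relative differences
swing widely between seeds); the V-shaped pattern is summarized by the
quadratic-versus-flat comparison, whose evidence ratio of 1.6 means the
trend is only weakly supported at this cohort size. The same functions
applied to the expression and survival generators reproduce the signature
and cure-fraction analyses; the numbered scripts under `analysis/` run
each stage end to end and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_gate_and_quantify.R
Rscript analysis/03_trends_and_spreads.R
Rscript analysis/04_signatures.R
Rscript analysis/05_survival.R
Rscript analysis/06_report.R   # one-shot seeded pipeline + manifest
```

See `vignettes/methods.Rmd` for the models, their assumptions, the
defaults and their rationale, and known limitations.

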