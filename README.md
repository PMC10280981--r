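# npsmap

Neuropsychiatric symptoms (NPS) — depression, apathy, agitation, psychosis
and their kin — cut across neurodegenerative and cerebrovascular disease.
`npsmap` is an R package for studying how informant-rated NPS relate to
structural brain measures across five diagnostic cohorts (AD/MCI, ALS, FTD,
PD, CVD). It is aimed at researchers working with harmonized multi-cohort
tabular data: NPI-Q questionnaires, FreeSurfer cortical thickness
(Desikan-Killiany, 68 regions) and regional white matter hyperintensity
(WMH) volumes.

The package implements the full analysis chain as reusable, tested
functions:

* **NPI-Q subsyndrome scoring** — the 12 item severities (0–3) are summed
  into the four EADC subsyndromes: hyperactivity (agitation, euphoria,
  irritability, disinhibition, aberrant motor), psychotic (hallucinations,
  delusions, night-time behaviours), affective (depression, anxiety) and
  apathy (apathy, appetite), plus total severity/distress and a 0–4
  vascular-risk burden count.
* **WMH normalization** — periventricular and deep lesion parcels are
  combined per region × hemisphere and corrected for head size as
  `log((x / STTIV) + 0.0001)`, where STTIV is the supratentorial total
  intracranial volume.
* **Contingency comparisons** — per-symptom Pearson chi-square tests across
  the five groups (denominators recovered from printed *count (percent)*
  cells as `round(100·count/percent)`), pairwise two-sided Fisher exact
  tests, and the age/sex-adjusted standardized association between
  vascular-risk burden and total WMH load.
* **Consensus elastic net** — for each subsyndrome, the model
  `subsyndrome ~ sex + age + MoCA + 68 thickness + 10 WMH` (82 predictors)
  is fit as a LASSO (`alpha = 1`) over repeated stratified 75/25
  train/test splits. Each of 500 repeats records the penalty `lambda`
  minimizing held-out MSE on a shared grid that includes a large sentinel
  (`lambda = 1000`, the intercept-only model); lambdas winning ≥ 5 % of
  repeats are refit on the full sample, giving a coefficient table whose
  columns are the retained lambdas with their occurrence counts.
* **Partial least squares correlation (PLSc)** — the SVD of the z-scored
  cross-block covariance `R = X'Y/(n−1)` between the four subsyndrome
  scores and the 82 predictors yields paired saliences and singular values;
  component significance is assessed by permutation of the outcome rows
  within sex-by-dx strata, and contributor stability by stratified
  bootstrap ratios (BSR = salience / bootstrap SE, |BSR| ≥ 2 "stable").
* **Synthetic cohorts** — a seeded generator reproduces the study's
  sex-by-dx margins (N = 490) and per-cohort age/MoCA distributions, with
  log-normal WMH volumes and plantable linear effects from any predictor to
  any subsyndrome, enabling null calibration and parameter-recovery
  studies. `run_pipeline()` orchestrates everything end to end.

## Worked example

Generate a cohort with one planted effect (thicker right pars triangularis
→ higher hyperactivity, standardized β = 0.5), then run the two core
analyses:

```r
library(npsmap)

spec   <- plant_effect(cohort_spec(seed = 1),
                       "thk_rh_parstriangularis", "hyperactivity", 0.5)
cohort <- normalize_wmh(score_npiq(generate_cohort(spec)))
design <- build_design(cohort, "hyperactivity")

fit <- consensus_enet(design, enet_config(repeats = 100, seed = 1))
fit
#> Consensus elastic net for subsyndrome: hyperactivity
#>   n = 490, repeats = 100, alpha = 1, selection = test
#>   retained lambdas (>= 5 wins): 0.1783, 0.1625, 0.148, 0.1349, 0.1229, ...
#>   selected variables (11): thk_lh_lingual, thk_lh_middletemporal, ...
```

The planted column is among the selected variables at every retained
non-sentinel lambda. The PLSc finds one interpretable component:

```r
Y    <- as.matrix(cohort[paste0("sub_", names(npiq_subsyndromes()))])
pf   <- plsc(design$x, Y)
plsc_permutation(pf, design$strata, n_perm = 1000, seed = 1)
#>   component singular_value        p
#> 1         1         0.6143 0.000999
#> 2         2         0.4222 0.428600
#> 3         3         0.3878 0.185800
#> 4         4         0.3393 0.243800

boot <- plsc_bootstrap(pf, design$strata, n_boot = 500, seed = 1)
head(stable_contributors(boot, component = 1, threshold = 2, block = "x"), 5)
#> thk_rh_parstriangularis  thk_lh_posteriorcingulate  thk_lh_superiorparietal
#>                    6.46                       2.85                     2.81
#>   thk_lh_middletemporal            thk_rh_fusiform
#>                    2.76                       2.61
```

Component 1 carries 45.9 % of the cross-block covariance and is the only
one with a permutation p below 0.05 (0.000999 = 1/1001, the smallest value
1000 permutations can produce); the planted region is its strongest stable
contributor (BSR 6.46).

The contingency side works directly from printed count/percent tables:

```r
rep <- chi2_frequency_report(nps_frequencies())
rep[rep$symptom == "anxiety", 1:4]
#>  symptom     chi2 df           p
#>  anxiety 22.94308  4 0.000129985
fisher_pairwise("agitation", "FTD", "PD")$p.value
#> [1] 0.003181781
```

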