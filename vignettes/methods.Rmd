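---
title: "Methods: subsyndrome scoring, consensus elastic net and PLSc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subsyndrome scoring, consensus elastic net and PLSc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npsmap)
```

`npsmap` relates informant-rated neuropsychiatric symptoms to cortical
thickness and white matter hyperintensity (WMH) burden across five
diagnostic cohorts (AD/MCI, ALS, FTD, PD, CVD). This vignette documents the
statistical procedures, the choices that were genuinely open, and what the
synthetic-data experiments do and do not establish.

## Scoring and normalization

The NPI-Q records severity (0–3) and study-partner distress (0–5) for 12
symptom domains. Subsyndrome scores are plain sums of member-item
severities — hyperactivity over 5 items (maximum 15), psychotic over 3
(maximum 9), affective and apathy over 2 each (maximum 6) — so the total
severity always equals the sum of the four composites. Night-time
behaviours are grouped with hallucinations and delusions in the psychotic
cluster; EADC variants differ on this point and the package follows the
grouping used in the five-cohort study it implements. A symptom's absence
is represented by severity 0; distress can be positive only for a present
symptom. Partially missing questionnaires are rejected by default because
a sum over missing items silently changes the composite's scale;
`skip_missing = TRUE` scores missing items as 0, which is the conservative
reading of an informant leaving a row blank.

Regional WMH volumes (frontal, parietal, temporal, occipital, basal
ganglia/thalamus, per hemisphere) are the sums of periventricular and deep
lesion parcels. Head-size correction is

> corrected = log((x / STTIV) + 0.0001)

with x the raw regional volume (mm³) and STTIV the supratentorial total
intracranial volume (mm³). The additive constant applies to the volume
*fraction*, so the transform is invariant to rescaling both x and STTIV by
a common factor, bounded below by log(10⁻⁴) ≈ −9.21 (attained exactly at
x = 0), and strictly increasing in x. The log base is natural by default;
a base-10 switch is provided because every downstream analysis
(standardized regression, z-scored PLSc) is invariant to the constant
factor between the two, and the choice is recorded in the output metadata.

## Contingency comparisons from printed tables

Published frequency tables print *count (percent)* cells with per-symptom
denominators that vary with questionnaire completeness. The denominator is
recovered as `round(100·count/percent)`; a reconstruction that cannot
reproduce the printed percentage within 0.05 points raises a warning
rather than an error, since printed values are themselves rounded. Group
differences use the Pearson chi-square statistic Σ(O−E)²/E with **no
continuity correction** — the uncorrected statistic is what reproduces the
published five-group values. Pairwise contrasts use the two-sided Fisher
exact test under the probability-mass convention (sum of all tables with
the observed margins whose probability does not exceed the observed
table's, ties within relative 10⁻⁷), which is the convention of mainstream
statistical software. Two published pairwise rows (apathy FTD > ALS,
euphoria FTD > PD) are not consistent with Fisher tests on the
reconstructed denominators; `fisher_flag_discrepancies()` reports the
recomputed values and flags those rows instead of matching them.

The vascular analysis regresses head-size-corrected log total WMH load on
the 0–4 vascular-risk burden count with age and sex as covariates; outcome
and exposure are z-scored so the exposure coefficient is a standardized β,
with a t-based 95 % interval.

## Consensus elastic net

For each subsyndrome the design holds 82 predictors: female and male
indicators (both retained; the penalized fit tolerates the collinearity and
published coefficient tables list both), age, MoCA, 68 Desikan-Killiany
thickness values and 10 normalized WMH values. Each of `repeats` (default
500) iterations draws a stratified 75/25 train/test split. Within each
sex-by-dx stratum, largest-remainder rounding fixes the train count so the
overall training size equals `round(0.75·n)` exactly (remainder ties broken
by stratum order); for the default margins this gives 368 of 490. The LASSO
path (`alpha = 1`, glmnet's coordinate descent) is fit on the training
split over a **shared** penalty grid and the repeat records the grid lambda
minimizing mean squared error on the held-out quarter, ties broken toward
the larger (more parsimonious) lambda.

Two genuinely open choices deserve a note:

* **Shared vs per-repeat grid.** Tabulating lambda frequencies over 500
  repeats is only well defined when every repeat selects from the same
  candidate set; data-driven per-repeat grids almost never repeat a value
  exactly. The package therefore computes one grid from the full sample —
  100 log-spaced values from λ_max (the smallest lambda zeroing every
  coefficient) down to 10⁻⁴·λ_max — and appends an explicit sentinel
  λ = 1000 so the intercept-only consensus is representable. The sentinel's
  full-sample fit has intercept equal to the outcome mean and all
  coefficients exactly zero.
* **Test-split vs internal-CV winner.** The per-repeat lambda can be
  defined either by the held-out 25 % (every grid value refit on the 75 %
  and evaluated on the test split) or by the internal 10-fold stratified
  cross-validation on the training split. Both are implemented
  (`selection = "test"` / `"cv"`); `"test"` is the default because the
  consensus is explicitly built from "the lowest MSE from the test step".
  The internal CV is computed by an explicit stratified k-fold loop rather
  than `cv.glmnet`, which silently drops grid values that some folds do not
  reach.

Lambdas winning at least `ceiling(0.05·repeats)` repeats are retained — a
deterministic reading of "approximately 5 % of the time" — and refit on the
full sample. Coefficients are reported on the original predictor scale
(matching published tables), with the standardized scale also available.
If nothing reaches the threshold the five most frequent lambdas are
reported with a warning. Convergence uses glmnet's `thresh = 10⁻⁹`;
the OLS-equivalence test tightens it to 10⁻¹² to compare the unpenalized
end of the path with `lm` at 10⁻⁶.

## Partial least squares correlation

Both blocks are column-wise z-scored (mean 0, SD 1) — the behavioural-PLS
convention, required for comparability of saliences across mixed-unit
predictors — and the SVD of R = X'Y/(n−1) provides saliences U, V and
singular values s₁ ≥ … ≥ s₄. Variance explained defaults to
s_i²/Σs_j² (squared singular values, the standard choice); a raw-singular-
value base is available as a switch. Signs are fixed by making the
largest-magnitude entry of each outcome salience non-negative, which makes
the fit deterministic; latent scores satisfy cov(Lx_i, Ly_i) = s_i.

**Permutation.** Outcome rows are permuted within sex-by-dx strata (cell
compositions preserved exactly, mirroring the split policy), the fit is
recomputed, and each observed s_i is compared with the same-index null
s_i — no Procrustes rotation of the null samples, the simplest defensible
statistic (a rotation option could be added, but same-index comparison is
the default precisely because it requires no alignment choices).
P-values use the add-one formula (1 + #{null ≥ observed})/(1 + n_perm), so
the smallest attainable p is 1/(n_perm+1). Defaults: n_perm = 5000
(configurable; the study's printed component p-values imply at least a few
thousand but state no count).

**Bootstrap.** Rows are resampled with replacement within strata; each
replicate is re-z-scored and refit, then aligned to the original fit by
greedy maximal-|correlation| matching of the stacked [U; V] columns with
sign flips. The bootstrap ratio is the **original** salience divided by the
standard deviation of the aligned replicate saliences (not the bootstrap
mean divided by its SE). Replicates where a column degenerates to zero
variance are dropped; more than 10 % dropped is an error. |BSR| ≥ 2 marks a
stable contributor, the conventional threshold. Default n_boot = 1000.

## The synthetic cohort generator

The generator is the package's test bed and defines the conditions under
which every calibration and recovery experiment runs. It reproduces the
study's modelling sample exactly where the study prints it: sex-by-dx cell
counts (52/65, 16/23, 19/32, 31/107, 46/99; N = 490) are fixed margins,
never sampled; age, education and MoCA are drawn per cohort from the
published means and SDs (MoCA rounded and clamped to 0–30). Where the
study prints no value, defaults are chosen for realism and held fixed:
baseline thickness per Desikan-Killiany region around published normative
magnitudes (SD 0.15 mm) with a mild global offset of −0.15 mm in AD/MCI
and FTD; per-hemisphere WMH volumes log-normal (σ_log = 1.1) with
location offsets ordered so CVD is highest; STTIV normal
(1.45×10⁶ ± 1.4×10⁵ mm³); vascular-flag prevalences per cohort from the
published percentages.

NPI-Q items arise from a latent-propensity model: each subsyndrome's
propensity is its baseline plus Σβ·z(predictor) over planted effects plus
N(0, noise_sd = 1); each member item's severity is
clip(round(latent/k + N(0, 0.5)), 0, 3) with k the number of items, which
preserves the summation identity that scoring relies on. Predictors named
`wmh_*` enter effects on the head-size-corrected log scale (the scale on
which they are analysed); everything else is z-scored as-is. With an empty
effect list every predictor-outcome association is chance-level, giving
null cohorts for calibration.

What the generator does **not** emulate: spatially correlated thickness
(regions are independent given dx), longitudinal visits, realistic
missingness mechanisms (an optional missing-at-random MoCA rate is the only
hook), diagnosis-specific symptom profiles beyond the latent baselines, and
any image-level artefact. Passing recovery tests therefore show that the
machinery is calibrated and can find planted linear structure at realistic
n — not that the published real-data coefficient values are recoverable,
which they are not without the raw data.

## Problem sizes and numerical tolerances in the test suite

The suite checks calibration at sizes chosen to keep a full run in a few
minutes on one CPU: permutation type-I error over 200 null cohorts of
N = 490 with 1000 permutations each (component-1 rejection at α = 0.05
expected in [0.03, 0.07]); consensus recovery of a planted standardized
thickness effect of 0.5 over 20 seeds at 100 repeats; bootstrap-ratio
recovery over 100 seeds at 500 replicates; smaller property loops (40–200
seeds) for generator nulls and skewness. Orthonormality and oracle
equivalences are asserted at 10⁻⁸, variance-sum at 10⁻⁶, closed-form
chi-square agreement at 10⁻¹⁰, Fisher-vs-enumeration at the tie tolerance
10⁻⁷. One spec-level expectation was corrected against order statistics:
with 328 null correlations at n = 490 the maximum |r| predictably exceeds
0.15 in roughly a quarter of cohorts, so the null-cohort test bounds the
maximum at 0.2 (analytic exceedance ≈ 0.3 %) and the pooled per-pair
exceedance of 0.15 at 1 %.

## Known limitations

* The consensus procedure's selected-variable sets inherit LASSO's
  instability under strong predictor correlation; the retention rule
  aggregates over splits but does not remove this.
* Bootstrap ratios for components whose direction is weakly identified
  (singular values close together) are optimistic, because sign/order
  alignment removes part of the sampling variability; interpret BSRs only
  for components that pass the permutation test.
* Reconstructed denominators are exact only when the printed percentage
  has enough digits; with one decimal the reconstruction is unique for the
  group sizes involved here but need not be in general.
* The pipeline models complete cases only; it drops and counts incomplete
  rows rather than imputing.
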