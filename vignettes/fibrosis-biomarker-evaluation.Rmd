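---
title: "Evaluating noninvasive liver fibrosis scores with fibroscores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating noninvasive liver fibrosis scores with fibroscores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscores)
library(dplyr)
```

## The problem

Advanced liver fibrosis (histological stage F3–F4) drives most of the excess
mortality in nonalcoholic fatty liver disease, and guidelines recommend
first-line screening with composite blood scores rather than biopsy. The
catch is that several widely used scores — most prominently the NAFLD
Fibrosis Score (NFS), but also BARD and FIB-C3 — contain body mass index as a
predictor, so their fixed cutoffs misbehave in the populations where NAFLD
screening matters most: obese and morbidly obese patients. `fibroscores`
packages the full evaluation workflow for this setting: the score
calculators themselves, the diagnostic-accuracy statistics used to judge
them, BMI-stratified cutoff derivation with a derivation/validation split,
sequential two-test triage, and a synthetic cohort generator so that every
step is runnable and testable without access to patient data.

## Scores and their inputs

Eight composite scores are implemented. Four are closed forms of routine
measurements:

* **FIB-4** `= age × AST / (platelets × √ALT)`
* **NFS** `= −1.675 + 0.037·age + 0.094·BMI + 1.13·(IFG or diabetes) +
  0.99·AST/ALT − 0.013·platelets − 0.66·albumin` (albumin in g/dL)
* **APRI** `= 100 × (AST/ULN) / platelets` (AST upper limit of normal
  defaults to 40 U/L, configurable)
* **BARD**: BMI ≥ 28 kg/m² → 1 point, AST/ALT ≥ 0.8 → 2 points,
  diabetes → 1 point.

The other four (HFS, ADAPT, FIB-C3, MACK-3) are regression scores whose
coefficients come from their source publications. They are deliberately not
hard-coded: `score_coefficients()` reads a versioned YAML config in which
every block carries a provenance string, so the transcription is auditable
and a locally validated coefficient set can be dropped in. The MACK-3 block
is explicitly flagged in its provenance string as the one transcription we
could not cross-verify against a second source; its structural behaviour
(logistic range, monotonicity, cutoff classification) is tested, but
absolute MACK-3 values should be treated as provisional.

Units are a real hazard here: NFS and HFS are defined on albumin in g/dL
while clinical chemistry in much of Europe reports g/L. `read_cohort()`
therefore normalizes declared units once at ingestion (g/L → g/dL ÷ 10;
mg/dL glucose → mmol/L ÷ 18.016), and everything downstream assumes
canonical units. Conversion is idempotent, and a record missing an input to
a given score yields a missing score rather than an imputed one — per-score
complete-case analysis, matching how such cohorts are reported.

Where a cohort has no explicit impaired-fasting-glucose flag, we flag IFG
at fasting glucose ≥ 5.6 mmol/L (the ADA threshold); this choice is
configurable because source publications rarely state their
operationalization.

## Diagnostic accuracy machinery

`dx_metrics()` computes sensitivity, specificity and predictive values with
exact Clopper–Pearson 95% intervals (chosen for reproducibility and
conservatism; the CI method behind published tables of this kind is rarely
stated), likelihood ratios, and the number needed to diagnose
(`1/(Se+Sp−1)`). Two conventions deserve comment:

* **Integer-percent likelihood ratios.** Published tables often derive
  their LR columns from the printed whole-percent Se/Sp rather than the
  underlying fractions (e.g. Se 79%, Sp 87% → LR+ 6.08, NND 1.5). The
  `lr_mode = "integer_percent"` option reproduces this exactly, with
  half-away-from-zero rounding; `"raw"` is the analytic default.
* **Indeterminate-as-correct.** For dual-cutoff tests,
  `combined_dual_metrics()` counts gray-zone subjects as true
  positives/negatives — the convention used when the gray zone is assumed
  to be resolved by biopsy. `dual_cutoff_performance()` instead evaluates
  each cutoff as a binary test (≥ lower positive; > upper positive) and
  reports the indeterminate fraction.

Cutoff boundary conventions follow the published application tables: the
rule-out screen is positive at or above the lower cutoff (rows printed
"≥ c"), the rule-in test strictly above the upper cutoff (rows printed
"> c"), and boundary values fall in the indeterminate zone. Single-cutoff
rules classify high at or above the cutoff. Age-adjusted lower cutoffs
(FIB-4 2.0, NFS 0.12) replace the standard lower cutoff at age ≥ 65.

ROC analysis is rank-based: the AUROC is the tie-corrected Mann–Whitney
statistic (ties count ½), confidence intervals and paired comparisons use
the DeLong structural-components estimator, and both are verified in the
test suite against brute-force pair enumeration, a permutation oracle, and
the independent `pROC` implementation. Perfect separation in both arms
makes the DeLong variance zero; such comparisons are flagged `degenerate`
rather than returning a spurious p-value.

The **Obuchowski measure** generalizes the AUROC to the ordinal F0–F4
scale: over all subject pairs with different stages, a pair scores 1 if the
biomarker ranks them concordantly with stage, ½ if tied, 0 otherwise, and
pairs are weighted by 0.25 per unit of stage difference. Because the
measure is defined here as the weighted mean pair score, the 0.25 scale
factor cancels in the normalization — only the proportionality of weight to
stage separation matters — and with exactly two stages the measure reduces
to the AUROC. The confidence interval is a leave-one-out jackknife
(computed in O(n²) via per-subject pair totals); the CI method behind
published Obuchowski values is generally unstated, so this choice is ours.

Rate comparisons use the exact McNemar test (binomial test on discordant
pairs, p = 1 when there are none) for paired designs and Pearson's
chi-squared otherwise. Predictive values of paired tests are compared with
a weighted generalized score statistic: under the null a common predictive
value (weighted by each test's number of qualifying subjects) replaces the
two estimates, and the squared difference over its robust per-subject score
variance is referred to χ²₁. The test suite checks it against a
subject-resampling bootstrap.

## BMI-stratified cutoff derivation

`derive_bmi_cutoffs()` reproduces the derivation design: subjects are
assigned to half-open BMI bands (nonobese < 30, obese 30–39.9, morbidly
obese ≥ 40 kg/m²), split 70:30 into derivation and validation sets within
each band — stratified on case status, so prevalence is preserved to within
one subject; stratification is our design choice, for stability at low
case counts — and three cutoffs are selected per band on the derivation
data:

* the **best single** cutoff maximizes Youden's index;
* the **rule-out** cutoff is the largest candidate with sensitivity ≥ 0.85;
* the **rule-in** cutoff is the smallest candidate with specificity ≥ 0.95.

The 85%/95% anchors are operationalized as floor constraints (optimize the
other coordinate subject to the floor) because at a planning prevalence of
15% they guarantee NPV ≥ 95%, PPV ≥ 75% and accuracy ≥ 90% by Bayes'
rule — run `predictive_values_at_prevalence(0.85, 0.95, 0.15)` to see the
identity. Candidate cutoffs are midpoints between adjacent distinct
observed scores (plus ±∞), which makes the selection invariant to strictly
increasing transforms and independent of ≥-versus-> conventions at the
selected value. Ties are broken toward the lower cutoff. One edge case is
worth knowing: when the Youden-optimal cutoff itself has sensitivity above
the 0.85 floor, the rule-out cutoff can sit one candidate step above the
best-single cutoff, so `rule_out ≤ best_single` holds in the typical
regime but is not a theorem.

Published BMI-adjusted NFS cutoffs (−2.022/0.326/−1.309; −1.083/1.076/
−0.438; 0.544/2.054/0.544) are data-dependent values from restricted
cohorts and are not re-derivable here; `validate_cutoffs()` applies any
such set to a cohort and emits the zone-count and metric report in the
shape of the published application tables.

## Sequential triage

`sequential_classify()` implements the two-stage algorithm: a dual-cutoff
first test (FIB-4 by default, age-adjusted lower cutoff applied at ≥ 65)
whose low/high calls are final, with only gray-zone subjects taking the
second, binary test (ADAPT 6.3287, FIBC3 0.4, HFS 0.12, or the
BMI-adjusted NFS rule-out cutoffs per band). The second stage can only
relabel first-stage indeterminates, which yields two monotone properties
verified on synthetic cohorts: sequential specificity is at least that of
the first test's lower cutoff alone, and sequential sensitivity at most.
`sequential_performance()` additionally reports the false-positive
(unnecessary-referral) reduction against the first test alone.

## The synthetic cohort generator

Because the motivating cohorts are access-restricted, `generate_cohort()`
provides the test bed. It draws fibrosis stage from a configurable
prevalence vector and then generates analytes conditionally on stage:
log-normal AST, ALT, insulin, PRO-C3 and CK-18 with stage-increasing
location (right-skewed, as these analytes are), truncated-normal platelets
with stage-decreasing mean, truncated-normal albumin and glucose, diabetes
as a logistic function of BMI and stage, and a NASH/NAS model conditional
on stage. AST and ALT share a latent log-normal factor so the AST/ALT
ratio — which BARD and FIB-4 exploit — has realistic behaviour; all other
analytes are conditionally independent given stage, BMI and diabetes, the
simplest structure that preserves what the scores use.

Three presets (`overweight_obese`, `hepatology_lean`, `elevated_risk`)
emulate the marginal structure of a bariatric-surgery referral cohort
(median BMI ≈ 40 kg/m², advanced fibrosis ≈ 7%), a leaner hepatology cohort
(median BMI ≈ 28, ≈ 12%), and an older high-prevalence biopsy cohort
(≈ 56%). Stage effect sizes default to values placing FIB-4's AUROC for
advanced fibrosis at ≈ 0.85–0.9 on the overweight/obese preset, the regime
reported for real cohorts of this kind; they are fully configurable, and
doubling them demonstrably raises the AUROC (a monotone signal-response
property in the test suite). The presets generate PRO-C3 and CK-18 in every
cohort even though leaner published cohorts often lack them, because the
downstream pipelines need complete panels; per-analyte missingness rates
can be set in the spec. What passing tests on these cohorts shows is that
the statistical machinery recovers designed-in signal; they say nothing
about the real joint distribution of analytes, whose correlations beyond
the AST–ALT coupling are not modelled.

```{r generator-demo}
coh <- generate_cohort(cohort_preset("overweight_obese", n = 1000, seed = 1))
panel <- score_panel(coh)
lab <- target_label(panel, "advanced_fibrosis")
ok <- !is.na(panel$fib4)
glance(roc_curve(panel$fib4[ok], lab[ok]))
```

## Numerical choices and degenerate inputs

* Proportion CIs: Clopper–Pearson via the beta closed form; zero
  denominators give `NA` metrics rather than NaN; NND is `NA` when
  Youden ≤ 0.
* ROC ties count ½ everywhere (AUROC, DeLong placements, Obuchowski).
* Rounding to printed percentages is half-away-from-zero
  (`round_half_up()`), since base R's `round()` is round-half-even.
* Degenerate inputs error early with informative messages: one-class
  labels for ROC/derivation, all-equal stages for the Obuchowski measure,
  zero ALT or platelets in score formulas (a domain error, not infinity).
* Splits and cohorts are pure functions of their seeds (`withr`-scoped
  RNG, inverse-CDF truncated sampling), so every pipeline stage is
  bit-reproducible.

## Problem sizes used in the shipped checks

The test suite exercises the oracle equivalences at the scales where
exhaustive enumeration is exact and fast (AUROC vs pair counting at
n ≤ 200; Obuchowski vs full pair enumeration at n ≤ 50; cutoff derivation
vs exhaustive candidate search at n ≤ 100; permutation and bootstrap
oracles at a few thousand resamples), and the parameter-recovery and
sequential-monotonicity properties on synthetic cohorts of 2000 subjects
per BMI band across 20 seeds. These sizes were chosen to make the binomial
sampling bands tight enough to be informative while keeping the whole
suite comfortably fast on a laptop.

## Known limitations

* HFS/ADAPT/FIBC3/MACK-3 coefficients are transcriptions; MACK-3's is
  flagged as unverified in its provenance string.
* The generator models conditional independence given stage/BMI/diabetes
  (plus the AST–ALT coupling); real analyte correlations are stronger.
* Published BMI-adjusted cutoff values themselves are not re-derivable
  without the restricted cohorts; the package derives cutoffs *by the same
  procedure* on data you supply.
* Elderly-specific (age ≥ 65) cutoff derivation is not attempted; the
  published age-adjusted lower cutoffs are applied at classification time
  instead.
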