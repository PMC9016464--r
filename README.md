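# fibroscores

Noninvasive blood-based scoring is the recommended first-line screen for
advanced liver fibrosis (histological stage F3–F4) in nonalcoholic fatty
liver disease, but several of the standard scores embed body mass index in
their formulae and lose specificity exactly where screening matters most —
in obese and morbidly obese patients. `fibroscores` is an R package for
clinical researchers evaluating these scores: it computes the eight common
composite scores, provides the full diagnostic-accuracy toolkit used to
judge them, derives and validates BMI-stratified cutoffs, evaluates
sequential two-test triage algorithms, and ships a synthetic cohort
generator so the entire pipeline runs without access to patient data.

## What it computes

**Scores** (`score_panel()` and individual calculators): FIB-4
(`age×AST/(platelets×√ALT)`), NFS (linear in age, BMI, IFG/diabetes,
AST/ALT, platelets, albumin), APRI, BARD, and the regression scores HFS,
ADAPT, FIB-C3 and MACK-3, whose coefficients live in a provenance-stamped,
overridable YAML config. HOMA-IR is `glucose (mmol/L) × insulin (mU/L) /
22.5`.

**Diagnostics** (`dx_metrics()`, `roc_curve()`, `delong_test()`,
`obuchowski()`, `compare_rates()`, `compare_predictive_values()`):
Se/Sp/PPV/NPV with exact Clopper–Pearson CIs, likelihood ratios
(`LR+ = Se/(1−Sp)`, `LR− = (1−Se)/Sp`), number needed to diagnose
(`1/(Se+Sp−1)`), tie-corrected Mann–Whitney AUROC with DeLong variance and
paired AUROC comparison, the stage-weighted Obuchowski measure with
jackknife CI, exact McNemar / chi-squared rate comparisons, and a weighted
generalized score test for paired predictive values.

**Cutoffs and triage** (`classify_dual()`, `derive_bmi_cutoffs()`,
`validate_cutoffs()`, `sequential_classify()`): dual-cutoff rules with
indeterminate zones and age-adjusted thresholds; per-BMI-band 70:30
derivation/validation with a Youden-optimal best-single cutoff, a rule-out
cutoff constrained to sensitivity ≥ 85% and a rule-in cutoff constrained
to specificity ≥ 95% (at 15% prevalence these anchors guarantee NPV ≥ 95%,
PPV ≥ 75%, accuracy ≥ 90% — see
`predictive_values_at_prevalence(0.85, 0.95, 0.15)`); and two-stage
algorithms in which a second test resolves only the first test's gray
zone.

## Worked example

```r
library(fibroscores)
library(dplyr)

coh   <- generate_cohort(cohort_preset("overweight_obese", n = 2000, seed = 42))
panel <- score_panel(coh)
lab   <- target_label(panel, "advanced_fibrosis")

ok <- !is.na(panel$fib4)
roc_curve(panel$fib4[ok], lab[ok])
#> <roc_curve> AUROC 0.8741 (95% CI 0.8469-0.9013); 143 cases / 1842 controls

combined_dual_metrics(panel$fib4, lab, published_cutoff_rules()$fib4,
                      ages = panel$age, lr_mode = "integer_percent") |>
  select(se, sp, ppv, npv, nnd, indeterminate_fraction) |> round(3)
#>      se    sp   ppv   npv   nnd indeterminate_fraction
#> 1 0.867 0.971 0.697 0.989  1.19                  0.289
```

The ROC line says FIB-4 separates biopsy-confirmed advanced fibrosis from
the rest of this synthetic bariatric-clinic cohort with AUROC 0.87. The
second call applies the published dual cutoffs (1.3, age-adjusted 2.0, and
2.67), counting gray-zone subjects as correctly resolved by biopsy: 29% of
subjects land in the indeterminate zone, and the combined test reaches 87%
sensitivity and 97% specificity. Adding ADAPT as a second-stage test for
those gray-zone subjects:

```r
rule <- sequential_rule(published_cutoff_rules()$fib4, 6.3287, "adapt")
sub  <- panel[ok & !is.na(panel$adapt), ]
sequential_performance(sub, "fib4", "adapt",
                       target_label(sub, "advanced_fibrosis"), rule)$fp_reduction
#> [1] 0.71
```

i.e. the sequential algorithm removes 71% of the unnecessary referrals
(false positives) that the FIB-4 lower cutoff alone would generate, at the
cost of some sensitivity — the trade the triage design makes on purpose.

## Documentation

The methods vignette
(`vignettes/fibrosis-biomarker-evaluation.Rmd`) describes the statistical
model and conventions in detail: cutoff boundary and rounding conventions,
the Obuchowski normalization, the weighted generalized score test, what
the synthetic generator does and does not emulate, and known limitations
(notably that the MACK-3 coefficient transcription is flagged as
unverified in its provenance string).
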