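# Versioned coefficient tables for the composite fibrosis scores whose
# formulae are not simple closed forms of the inputs.  Each entry carries a
# provenance string naming the source publication the coefficients were
# transcribed from.  Boundary conventions for categorical terms use closed
# lower bounds (>=), as in the source publications.
version: 1
apri:
  ast_uln: 40.0
  provenance: >
    AST upper limit of normal, U/L. Default 40 U/L (common laboratory
    convention; configurable).
hfs:
  provenance: >
    Hepamet Fibrosis Score, transcribed from Ampuero et al. 2020
    (Clin Gastroenterol Hepatol 18:216-225, supplementary material).
    HFS = 1 / (1 + exp(x)); x = intercept minus the sum of the indicator
    terms below.  Higher HFS = higher fibrosis risk.
  intercept: 5.390
  terms:
    age_45_64: 0.986        # 45 <= age < 65 years
    age_ge_65: 1.719        # age >= 65 years
    male: 0.875
    ast_35_69: 0.896        # 35 <= AST < 70 U/L
    ast_ge_70: 2.126        # AST >= 70 U/L
    albumin_4_449: 0.027    # 4.0 <= albumin < 4.5 g/dL
    albumin_lt_4: 0.897     # albumin < 4.0 g/dL
    homa_2_399: 0.990       # 2 <= HOMA-IR < 4
    homa_ge_4: 1.171        # HOMA-IR >= 4
    diabetes: 0.890
    platelets_155_219: 1.119  # 155 <= platelets < 220 (10^9/L)
    platelets_lt_155: 2.233   # platelets < 155 (10^9/L)
adapt:
  provenance: >
    ADAPT, transcribed from Daniels et al. 2019 (Hepatology 69:1075-1086).
    ADAPT = exp(log10(age * PRO-C3 / sqrt(platelets))) + diabetes(0/1).
    age years, PRO-C3 ng/mL, platelets 10^9/L.
  diabetes_points: 1.0
fibc3:
  provenance: >
    FIB-C3, transcribed from Boyle et al. 2019 (JHEP Reports 1:188-198).
    Linear predictor in age (years), BMI (kg/m^2), type 2 diabetes (0/1),
    platelets (10^9/L) and PRO-C3 (ng/mL).
  intercept: -5.939
  age: 0.053
  bmi: 0.076
  diabetes: 1.614
  platelets: -0.009
  pro_c3: 0.071
mack3:
  provenance: >
    MACK-3, transcribed from Boursier et al. 2018 (Aliment Pharmacol Ther
    47:1387-1396): logistic model in HOMA-IR, AST (U/L) and CK-18 M30 (U/L).
    The intercept could not be cross-verified against an independent source;
    treat absolute MACK-3 values from this config as provisional and
    override with a locally validated transcription for clinical use.
  intercept: -5.655
  homa_ir: 0.12644
  ast: 0.0433
  ck18_m30: 0.0033
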