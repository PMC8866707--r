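# SYNTHETIC pooled-cohort-equation coefficient set -- NOT FOR CLINICAL USE.
#
# Placeholder coefficients with a plausible sign/transform structure for the
# revised (logistic) model form: risk increases with age, systolic blood
# pressure, total cholesterol, diabetes and smoking, and decreases with
# HDL-C. Magnitudes are invented; they produce 10-year risks in a realistic
# 0.1%-40% range for adult covariate profiles, which is all the pipeline
# needs (risk scores are used only to rank participants into vigintiles).
# No race term (see package documentation).
label: synthetic-revised-pce
model_form: revised-logistic
clinical_use: false
sexes:
  male:
    intercept: -20.1
    terms:
      - {covariate: age, transform: log, coefficient: 2.30}
      - {covariate: tc, transform: log, coefficient: 0.65}
      - {covariate: hdl, transform: log, coefficient: -0.85}
      - {covariate: systolic_bp, transform: log, coefficient: 1.85, interact_with: bp_treated}
      - {covariate: systolic_bp, transform: log, coefficient: 1.70, interact_with: bp_untreated}
      - {covariate: diabetes, transform: identity, coefficient: 0.70}
      - {covariate: smoker, transform: identity, coefficient: 0.65}
  female:
    intercept: -21.9
    terms:
      - {covariate: age, transform: log, coefficient: 2.50}
      - {covariate: tc, transform: log, coefficient: 0.70}
      - {covariate: hdl, transform: log, coefficient: -0.95}
      - {covariate: systolic_bp, transform: log, coefficient: 2.00, interact_with: bp_treated}
      - {covariate: systolic_bp, transform: log, coefficient: 1.80, interact_with: bp_untreated}
      - {covariate: diabetes, transform: identity, coefficient: 0.85}
      - {covariate: smoker, transform: identity, coefficient: 0.70}
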