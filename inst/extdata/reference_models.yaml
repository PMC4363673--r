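# Packaged reference normalization models: coefficient sets fitted on a
# 32-subject healthy-control calibration cohort (30 complete cases),
# for applying the residual normalization to new cohorts without
# refitting.  Covariate units: age years, ticv mm^3,
# ap_vertebra_diameter mm, sagittal_vertebra_area mm^2; areas mm^2.
# adj_r2 null = not reported (model failed the adj R^2 > 0.35 gate).
reference_means:
  age: 48.84
  ticv: 1434165.26
  ap_vertebra_diameter: 15.63
  sagittal_vertebra_area: 199.93
models:
  - name: model1_tca_c2c3
    outcome: "C2-C3:TCA"
    coefficients: {ticv: 2.33e-05, sagittal_vertebra_area: 0.059}
    adj_r2: 0.44
    n: 30
  - name: model2_tca_c2c3
    outcome: "C2-C3:TCA"
    coefficients: {age: -0.113, ticv: 2.20e-05, ap_vertebra_diameter: 0.873}
    adj_r2: 0.41
    n: 30
  - name: model3_tca_c2c3
    outcome: "C2-C3:TCA"
    coefficients: {age: -0.105, ticv: 1.89e-05, sagittal_vertebra_area: 0.063}
    adj_r2: 0.47
    n: 30
  - name: model1_gm_c2c3
    outcome: "C2-C3:GM"
    coefficients: {ticv: 7.20e-06, sagittal_vertebra_area: 0.017}
    adj_r2: 0.42
    n: 30
  - name: model2a_gm_c2c3
    outcome: "C2-C3:GM"
    coefficients: {ticv: 7.19e-06, ap_vertebra_diameter: 0.466}
    adj_r2: 0.50
    n: 30
  - name: model3_tca_c3c4
    outcome: "C3-C4:TCA"
    coefficients: {age: -0.150, ticv: 1.17e-05, sagittal_vertebra_area: 0.080}
    adj_r2: 0.44
    n: 30
  - name: model3_tca_t8t9
    outcome: "T8-T9:TCA"
    coefficients: {age: -0.101, ticv: 6.58e-06, sagittal_vertebra_area: 0.027}
    adj_r2: 0.42
    n: 30
  - name: model3_tca_t9t10
    outcome: "T9-T10:TCA"
    coefficients: {age: -0.110, ticv: 6.36e-06, sagittal_vertebra_area: 0.037}
    adj_r2: 0.43
    n: 30
  - name: model2_tca_c3c4
    outcome: "C3-C4:TCA"
    coefficients: {age: -0.153, ticv: 1.72e-05, ap_vertebra_diameter: 0.809}
    adj_r2: 0.36
    n: 30
  - name: model2_tca_t8t9
    outcome: "T8-T9:TCA"
    coefficients: {age: -0.116, ticv: 6.52e-06, ap_vertebra_diameter: 0.709}
    adj_r2: 0.56
    n: 30
  - name: model2_tca_t9t10
    outcome: "T9-T10:TCA"
    coefficients: {age: -0.127, ticv: 6.80e-06, ap_vertebra_diameter: 0.854}
    adj_r2: 0.53
    n: 30
  - name: model2a_gm_c3c4
    outcome: "C3-C4:GM"
    coefficients: {ticv: 7.70e-06, ap_vertebra_diameter: 0.172}
    adj_r2: 0.37
    n: 30
  - name: model2a_gm_t8t9
    outcome: "T8-T9:GM"
    coefficients: {ticv: 1.84e-06, ap_vertebra_diameter: 0.143}
    adj_r2: null
    n: 30
  - name: model2a_gm_t9t10
    outcome: "T9-T10:GM"
    coefficients: {ticv: 4.77e-06, ap_vertebra_diameter: 0.191}
    adj_r2: 0.33
    n: 30
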