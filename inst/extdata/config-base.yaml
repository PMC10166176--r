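# Synthetic base case: three treatment sequences for transplant-ineligible
# newly diagnosed multiple myeloma, 15-year horizon, monthly cycles.
seed: 1
start_age: 74.1
horizon_cycles: 180
families: [exponential, weibull, loglogistic, lognormal, gompertz,
           generalized_gamma]
lifetable:
  synthetic: true
data:
  synthetic: true          # replace with `cohorts: {rd_ttnt: path.csv, ...}`
hazard_ratios:
  hr_vrd:                  # PFS HR used as the TTNT proxy for the VRd arm
    value: 0.70
    source: "VRd vs Rd PFS HR proxy"
attrition:
  drd: {numerator: 110, denominator: 368}   # predicted deaths / patients
  rd: {numerator: 90, denominator: 369}
  vrd: {numerator: 200, denominator: 737}   # pooled estimate
sequences:
  - label: "D-Rd -> Pom/Car"
    s1: drd_ttnt
    attrition: drd
    s2: pomcar_os
  - label: "VRd -> Dara"
    s1: rd_ttnt
    s1_hr: hr_vrd
    attrition: vrd
    s2: dara_os
  - label: "Rd -> Dara"
    s1: rd_ttnt
    attrition: rd
    s2: dara_os
reference: "D-Rd -> Pom/Car"
psa:
  n_draws: 1000
scenarios:
  attrition_crude_58.8:
    attrition: 0.588       # crude rate, censored patients in denominator
  attrition_excl_censored_27.2:
    attrition: 0.272       # conservative rate excluding censored patients
  vrd_hr_alternative:
    hrs: {hr_vrd: 0.76}    # alternative indirect-comparison PFS HR
  best_distributions:
    fit_choice: best       # highest restricted mean survival per cohort
  worst_distributions:
    fit_choice: worst
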