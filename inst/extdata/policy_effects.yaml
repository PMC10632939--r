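# Policy effect sizes by MPOWER component (versioned; all values overridable).
# Fractions are effect sizes: prevalence/initiation entries reduce the
# quantity by the stated fraction; cessation entries increase the cessation
# rate by the stated fraction. Price elasticities are per proportional change
# in the real (CPI-deflated) cigarette price, by age band.
version: 1
clean_air:
  workplace_complete: 0.06
  workplace_partial: 0.02
  restaurant_complete: 0.01
  restaurant_partial: 0.005
  bars_other: 0.005
cessation_treatment:
  prevalence_reduction: 0.026
  cessation_rate_increase: 0.50
  partial_fraction: 0.5
warnings:
  high: {prevalence: 0.02, initiation: 0.02, cessation: 0.04}
  low: {prevalence: 0.01, initiation: 0.01, cessation: 0.02}
  enforcement_publicity: 0.01
ad_ban:
  comprehensive: {prevalence: 0.06, initiation: 0.08, cessation: 0.03}
  complete: {prevalence: 0.04, initiation: 0.06, cessation: 0.02}
  partial: {prevalence: 0.01, initiation: 0.01, cessation: 0.0}
  enforcement_publicity: 0.01
price_elasticity:
  age_15_17: -0.4
  age_18_24: -0.3
  age_25_34: -0.2
  age_35_plus: -0.1
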