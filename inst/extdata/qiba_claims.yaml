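# QIBA DWI profile claims for phantom-based validation, transcribed from the
# published profile claim table. Boundary semantics follow the printed
# comparator exactly (<= passes at the threshold, < does not).
# The bias claim is shipped as abs <= 3.6% (the value the conformance tables
# check against); the claim-definition table also prints a looser 4% bound
# for the central tube.
version: "QIBA-DWI-2019"
claims:
  - metric: adc_bias_pct
    cmp: abs_le
    threshold: 3.6
    units: "%"
    description: "ADC bias of the central (0% PVP) vial"
  - metric: rc_short_term
    cmp: lt
    threshold: 15
    units: "um^2/s"
    description: "Short-term (intra-exam) repeatability coefficient"
  - metric: wcv_short_term
    cmp: le
    threshold: 0.5
    units: "%"
    description: "Short-term within-subject coefficient of variation"
  - metric: rc_long_term
    cmp: lt
    threshold: 65
    units: "um^2/s"
    description: "Long-term (multiday) repeatability coefficient"
  - metric: wcv_long_term
    cmp: lt
    threshold: 2.2
    units: "%"
    description: "Long-term within-subject coefficient of variation"
  - metric: r_squared
    cmp: gt
    threshold: 0.90
    units: ""
    description: "R-squared of measured ADC vs reference diffusivity"
  - metric: slope
    cmp: ci_within
    lo: 0.95
    hi: 1.05
    units: ""
    description: "95% CI of the linearity slope must lie within [0.95, 1.05]"
  - metric: max_bvalue_dependence_pct
    cmp: le
    threshold: 2
    units: "%"
    description: "Max deviation of per-b two-point ADCs from their average"
    applicability: ">= 2 nonzero b-values"
  - metric: random_error_pct
    cmp: le
    threshold: 2
    units: "%"
    description: "Within-VOI coefficient of variation of the central vial"
  - metric: snr_b0
    cmp: ge
    threshold: 45
    units: ""
    description: "b = 0 SNR of the 0% PVP vial (difference method)"
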