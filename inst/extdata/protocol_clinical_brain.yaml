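# Tiered clinical brain DWI protocol specification (ideal / target /
# acceptable). Tiers are regularised to be monotone (anything meeting ideal
# also meets target and acceptable), which the loader validates:
#   - TR: printed target "3000-5000 ms" with ideal "> 5000 ms" is encoded as
#     target >= 3000 so a longer TR cannot fail the lower tier;
#   - parallel factor: printed acceptable "2" with ideal "2-3" is encoded as
#     acceptable 2-3;
#   - highest b-value: printed acceptable "850-999" with target "1000" is
#     encoded as acceptable >= 850, target >= 1000;
#   - number of b-values: printed ideal "> 3" -> ideal >= 4, target and
#     acceptable >= 2;
#   - TE target "minimum TE" is not numerically checkable and is encoded as
#     the ideal bound (< 60 ms); acceptable < 120 ms;
#   - half-scan factor has no printed ideal tier; ideal = target.
# Missing tiers inherit downward (ideal <- target <- acceptable).
profile: clinical_brain
parameters:
  - parameter: n_bvalues
    extract: n_bvalues
    ideal: {cmp: min, value: 4}
    target: {cmp: min, value: 2}
    acceptable: {cmp: min, value: 2}
  - parameter: highest_b_value
    extract: b_max
    ideal: {cmp: min, value: 1000}
    target: {cmp: min, value: 1000}
    acceptable: {cmp: min, value: 850}
  - parameter: slice_thickness_mm
    extract: slice_thickness_mm
    ideal: {cmp: max, value: 4, strict: true}
    target: {cmp: max, value: 5}
    acceptable: {cmp: max, value: 5}
  - parameter: gap_mm
    extract: gap_mm
    ideal: {cmp: max, value: 1}
    target: {cmp: max, value: 1}
    acceptable: {cmp: max, value: 2}
  - parameter: fov_mm
    extract: fov_mm
    acceptable: {cmp: range, lo: 220, hi: 240}
  - parameter: matrix_frequency
    extract: matrix_freq
    ideal: {cmp: range, lo: 160, hi: 256}
    target: {cmp: range, lo: 160, hi: 256}
    acceptable: {cmp: range, lo: 128, hi: 256}
  - parameter: nex
    extract: nex
    ideal: {cmp: min, value: 2}
    target: {cmp: min, value: 2}
    acceptable: {cmp: min, value: 1}
  - parameter: half_scan_factor
    extract: half_scan_factor
    target: {cmp: min, value: 0.65, strict: true}
    acceptable: {cmp: min, value: 0.65, strict: true}
  - parameter: parallel_factor
    extract: parallel_factor
    ideal: {cmp: range, lo: 2, hi: 3}
    target: {cmp: range, lo: 2, hi: 3}
    acceptable: {cmp: range, lo: 2, hi: 3}
  - parameter: tr_ms
    extract: tr_ms
    ideal: {cmp: min, value: 5000, strict: true}
    target: {cmp: min, value: 3000}
    acceptable: {cmp: min, value: 3000}
  - parameter: te_ms
    extract: te_ms
    ideal: {cmp: max, value: 60, strict: true}
    target: {cmp: max, value: 60, strict: true}
    acceptable: {cmp: max, value: 120, strict: true}
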