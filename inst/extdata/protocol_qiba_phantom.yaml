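# QIBA phantom acquisition protocol as a compliance specification.
# Single-tier: an exam is either compliant ("acceptable") or not.
# "Shortest TE" is encoded as TE < 60 ms, the bound all compliant scans in
# the validation study satisfied.
profile: qiba_phantom
parameters:
  - parameter: b_values
    extract: b_values
    acceptable: {cmp: set_eq, value: [0, 500, 1000, 1500, 2000]}
  - parameter: tr_ms
    extract: tr_ms
    acceptable: {cmp: eq, value: 8000}
  - parameter: te_ms
    extract: te_ms
    acceptable: {cmp: max, value: 60, strict: true}
  - parameter: fov_mm
    extract: fov_mm
    acceptable: {cmp: eq, value: 220}
  - parameter: matrix
    extract: matrix
    acceptable: {cmp: set_eq, value: [128, 128]}
  - parameter: slice_thickness_mm
    extract: slice_thickness_mm
    acceptable: {cmp: eq, value: 4}
  - parameter: gap_mm
    extract: gap_mm
    acceptable: {cmp: eq, value: 1}
  - parameter: n_slices
    extract: n_slices
    acceptable: {cmp: eq, value: 25}
  - parameter: parallel_factor
    extract: parallel_factor
    acceptable: {cmp: eq, value: 2}
  - parameter: nex
    extract: nex
    acceptable: {cmp: eq, value: 2}
  - parameter: half_scan_factor
    extract: half_scan_factor
    acceptable: {cmp: min, value: 0.75}
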