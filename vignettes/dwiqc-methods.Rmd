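---
title: "Quantitative DWI quality control: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DWI quality control: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiqc)
```

## The problem

The apparent diffusion coefficient (ADC) is only usable as a quantitative
imaging biomarker — for treatment response, longitudinal monitoring, or
multi-centre trials — if the scanner and the acquisition protocol are shown
to measure it accurately and repeatably. The accepted way to show this is a
staged quality-control workflow: scan a diffusion phantom with known
ground-truth diffusivities under a standardized protocol, compute a defined
set of performance metrics, check each against a published claim
(a quantitative performance requirement), verify the acquisition parameters
against tiered protocol specifications, and finally audit patient scans for
image quality and ADC repeatability. `dwiqc` implements that workflow end to
end, including the simulators needed to exercise and test every stage
without scanner data.

## Signal model

All quantitative stages rest on the mono-exponential diffusion decay

$$ S(b) = S_0 \, e^{-b \cdot \mathrm{ADC}} $$

with $b$ in s/mm² and ADC in mm²/s. Internally every ADC is carried in
μm²/s (1 × 10⁻³ mm²/s = 1000 μm²/s) and the exponent uses
$b \cdot \mathrm{ADC} \cdot 10^{-6}$; keeping a single internal unit with
one explicit conversion avoids the classic factor-10⁶ mistakes when tables
in mm²/s and μm²/s are mixed. ADC maps are fitted two ways, matching the
two protocols' conventions:

* **log-linear** (`fit_adc_loglinear()`, method `"loglinear"`): unweighted
  ordinary least squares of $\ln S$ on $b$ over all usable b-values; the
  slope is $-\mathrm{ADC}$. The phantom-validation protocol (five b-values:
  0, 500, 1000, 1500, 2000 s/mm²) uses this map. OLS on the log scale is
  deliberately unweighted: the workflow's sources name the model but not a
  weighting, and the choice is isolated behind `fit_options()` so a
  variance-weighted variant could be swapped in without touching callers.
* **two-point** (`fit_adc_twopoint()`, method `"two_point"`): the closed
  form $\ln(S_{low}/S_{high}) / (b_{high}-b_{low})$ from the lowest and
  highest b-value, as clinical b = 0/1000 protocols compute it. On noiseless
  mono-exponential data both methods are exact and identical; they differ
  only in their noise behaviour.

Per-voxel robustness: a b-point with signal at or below `min_signal`
(default 0) is dropped for that voxel rather than discarding the voxel, so
maps keep coverage when the noise floor swallows the highest b-values;
voxels with fewer than `require_n_points` (default 2) usable points become
NaN and are excluded from all VOI statistics.

## Noise model

Magnitude MRI noise is Rician: `noise_model("rician", sigma)` reconstructs
$\sqrt{(S+n_1)^2 + n_2^2}$ from two independent $N(0,\sigma^2)$ channels,
the single-coil magnitude convention. `nex` excitations average `nex`
independent magnitude images, which reduces variance but not the Rician
floor. The b = 0 SNR of a vial is approximately $S_0/\sigma$ per
excitation; the SNR *metric*, however, is the difference method actually
used in phantom QC — in-ROI mean of a b = 0 image divided by the in-ROI
mean of $|rep_1 - rep_2|/\sqrt{2}$. Because that denominator is a mean
absolute difference rather than an SD, its expectation is
$\sigma\sqrt{2/\pi} \approx 0.80\,\sigma$, and the measured SNR at a
configured $S_0/\sigma = 45$ comes out near $45/\sqrt{2/\pi} \approx 56$.
The package reports the metric exactly as defined and leaves that
interpretation to this vignette.

## The phantom and its simulator

The simulator (`make_phantom_layout()`, `simulate_dwi_exam()`,
`simulate_repeated_exams()`) emulates a commercial multi-vial diffusion
phantom: one central vial of pure water (0% PVP) with ground-truth ADC
**1100 μm²/s** — the reference value (`DC_true`) that anchors the bias,
repeatability, random error and SNR claims — surrounded by a ring of vials
with increasing polyvinylpyrrolidone concentration. The published phantom
description does not print the nonzero-PVP ground truths, so the default
layout uses a synthetic monotone-decreasing ladder
($1100 \cdot e^{-0.025\,\mathrm{PVP}}$ μm²/s, i.e. down to ~315 μm²/s at
50% PVP, spanning the physiological range); every vial's truth is free
configuration because all metrics are defined per-vial. The default grid is
13 vials of 9 mm radius on a 96 × 96 × 5 grid at 1.72 mm in-plane / 4 mm
slices — the in-plane resolution of the reference protocol on a grid
cropped to the vial tray, chosen so a full four-repeat session simulates
and fits in well under a second while the central-vial VOI still contains
~440 voxels, enough that VOI means are estimated to a few tenths of a
percent. Repeat-exam sessions follow the standard design: four exams per
session (short-term repeatability), sessions separated by a month
(long-term), with an optional multiplicative baseline drift
(`inter_exam_cv`) between repeats.

What the simulator does **not** model: EPI ghosting, susceptibility
distortion, eddy currents, coil sensitivity profiles, gradient
nonlinearity, partial-volume voxels at vial walls, or temperature drift.
Passing simulated conformance therefore demonstrates the correctness of
the *analysis* chain — fitting, statistics, claims logic — not that any
physical scanner conforms; real-scanner effects enter only through the
artifact scorecards and measured tables the patient stage consumes.

## ROIs and VOI statistics

ROIs are single-slice circles (`roi_spec()`), rasterized by the
voxel-centre-in-circle rule with strict inequality — unambiguous, and
matching common ROI tools; vial VOIs stack the circle across slices into a
cylinder. Statistics (`voi_statistics()`) are the sample mean and SD
(n − 1) of finite in-mask voxels plus a histogram; n − 1 matters because
downstream RC and wCV treat these SDs as variance estimates. ROIs drawn on
a b = 1000 image transfer to the ADC map by identical voxel indices — no
resampling, as in the clinical workflow.

## Performance metrics and claims

All metrics live in tidy, pipe-friendly functions returning tibbles:

| Metric | Definition | Claim (shipped YAML) |
|---|---|---|
| ADC bias | $100(\mu - DC_{true})/DC_{true}$ | abs ≤ 3.6% |
| Repeatability | $\sigma_w$, RC $= 2.77\sigma_w$, wCV $= 100\sigma_w/\mu$ | RC < 15 μm²/s, wCV ≤ 0.5% (short-term); RC < 65 μm²/s, wCV < 2.2% (long-term) |
| Linearity | OLS of $\mu$ on $DC_{true}$ | R² > 0.90; slope 95% CI within [0.95, 1.05] |
| b-value dependence | $100 \max_b \lvert ADC_b - \overline{ADC} \rvert / \overline{ADC}$ | ≤ 2% |
| Random error | $100\,\sigma/\mu$ (within-VOI spatial CV) | ≤ 2% |
| SNR (b = 0) | mean signal / mean noise image | ≥ 45 |

Choices worth stating, because the definitions leave them open:

* $\sigma_w$ is the square root of the **unweighted mean of within-group
  sample variances** (each n − 1) — the standard pooled within-subject
  estimator; groups are vials (phantom) or patients (clinical).
* **2.77 is used literally**, not $1.96\sqrt{2} = 2.7719\ldots$; this
  reproduces published table arithmetic exactly.
* **Random error** uses the within-VOI spatial SD of a single exam's
  central-vial ADC map (the definition names no subscript; this reading is
  isolated in `random_error()` and swappable). Note its strong SNR
  dependence: at the SNR-45 claim boundary the per-voxel ADC noise alone
  puts the spatial CV near 8%, so this claim is only attainable at the
  comfortably higher SNRs real systems deliver — the simulated claim
  boundary is a worst case, not a typical scanner.
* **b-value dependence** implements the claim sentence (max deviation of
  the per-b two-point ADCs from their average) rather than a pairwise-ratio
  reading of the formula fragment; the two coincide at zero. With fewer
  than two nonzero b-values the metric is **not evaluable** — reported as
  NA, never as a failure, mirroring how two-b clinical protocols are
  validated.
* Reports round half-up to one decimal **for display only**
  (`round_half_up()`); everything downstream keeps full precision.

`check_claims()` assigns `pass` / `fail` / `not_evaluable` per metric with
the comparator boundary semantics exactly as printed (wCV ≤ 0.5 passes at
0.5; RC < 15 fails at 15); overall conformance is "no failures". Claims
ship as versioned YAML (`inst/extdata/qiba_claims.yaml`) rather than code,
because profile revisions change thresholds, not logic.

## Protocol tiers

`check_protocol_compliance()` grades acquisition metadata against YAML tier
specs: the phantom protocol is single-tier (compliant or not); the clinical
brain protocol has ideal / target / acceptable tiers. Two regularisations
were needed. First, the printed tier table is not monotone (e.g. TR ideal
"> 5000 ms" but target "3000–5000 ms", so a 8000 ms TR would absurdly fail
the *lower* tier); the shipped specs encode each rule monotonically
(target TR ≥ 3000 ms) and the loader *validates* nesting, refusing
non-monotone specs. Every worked example still lands on its printed tier
(TR 3000 → target; 2 mm gap → acceptable). Second, "shortest TE" is encoded
as TE < 60 ms, the bound the validated scans satisfied. Known deviations
(a vendor forcing NEX 1) are recorded as **waivers** — visible in the
report but not failures. The generic `clinical_brain_protocol()`
constructor defaults to a 240 mm FOV so the shipped demo protocol sits
inside the spec's printed 220–240 mm window.

## Patient-stage QA

The computable surface starts at extracted ROI statistics (CSV), not raw
patient images — ROI placement is manual in practice. The stage covers:

* `aggregate_quality()`: per-scanner mean ± SD of seven 3-point artifact
  scores (1 unacceptable / 2 acceptable / 3 ideal), flagging any 1.
* `tissue_repeatability()`: patients with ≥ 2 scans on a scanner form the
  repeated groups; scanners without repeats yield an explicit
  not-evaluable row (an "N.A." table cell, not an error).
  `tissue_reproducibility()` is the pooled cross-sectional companion
  (all scans, RC/wCV from the pooled SD) — the two reproduce the published
  table's two blocks, whose N-counts are what distinguish the designs.
* `csf_water_comparison()`: per-scanner CSF means against free water at
  37 °C, 3037.7 μm²/s — CSF is the in-vivo object closest to an absolute
  reference.

The cohort simulator (`simulate_patient_cohort()`) draws patient-level
true means around the tissue mean (between-subject CV, default 1% — in the
published cohort the total cross-sectional SD ≈ the within-subject SD, so
the between-subject spread of healthy white-matter ADC is small) and
per-scan observations with within-subject CV 2%, the level clinical brain
QA reports. Defaults: 14 patients × 2 scans, white matter 800 μm²/s, CSF
at the water reference.

## Numerical choices and degenerate inputs

* Voxelwise log-linear fitting groups voxels by usable-point pattern and
  solves the closed-form normal equations per group — exact OLS at
  vectorised speed (a per-voxel `lm()` would be ~10⁴× slower); tests
  cross-check against `lm()`.
* Unfittable voxels are NaN by contract, never errors; empty ROI masks and
  all-NaN masks are errors naming the ROI.
* Noiseless limits are exact: zero bias, zero wCV, slope 1 with a
  degenerate CI, R² = 1 — asserted at 1e-9 in the test suite.
* All simulators take explicit seeds (`withr::with_seed`, leaving the
  session RNG untouched); identical configuration + seed gives
  bit-identical volumes and byte-identical reports.
* A perfect linearity fit would trigger `summary.lm`'s "essentially
  perfect fit" warning; it is suppressed because that regime is the
  expected noiseless baseline here.

## Problem sizes in the shipped tests

The Monte-Carlo checks run at sizes chosen to make their estimators
informative at interactive speed: 100 seeded sessions for the
Rician-regime check at the SNR-45 claim boundary (the estimator's mean
|bias| stays well under the 4% claim and the mean intra-exam wCV under
0.5% — individual 3-degree-of-freedom wCV estimates scatter around 0.34%,
so only distribution-level statements are meaningful), and 500 simulated
cohorts for within-subject CV recovery (the 2% generating value sits
centrally in the estimate distribution, mean ≈ 1.96%). The published
patient-QA table is audited arithmetically: every wCV cell reproduces
exactly at the printed precision from its mean ± SD, and every RC cell
agrees within the tolerance implied by the printed rounding itself
(±0.05 on a 1-d.p. SD propagates to ±0.14 on RC) — a handful of RC cells
were evidently computed from unrounded SDs.

## Known limitations

Single-slice circular ROIs only (no freehand or true 3-D spheres); no
IVIM/kurtosis or noise-floor-corrected fitting; no cross-site
reproducibility statistic (RDC) or confidence intervals on wCV; no DICOM
ingestion (NIfTI-1 + JSON sidecar is the exam container — desk-scale
testability without vendor-header complexity); the tiered specs encode the
published tables, not any later profile revision.
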