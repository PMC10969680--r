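test_that("default layout carries the water reference ADC and unique labels", {
  lay <- make_phantom_layout()
  expect_equal(nrow(lay$vials), 13)
  expect_equal(sum(lay$vials$central), 1)
  expect_false(anyDuplicated(lay$vials$label) > 0)
  expect_equal(lay$vials$true_adc[lay$vials$central], 1100)
  # nonzero-PVP ladder decreases with concentration
  ladder <- dplyr::distinct(lay$vials, pvp_concentration, true_adc)
  ladder <- dplyr::arrange(ladder, pvp_concentration)
  expect_true(all(diff(ladder$true_adc) < 0))
})

test_that("degenerate and inconsistent geometries are rejected", {
  expect_error(make_phantom_layout(vials = vial_spec("v", 16, 16, radius_mm = 0,
                                                     true_adc = 1100)),
               "radius_mm")
  # vial poking out of the grid
  expect_error(
    make_phantom_layout(n_ring = 0, grid_shape = c(1, 16, 16),
                        vial_radius_mm = 20),
    "outside the image grid")
  # overlapping pair
  v <- dplyr::bind_rows(
    vial_spec("a", 16, 14, 6, 1100, central = TRUE),
    vial_spec("b", 16, 18, 6, 900))
  expect_error(make_phantom_layout(grid_shape = c(1, 32, 32), vials = v),
               "overlap")
  # no central vial
  expect_error(
    make_phantom_layout(grid_shape = c(1, 32, 32),
                        vials = vial_spec("a", 16, 16, 6, 1100)),
    "central")
})

test_that("noiseless forward model is exact mono-exponential decay", {
  lay <- tiny_layout()
  ex <- simulate_dwi_exam(lay, qiba_phantom_protocol(), noise_model("none"))
  mask <- dwiqc:::vial_mask(lay, "vial_00")
  b <- qiba_b
  for (k in seq_along(b)) {
    vol <- array(ex$signal[, , , k], dim(ex$signal)[1:3])
    expected <- 1000 * exp(-b[k] * 1100 * 1e-6)
    expect_lt(max(abs(vol[mask] - expected)) / expected, 1e-12)
    expect_true(all(vol[!mask] == 0))
  }
  # closed form at b = 1000: 1000 * exp(-1.1)
  v1000 <- array(ex$signal[, , , 3], dim(ex$signal)[1:3])
  expect_equal(v1000[mask][1], 332.8710836981, tolerance = 1e-10)
})

test_that("simulation is seed-deterministic and Rician noise is positively biased", {
  lay <- tiny_layout()
  p <- qiba_phantom_protocol(nex = 1)
  nm <- noise_model("rician", sigma = 400) # deliberately low SNR
  a <- simulate_dwi_exam(lay, p, nm, seed = 11)
  b2 <- simulate_dwi_exam(lay, p, nm, seed = 11)
  c2 <- simulate_dwi_exam(lay, p, nm, seed = 12)
  expect_identical(a$signal, b2$signal)
  expect_false(identical(a$signal, c2$signal))

  # Rician floor: mean magnitude exceeds the true signal at low SNR
  mask <- dwiqc:::vial_mask(lay, "vial_00")
  s_true <- 1000 * exp(-2000 * 1100 * 1e-6) # ~110, SNR ~0.3
  high_b <- array(a$signal[, , , 5], dim(a$signal)[1:3])
  expect_gt(mean(high_b[mask]), s_true)
})

test_that("repeated exams: identical when noiseless, indexed, and >= 2 enforced", {
  lay <- tiny_layout()
  p <- qiba_phantom_protocol()
  exams <- simulate_repeated_exams(lay, p, noise_model("none"),
                                   n_repeats = 4, inter_exam_cv = 0)
  expect_length(exams, 4)
  expect_equal(purrr::map_int(exams, "repeat_index"), 0:3)
  for (ex in exams[-1]) expect_identical(ex$signal, exams[[1]]$signal)
  expect_error(simulate_repeated_exams(lay, p, n_repeats = 1), ">= 2")
})

test_that("scaling s0 scales the noiseless signal and leaves the ADC map unchanged", {
  lay1 <- tiny_layout(s0 = 1000)
  lay2 <- tiny_layout(s0 = 3000)
  p <- qiba_phantom_protocol()
  e1 <- simulate_dwi_exam(lay1, p, noise_model("none"))
  e2 <- simulate_dwi_exam(lay2, p, noise_model("none"))
  expect_equal(e2$signal, 3 * e1$signal)
  m1 <- compute_adc_map(e1, fit_options("loglinear"))
  m2 <- compute_adc_map(e2, fit_options("loglinear"))
  expect_equal(m1$values, m2$values)
})

test_that("patient cohort simulator has the assumed two-level structure", {
  # zero CVs: every record equals the tissue mean
  z <- simulate_patient_cohort(n_patients = 4, scans_per_patient = 3,
                               tissue_means = c(csf = 3037.7),
                               within_subject_cv = 0, between_subject_cv = 0,
                               seed = 1)
  expect_true(all(z$roi_mean_adc == 3037.7))

  # within-subject cv 0: a patient's scans identical, patients differ
  w <- simulate_patient_cohort(n_patients = 5, scans_per_patient = 3,
                               within_subject_cv = 0,
                               between_subject_cv = 0.05, seed = 2)
  per <- dplyr::summarise(
    dplyr::group_by(w, patient_id, tissue),
    spread = diff(range(roi_mean_adc)), .groups = "drop")
  expect_true(all(per$spread == 0))
  expect_gt(dplyr::n_distinct(w$roi_mean_adc), 5)

  expect_error(simulate_patient_cohort(tissue_means = c(wm = -5)), "positive")
  expect_identical(simulate_patient_cohort(seed = 9),
                   simulate_patient_cohort(seed = 9))
})
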