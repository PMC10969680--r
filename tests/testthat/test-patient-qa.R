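make_cards <- function(n, scanner = "s1", tweak = list()) {
  cards <- tibble::tibble(scan_id = sprintf("scan%02d", seq_len(n)),
                          scanner_id = scanner)
  for (it in dwiqc:::qc_items()) cards[[it]] <- 3L
  for (nm in names(tweak)) cards[[nm]][tweak[[nm]]$rows] <- tweak[[nm]]$score
  cards
}

test_that("quality aggregation reports per-item mean +/- SD and flags score 1", {
  all3 <- aggregate_quality(make_cards(5))
  expect_true(all(all3$mean == 3))
  expect_true(all(all3$sd == 0))
  expect_false(any(all3$any_unacceptable))

  # 17 scans, one scored acceptable on nyquist: mean 2.94 -> prints 2.9 +/- 0.2
  one2 <- aggregate_quality(
    make_cards(17, tweak = list(nyquist_ghost = list(rows = 5, score = 2L))))
  ny <- one2[one2$item == "nyquist_ghost", ]
  expect_equal(ny$mean, 50 / 17, tolerance = 1e-12)
  expect_equal(round_half_up(ny$mean, 1), 2.9)
  expect_equal(round_half_up(ny$sd, 1), 0.2)
  expect_false(ny$any_unacceptable)

  # two acceptable scores reproduce the published "2.9 +/- 0.3" cell
  two2 <- aggregate_quality(
    make_cards(17, tweak = list(nyquist_ghost = list(rows = c(5, 9), score = 2L))))
  ny2 <- two2[two2$item == "nyquist_ghost", ]
  expect_equal(round_half_up(ny2$mean, 1), 2.9)
  expect_equal(round_half_up(ny2$sd, 1), 0.3)

  # any unacceptable score raises the flag
  bad <- aggregate_quality(
    make_cards(4, tweak = list(motion = list(rows = 2, score = 1L))))
  expect_true(bad$any_unacceptable[bad$item == "motion"])

  # all items mandatory; scores outside 1..3 rejected
  incomplete <- make_cards(3)
  incomplete$motion <- NULL
  expect_error(aggregate_quality(incomplete), "motion")
  out_of_range <- make_cards(3, tweak = list(motion = list(rows = 1, score = 4L)))
  expect_error(aggregate_quality(out_of_range), "1, 2 or 3")
})

test_that("tissue repeatability groups patients and honours the profile identities", {
  set.seed(3)
  scans <- simulate_patient_cohort(n_patients = 8, scans_per_patient = 2,
                                   seed = 3)
  r <- tissue_repeatability(scans, "white_matter", "scanner_1")
  expect_true(r$evaluable)
  expect_equal(r$n_patients, 8)
  expect_equal(r$rc, 2.77 * r$sigma_w)
  expect_equal(r$wcv, 100 * r$sigma_w / r$mean_adc)

  # matches the metrics-layer estimator on the same grouping
  wm <- scans[scans$tissue == "white_matter", ]
  direct <- repeatability(wm, roi_mean_adc, patient_id)
  expect_equal(r$sigma_w, direct$sigma_w)

  # single-scan patients only: N.A. row, not an error
  singles <- simulate_patient_cohort(n_patients = 5, scans_per_patient = 1,
                                     seed = 4)
  na_row <- tissue_repeatability(singles, "white_matter")
  expect_false(na_row$evaluable)
  expect_true(is.na(na_row$rc))
})

test_that("reproducibility pools all scans per scanner", {
  scans <- simulate_patient_cohort(n_patients = 6, scans_per_patient = 2,
                                   seed = 5)
  rp <- tissue_reproducibility(scans, "csf", "scanner_1")
  csf <- scans$roi_mean_adc[scans$tissue == "csf"]
  expect_equal(rp$mean_adc, mean(csf))
  expect_equal(rp$sd_adc, sd(csf))
  expect_equal(rp$rc, 2.77 * sd(csf))
  expect_equal(rp$n_scans, 12)
})

test_that("CSF-water comparison reproduces the published extremes", {
  cmp <- csf_water_comparison(c(ge = 3156.5, philips = 3114.7,
                                siemens = 3011.0))
  expect_equal(cmp$max, 118.8, tolerance = 1e-9)
  expect_equal(cmp$min, 26.7, tolerance = 1e-9)
  expect_true(all(cmp$differences$difference >= 0))
  expect_gte(cmp$max, cmp$min)

  expect_equal(csf_water_comparison(3037.7)$max, 0)
  expect_error(csf_water_comparison(numeric(0)), "nonempty")
})

test_that("patient QA orchestration covers every scanner-tissue cell", {
  scans <- dplyr::bind_rows(
    simulate_patient_cohort(n_patients = 3, scans_per_patient = 2,
                            scanner_id = "sc_a", seed = 6),
    simulate_patient_cohort(n_patients = 2, scans_per_patient = 1,
                            scanner_id = "sc_b", seed = 7))
  cards <- make_cards(4, scanner = "sc_a")
  res <- run_patient_qa(scans, cards)
  expect_equal(nrow(res$repeatability), 4) # 2 scanners x 2 tissues
  expect_equal(nrow(res$reproducibility), 4)
  # single-scan scanner is not evaluable for repeatability
  b_rows <- res$repeatability[res$repeatability$scanner_id == "sc_b", ]
  expect_true(all(!b_rows$evaluable))
  expect_equal(nrow(res$csf_water$differences), 2)
  expect_equal(nrow(res$quality), length(dwiqc:::qc_items()))
})
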