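#' Simulate a longitudinal patient ROI cohort
#'
#' Generates per-scan tissue-ROI ADC records with the two-level structure
#' the repeatability analysis assumes: each patient's true tissue mean is
#' drawn around the population tissue mean with the between-subject CV, and
#' each scan observes that mean with multiplicative within-subject error
#' (`value = patient_mean * (1 + eps)`, `eps ~ N(0, within_subject_cv^2)`).
#'
#' Defaults emulate a brain QA cohort: frontoparietal white matter around
#' 800 um^2/s and ventricular CSF around the body-temperature water value
#' 3037.7 um^2/s, with ~2% within-subject CV.
#'
#' @param n_patients Number of patients.
#' @param scans_per_patient Scans per patient (>= 1), one per session.
#' @param tissue_means Named numeric: mean ADC (um^2/s) per tissue.
#' @param within_subject_cv Fractional within-subject (scan-to-scan) CV.
#' @param between_subject_cv Fractional between-subject CV of true means.
#' @param roi_voxels Nominal ROI voxel count recorded per row.
#' @param scanner_id Scanner label stamped on every row.
#' @param session_spacing_days Days between a patient's successive scans.
#' @param seed Integer seed.
#' @return A tibble with columns `patient_id`, `scanner_id`, `session_date`,
#'   `tissue`, `roi_mean_adc`, `roi_sd`, `n_voxels`.
#' @export
#' @examples
#' cohort <- simulate_patient_cohort(n_patients = 3, seed = 1)
#' dplyr::count(cohort, tissue)
simulate_patient_cohort <- function(n_patients = 14, scans_per_patient = 2,
                                    tissue_means = c(white_matter = 800,
                                                     csf = 3037.7),
                                    within_subject_cv = 0.02,
                                    between_subject_cv = 0.01,
                                    roi_voxels = c(white_matter = 106, csf = 26),
                                    scanner_id = "scanner_1",
                                    session_spacing_days = 30,
                                    seed = NULL) {
  check_number(within_subject_cv, "within_subject_cv", 0)
  check_number(between_subject_cv, "between_subject_cv", 0)
  if (any(tissue_means <= 0)) abort("All tissue means must be positive.")
  if (scans_per_patient < 1) abort("`scans_per_patient` must be >= 1.")
  if (is.null(names(tissue_means)) || any(!nzchar(names(tissue_means)))) {
    abort("`tissue_means` must be a named vector (tissue -> mean ADC).")
  }

  with_seed_or_not(seed, {
    grid <- tidyr::expand_grid(
      patient_id = sprintf("pt_%02d", seq_len(n_patients)),
      tissue = names(tissue_means)
    )
    grid$patient_mean <- tissue_means[grid$tissue] *
      (1 + rnorm(nrow(grid), 0, between_subject_cv))
    out <- tidyr::expand_grid(grid, scan = seq_len(scans_per_patient) - 1L)
    out$session_date <- out$scan * session_spacing_days
    out$roi_mean_adc <- out$patient_mean * (1 + rnorm(nrow(out), 0, within_subject_cv))
    nv <- roi_voxels[out$tissue]
    nv[is.na(nv)] <- 50
    out$n_voxels <- as.integer(nv)
    # within-ROI spatial SD, nominal ~6% of the mean
    out$roi_sd <- 0.06 * out$roi_mean_adc
    out$scanner_id <- scanner_id
    dplyr::select(out, "patient_id", "scanner_id", "session_date", "tissue",
                  "roi_mean_adc", "roi_sd", "n_voxels")
  })
}

#' Simulate image-quality scorecards
#'
#' Produces per-scan 3-point artifact scores (1 unacceptable, 2 acceptable,
#' 3 ideal) for the seven QC items reviewed on clinical DWI. Scores are
#' drawn independently per item with probability `p_acceptable` of a 2 and
#' `p_unacceptable` of a 1, otherwise 3.
#'
#' @param scan_ids Character vector of scan identifiers.
#' @param scanner_id Scanner label (recycled).
#' @param p_acceptable,p_unacceptable Per-item probabilities of scores 2, 1.
#' @param seed Integer seed.
#' @return Tibble with `scan_id`, `scanner_id` and one column per QC item.
#' @export
simulate_quality_scorecards <- function(scan_ids, scanner_id = "scanner_1",
                                        p_acceptable = 0.05,
                                        p_unacceptable = 0, seed = NULL) {
  items <- qc_items()
  with_seed_or_not(seed, {
    n <- length(scan_ids)
    out <- tibble::tibble(scan_id = as.character(scan_ids),
                          scanner_id = rep_len(scanner_id, n))
    for (it in items) {
      out[[it]] <- sample(c(1L, 2L, 3L), n, replace = TRUE,
                          prob = c(p_unacceptable, p_acceptable,
                                   1 - p_acceptable - p_unacceptable))
    }
    out
  })
}

qc_items <- function() {
  c("low_snr", "ghost_parallel", "spatial_distortion", "eddy_currents",
    "fat_suppression", "motion", "nyquist_ghost")
}
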