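#' Published brain QA cohort summary statistics
#'
#' Per-scanner, per-tissue summary statistics (mean +/- SD of ROI-mean ADC,
#' with the printed RC and wCV) from the brain QA validation cohort: 17
#' stroke-trial patients, 55 scans across three scanners, white-matter and
#' CSF ROIs, analysed as within-patient repeatability (patients with
#' repeated scans on the same scanner) and pooled per-scanner
#' reproducibility. Scanners with no repeated patients have `NA` rows.
#' These printed summaries are inputs for auditing: RC and wCV can be
#' recomputed from mean and SD via [repeatability_from_summary()].
#'
#' @return Tibble with columns `scanner`, `tissue`, `analysis`,
#'   `n_patients`, `n_scans`, `mean_adc`, `sd_adc`, `rc_printed`,
#'   `wcv_printed`.
#' @export
#' @examples
#' s <- brain_cohort_summary()
#' with(s[3, ], repeatability_from_summary(mean_adc, sd_adc)) # rc ~ 44.9
brain_cohort_summary <- function() {
  path <- system.file("extdata", "brain_cohort_summary.csv",
                      package = "dwiqc", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    scanner = "c", tissue = "c", analysis = "c",
                    .default = "d"))
}
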