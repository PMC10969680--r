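#' Reference ADC of free water at body temperature
#'
#' The experimental ADC of water at 37 degrees C, used as the physiological
#' reference for ventricular CSF.
#'
#' @param tissue Tissue label recorded with the reference.
#' @param reference_adc Reference ADC in um^2/s.
#' @param note Free-text provenance note.
#' @return A one-row tibble of class `tissue_reference`.
#' @export
water_reference_37c <- function(tissue = "csf", reference_adc = 3037.7,
                                note = "free water at 37 C") {
  check_number(reference_adc, "reference_adc", 0, strict = TRUE)
  out <- tibble::tibble(tissue = tissue, reference_adc = reference_adc,
                        note = note)
  class(out) <- c("tissue_reference", class(out))
  out
}

#' Aggregate image-quality scorecards
#'
#' Per scanner and QC item: mean and sample SD of the 3-point scores
#' (1 unacceptable, 2 acceptable, 3 ideal) across scans, plus a flag set
#' when any scan scored 1 on the item. Report display rounds to one
#' decimal; the returned values are unrounded.
#'
#' @param scorecards Tibble with `scan_id`, `scanner_id` and one integer
#'   column per QC item (all of [qc_items()] must be present, scores in
#'   1..3).
#' @return Tibble with `scanner_id`, `item`, `n_scans`, `mean`, `sd`,
#'   `any_unacceptable`.
#' @export
aggregate_quality <- function(scorecards) {
  items <- qc_items()
  missing <- setdiff(items, names(scorecards))
  if (length(missing) > 0) {
    abort(paste0("Scorecards lack QC item(s): ", paste(missing, collapse = ", ")))
  }
  scores <- unlist(scorecards[items], use.names = FALSE)
  if (anyNA(scores) || !all(scores %in% 1:3)) {
    abort("All QC scores must be 1, 2 or 3.")
  }
  long <- tidyr::pivot_longer(scorecards, dplyr::all_of(items),
                              names_to = "item", values_to = "score")
  dplyr::summarise(
    dplyr::group_by(long, .data$scanner_id, .data$item),
    n_scans = dplyr::n(),
    mean = mean(.data$score),
    sd = if (dplyr::n() > 1) sd(.data$score) else 0,
    any_unacceptable = any(.data$score == 1),
    .groups = "drop"
  )
}

#' Tissue ROI repeatability across sessions
#'
#' Long-term repeatability of a tissue's ROI-mean ADC for one scanner:
#' patients are the repeated units, sessions the repeats. Delegates to
#' [repeatability()] (pooled within-patient SD, RC = 2.77 sigma_w,
#' wCV = 100 sigma_w / mu). Patients with a single scan cannot contribute;
#' if no patient has repeats the result is flagged not evaluable rather
#' than an error, mirroring a QA table's "N.A." cell.
#'
#' @param scans Patient scan tibble (as from [simulate_patient_cohort()] or
#'   [read_patient_scans()]).
#' @param tissue Tissue to analyse (e.g. `"white_matter"`, `"csf"`).
#' @param scanner Optional scanner filter.
#' @return One-row tibble: `tissue`, `scanner_id`, `n_patients`, `n_scans`,
#'   `mean_adc`, `sd_adc` (across scans), `sigma_w`, `rc`, `wcv`,
#'   `evaluable`.
#' @export
tissue_repeatability <- function(scans, tissue, scanner = NULL) {
  df <- dplyr::filter(scans, .data$tissue == !!tissue)
  if (!is.null(scanner)) df <- dplyr::filter(df, .data$scanner_id == !!scanner)
  counts <- dplyr::count(df, .data$patient_id)
  eligible <- counts$patient_id[counts$n >= 2]
  if (length(eligible) == 0) {
    return(tibble::tibble(tissue = tissue,
                          scanner_id = scanner %||% "all",
                          n_patients = 0L, n_scans = 0L,
                          mean_adc = NA_real_, sd_adc = NA_real_,
                          sigma_w = NA_real_, rc = NA_real_, wcv = NA_real_,
                          evaluable = FALSE))
  }
  df <- dplyr::filter(df, .data$patient_id %in% eligible)
  rep <- repeatability(df, .data$roi_mean_adc, .data$patient_id)
  tibble::tibble(tissue = tissue, scanner_id = scanner %||% "all",
                 n_patients = rep$n_groups, n_scans = rep$n_obs,
                 mean_adc = rep$mean, sd_adc = sd(df$roi_mean_adc),
                 sigma_w = rep$sigma_w, rc = rep$rc, wcv = rep$wcv,
                 evaluable = TRUE)
}

#' Pooled per-scanner tissue statistics (reproducibility)
#'
#' Mean and SD of the ROI-mean ADC over all of a scanner's scans of a
#' tissue, pooled across patients, with RC and wCV derived from the pooled
#' SD — the cross-sectional companion to [tissue_repeatability()].
#'
#' @inheritParams tissue_repeatability
#' @return One-row tibble: `tissue`, `scanner_id`, `n_patients`, `n_scans`,
#'   `mean_adc`, `sd_adc`, `rc`, `wcv`.
#' @export
tissue_reproducibility <- function(scans, tissue, scanner = NULL) {
  df <- dplyr::filter(scans, .data$tissue == !!tissue)
  if (!is.null(scanner)) df <- dplyr::filter(df, .data$scanner_id == !!scanner)
  if (nrow(df) == 0) abort("No scans match the tissue/scanner filter.")
  mu <- mean(df$roi_mean_adc)
  sigma <- if (nrow(df) > 1) sd(df$roi_mean_adc) else 0
  tibble::tibble(tissue = tissue, scanner_id = scanner %||% "all",
                 n_patients = dplyr::n_distinct(df$patient_id),
                 n_scans = nrow(df), mean_adc = mu, sd_adc = sigma,
                 rc = 2.77 * sigma, wcv = 100 * sigma / mu)
}

#' Compare measured CSF ADC against the 37 C water reference
#'
#' Absolute differences between per-scanner mean CSF ADCs and the
#' body-temperature free-water reference, with the cohort-wide minimum and
#' maximum difference.
#'
#' @param csf_means Numeric vector of per-scanner mean CSF ADCs (um^2/s),
#'   optionally named by scanner.
#' @param reference A [water_reference_37c()] row (default 3037.7 um^2/s).
#' @return List with `differences` (tibble: `scanner`, `csf_mean`,
#'   `difference`), `min` and `max`.
#' @export
#' @examples
#' csf_water_comparison(c(ge = 3156.5, philips = 3114.7, siemens = 3011.0))
csf_water_comparison <- function(csf_means, reference = water_reference_37c()) {
  if (length(csf_means) == 0) abort("`csf_means` must be nonempty.")
  if (any(csf_means <= 0)) abort("CSF means must be positive.")
  diffs <- abs(csf_means - reference$reference_adc)
  tbl <- tibble::tibble(
    scanner = names(csf_means) %||% paste0("scanner_", seq_along(csf_means)),
    csf_mean = unname(csf_means), difference = unname(diffs))
  list(differences = tbl, min = min(diffs), max = max(diffs),
       reference_adc = reference$reference_adc)
}
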