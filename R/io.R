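#' Write a DWI series as NIfTI-1 plus a JSON sidecar
#'
#' The 4-D signal volume is stored as NIfTI (axes slice, row, col, b) and
#' the acquisition metadata as a JSON sidecar next to it (same stem,
#' `.json`), holding at least `b_values`, `tr_ms`, `te_ms`, `matrix`,
#' `fov_mm`, `slice_thickness_mm`, `gap_mm`, `nex`, `field_strength_T`,
#' `n_slices`, plus the exam identifiers.
#'
#' @param series A `dwi_series`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_dwi <- function(series, path) {
  stopifnot(inherits(series, "dwi_series"))
  RNifti::writeNifti(RNifti::asNifti(series$signal), path)
  p <- series$params
  meta <- list(
    b_values = p$b_values, tr_ms = p$tr_ms, te_ms = p$te_ms,
    matrix = p$matrix, fov_mm = p$fov_mm,
    slice_thickness_mm = p$slice_thickness_mm, gap_mm = p$gap_mm,
    nex = p$nex, field_strength_T = p$field_strength_T,
    n_slices = p$n_slices, parallel_factor = p$parallel_factor,
    half_scan_factor = p$half_scan_factor,
    fat_suppression = p$fat_suppression,
    exam_id = series$exam_id, repeat_index = series$repeat_index,
    session_date = series$session_date
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a DWI series written by [write_dwi()]
#'
#' @param path Path to the `.nii`/`.nii.gz` file; the JSON sidecar must sit
#'   next to it.
#' @return A `dwi_series`.
#' @export
read_dwi <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort(sprintf("Missing JSON sidecar for '%s' (expected '%s').", path, sc))
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4) {
    abort(sprintf("'%s' is not a 4-D DWI volume (found %d dims).",
                  path, length(dim(arr))))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (length(meta$b_values) != dim(arr)[4]) {
    abort(sprintf(
      "'%s': sidecar lists %d b-values but the volume has %d; corrupt exam.",
      path, length(meta$b_values), dim(arr)[4]))
  }
  params <- acquisition_params(
    b_values = meta$b_values, tr_ms = meta$tr_ms, te_ms = meta$te_ms,
    field_strength_T = meta$field_strength_T, matrix = meta$matrix,
    fov_mm = meta$fov_mm, slice_thickness_mm = meta$slice_thickness_mm,
    gap_mm = meta$gap_mm, nex = meta$nex, n_slices = meta$n_slices,
    parallel_factor = meta$parallel_factor %||% NA_real_,
    half_scan_factor = meta$half_scan_factor %||% NA_real_,
    fat_suppression = meta$fat_suppression %||% NA_character_)
  structure(
    list(signal = arr, params = params,
         exam_id = meta$exam_id %||% basename(path),
         repeat_index = as.integer(meta$repeat_index %||% 0L),
         session_date = as.integer(meta$session_date %||% 0L)),
    class = "dwi_series"
  )
}

#' Write an ADC map as NIfTI plus a JSON sidecar
#'
#' @param map An `adc_map`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_adc_map <- function(map, path) {
  stopifnot(inherits(map, "adc_map"))
  RNifti::writeNifti(RNifti::asNifti(map$values), path)
  jsonlite::write_json(
    list(method = map$method, b_values = map$b_values, exam_id = map$exam_id,
         units = "um^2/s"),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write patient scan tables
#'
#' Patient-stage QA consumes tabular ROI statistics, one row per
#' (patient, scanner, session, tissue) with columns `patient_id`,
#' `scanner_id`, `session_date`, `tissue`, `roi_mean_adc`, `roi_sd`,
#' `n_voxels`.
#'
#' @param path CSV path.
#' @return `read_patient_scans()` returns the validated tibble;
#'   `write_patient_scans()` returns `path` invisibly.
#' @export
read_patient_scans <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("patient_id", "scanner_id", "session_date", "tissue",
              "roi_mean_adc", "roi_sd", "n_voxels")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("'", path, "' lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(df$roi_mean_adc <= 0)) abort("`roi_mean_adc` must be positive.")
  key <- df[, c("patient_id", "scanner_id", "session_date", "tissue")]
  if (anyDuplicated(key)) {
    abort("Duplicate (patient, scanner, session, tissue) records.")
  }
  df
}

#' @rdname read_patient_scans
#' @param scans Patient scan tibble.
#' @export
write_patient_scans <- function(scans, path) {
  readr::write_csv(scans, path)
  invisible(path)
}
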