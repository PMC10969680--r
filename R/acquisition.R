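#' Acquisition parameter set for a DWI exam
#'
#' Bundles the sequence parameters the conformance checker inspects.
#' `b_values` must be nonnegative and strictly increasing; the first entry is
#' b_min (normally 0).
#'
#' @param b_values Diffusion weightings in s/mm^2, strictly increasing.
#' @param tr_ms Repetition time, ms.
#' @param te_ms Echo time, ms.
#' @param field_strength_T Main field strength in tesla.
#' @param matrix Acquired matrix (frequency x phase), length-2 integer.
#' @param fov_mm Field of view, mm.
#' @param slice_thickness_mm,gap_mm Slice thickness and inter-slice gap, mm.
#' @param nex Number of excitations (signal averages).
#' @param n_slices Number of slices.
#' @param parallel_factor In-plane parallel imaging acceleration factor.
#' @param half_scan_factor Partial-Fourier (half-scan) factor.
#' @param fat_suppression Fat suppression technique (e.g. "STIR").
#' @param ... Further free-form metadata kept alongside.
#' @return An object of class `acquisition_params` (named list); `n_bvalues`
#'   is derived from `b_values`.
#' @export
acquisition_params <- function(b_values, tr_ms, te_ms,
                               field_strength_T = 3.0,
                               matrix = c(128L, 128L), fov_mm = 220,
                               slice_thickness_mm = 4, gap_mm = 1,
                               nex = 1, n_slices = 25,
                               parallel_factor = 2, half_scan_factor = 0.811,
                               fat_suppression = "STIR", ...) {
  if (length(b_values) < 1 || any(b_values < 0) ||
      any(diff(b_values) <= 0) || anyNA(b_values)) {
    abort("`b_values` must be nonempty, nonnegative and strictly increasing.")
  }
  structure(
    list(b_values = as.numeric(b_values), n_bvalues = length(b_values),
         tr_ms = tr_ms, te_ms = te_ms, field_strength_T = field_strength_T,
         matrix = as.integer(matrix), fov_mm = fov_mm,
         slice_thickness_mm = slice_thickness_mm, gap_mm = gap_mm,
         nex = nex, n_slices = n_slices, parallel_factor = parallel_factor,
         half_scan_factor = half_scan_factor,
         fat_suppression = fat_suppression, extras = list(...)),
    class = "acquisition_params"
  )
}

#' QIBA phantom acquisition protocol
#'
#' The scanner-validation protocol: five b-values (0, 500, 1000, 1500,
#' 2000 s/mm^2), TR 8000 ms, shortest TE (< 60 ms), NEX 2, 25 slices of
#' 4 mm with 1 mm gap, 220 mm FOV on a 128 x 128 matrix.
#'
#' @param ... Overrides passed to [acquisition_params()].
#' @return An `acquisition_params` object.
#' @export
qiba_phantom_protocol <- function(...) {
  defaults <- list(
    b_values = c(0, 500, 1000, 1500, 2000), tr_ms = 8000, te_ms = 55,
    field_strength_T = 3.0, matrix = c(128L, 128L), fov_mm = 220,
    slice_thickness_mm = 4, gap_mm = 1, nex = 2, n_slices = 25,
    parallel_factor = 2, half_scan_factor = 0.811, fat_suppression = "STIR"
  )
  do.call(acquisition_params, modifyList(defaults, list(...)))
}

#' Clinical brain acquisition protocol
#'
#' A routine clinical brain DWI protocol: two b-values (0 and 1000 s/mm^2),
#' TR 3000 ms, TE < 60 ms, single average, 5 mm slices with 2 mm gap,
#' 128 x 128 matrix. ADC maps from this protocol use the two-point
#' mono-exponential fit.
#'
#' @param ... Overrides passed to [acquisition_params()].
#' @return An `acquisition_params` object.
#' @export
clinical_brain_protocol <- function(...) {
  defaults <- list(
    b_values = c(0, 1000), tr_ms = 3000, te_ms = 58,
    field_strength_T = 3.0, matrix = c(128L, 128L), fov_mm = 240,
    slice_thickness_mm = 5, gap_mm = 2, nex = 1, n_slices = 25,
    parallel_factor = 2.5, half_scan_factor = 0.811, fat_suppression = "STIR"
  )
  do.call(acquisition_params, modifyList(defaults, list(...)))
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "<acquisition_params> %d b-values [%s] s/mm^2, TR %s ms, TE %s ms, NEX %s\n",
    x$n_bvalues, paste(x$b_values, collapse = ", "), x$tr_ms, x$te_ms, x$nex))
  invisible(x)
}

#' Specify a measurement noise model
#'
#' Magnitude MRI noise: `"rician"` reconstructs the magnitude of a complex
#' signal with independent Gaussian noise of standard deviation `sigma` in
#' each channel, `"gaussian"` adds real Gaussian noise, `"none"` is
#' noiseless. The b = 0 SNR of a vial with baseline signal `s0` is
#' approximately `s0 / sigma` (per excitation).
#'
#' @param kind One of "rician", "gaussian", "none".
#' @param sigma Noise standard deviation in signal units (>= 0); ignored for
#'   `kind = "none"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("rician", "gaussian", "none"), sigma = 0) {
  kind <- arg_match(kind)
  check_number(sigma, "sigma", 0)
  if (kind == "none") sigma <- 0
  structure(list(kind = kind, sigma = sigma), class = "noise_model")
}
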