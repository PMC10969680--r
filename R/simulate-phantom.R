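#' Simulate one phantom DWI exam
#'
#' Forward model: inside vial v the noiseless signal at diffusion weighting b
#' is `S(b) = s0_v * exp(-b * ADC_v * 1e-6)` with ADC in um^2/s and b in
#' s/mm^2 (the 1e-6 converts um^2/s to mm^2/s). Rician noise reconstructs
#' the magnitude `sqrt((S + n1)^2 + n2^2)` with independent
#' `n1, n2 ~ N(0, sigma^2)`; `nex` independent magnitude images are averaged,
#' as in single-coil magnitude MRI with signal averaging.
#'
#' @param layout A [make_phantom_layout()] object.
#' @param params An [acquisition_params()] object; its `b_values` define the
#'   4th axis.
#' @param noise A [noise_model()].
#' @param seed Integer seed for reproducibility (NULL leaves the RNG alone).
#' @param exam_id Identifier stored with the series.
#' @param repeat_index Repeat number within a session (0-based).
#' @param session_date Ordinal day of acquisition.
#' @return A `dwi_series` object: list with 4-D `signal`
#'   (slice, row, col, b), `params`, `exam_id`, `repeat_index`,
#'   `session_date`.
#' @export
#' @examples
#' lay <- make_phantom_layout(n_ring = 0, grid_shape = c(1, 32, 32))
#' ex <- simulate_dwi_exam(lay, qiba_phantom_protocol(), noise_model("none"))
#' max(ex$signal[, , , 1]) # s0 = 1000 inside the vial
simulate_dwi_exam <- function(layout, params, noise = noise_model("none"),
                              seed = NULL, exam_id = "exam",
                              repeat_index = 0L, session_date = 0L) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(params, "acquisition_params"),
            inherits(noise, "noise_model"))
  b <- params$b_values
  shp <- layout$grid_shape
  clean <- array(layout$background, c(shp, length(b)))
  for (i in seq_len(nrow(layout$vials))) {
    v <- layout$vials[i, ]
    mask <- vial_mask(layout, v$label)
    decay <- v$s0 * exp(-b * v$true_adc * 1e-6)
    for (k in seq_along(b)) {
      vol <- clean[, , , k, drop = FALSE]
      dim(vol) <- shp
      vol[mask] <- decay[k]
      clean[, , , k] <- vol
    }
  }

  signal <- with_seed_or_not(seed, apply_noise(clean, noise, params$nex))

  structure(
    list(signal = signal, params = params, exam_id = exam_id,
         repeat_index = as.integer(repeat_index),
         session_date = as.integer(session_date)),
    class = "dwi_series"
  )
}

apply_noise <- function(clean, noise, nex = 1) {
  if (noise$kind == "none" || noise$sigma == 0) return(clean)
  n <- length(clean)
  acc <- array(0, dim(clean))
  for (avg in seq_len(max(1L, as.integer(nex)))) {
    if (noise$kind == "rician") {
      acc <- acc + sqrt((clean + rnorm(n, 0, noise$sigma))^2 +
                          rnorm(n, 0, noise$sigma)^2)
    } else {
      acc <- acc + clean + rnorm(n, 0, noise$sigma)
    }
  }
  out <- acc / max(1L, as.integer(nex))
  if (noise$kind == "gaussian") out[out < 0] <- 0
  out
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("<dwi_series> '%s' repeat %d, day %d: %s voxels x %d b-values\n",
              x$exam_id, x$repeat_index, x$session_date,
              paste(dim(x$signal)[1:3], collapse = " x "),
              dim(x$signal)[4]))
  invisible(x)
}

#' Simulate a repeated-exam session
#'
#' Emulates the QIBA repeat design: several back-to-back exams of the same
#' phantom (short-term repeatability), optionally with a small multiplicative
#' drift of the baseline signal between repeats.
#'
#' @inheritParams simulate_dwi_exam
#' @param n_repeats Number of exams (>= 2).
#' @param inter_exam_cv Fractional multiplicative s0 drift between repeats
#'   (lognormal-free: `s0 * (1 + delta)`, `delta ~ N(0, inter_exam_cv^2)`).
#' @param session_date Ordinal day stamped on every repeat.
#' @return List of `dwi_series`, `repeat_index` 0 .. n_repeats - 1.
#' @export
simulate_repeated_exams <- function(layout, params, noise = noise_model("none"),
                                    n_repeats = 4, inter_exam_cv = 0,
                                    seed = NULL, session_date = 0L) {
  if (!is.numeric(n_repeats) || n_repeats < 2) {
    abort("`n_repeats` must be >= 2 for a repeatability design.")
  }
  check_number(inter_exam_cv, "inter_exam_cv", 0)
  with_seed_or_not(seed, {
    purrr::map(seq_len(n_repeats) - 1L, function(r) {
      lay <- layout
      if (inter_exam_cv > 0) {
        lay$vials$s0 <- lay$vials$s0 * (1 + rnorm(nrow(lay$vials), 0, inter_exam_cv))
      }
      simulate_dwi_exam(lay, params, noise, seed = NULL,
                        exam_id = sprintf("exam_r%d", r),
                        repeat_index = r, session_date = session_date)
    })
  })
}
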