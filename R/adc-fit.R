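#' Log-linear ADC fit for one voxel
#'
#' Ordinary least squares of `ln S` on b: under the mono-exponential model
#' `S(b) = S0 exp(-b * ADC)` the slope is `-ADC` in mm^2/s. Signals at or
#' below `min_signal` are dropped (point-wise, not voxel-wise); fewer than
#' `require_n_points` usable points yields NaN rather than an error so that
#' map-level fitting can flag the voxel and continue.
#'
#' @param signals Numeric vector of signals, one per b-value.
#' @param b_values Matching diffusion weightings, s/mm^2.
#' @param min_signal Exclusion threshold; points with `signal <= min_signal`
#'   are unusable (default 0, i.e. positivity needed for the log).
#' @param require_n_points Minimum usable points (>= 2).
#' @return Named list `adc` (um^2/s) and `s0` (= exp(intercept)); both NaN
#'   when the voxel is unfittable.
#' @export
#' @examples
#' b <- c(0, 500, 1000, 1500, 2000)
#' fit_adc_loglinear(1000 * exp(-b * 1.1e-3), b) # adc 1100, s0 1000
fit_adc_loglinear <- function(signals, b_values, min_signal = 0,
                              require_n_points = 2) {
  if (length(signals) != length(b_values)) {
    abort("`signals` and `b_values` must have the same length.")
  }
  if (require_n_points < 2) abort("`require_n_points` must be >= 2.")
  use <- is.finite(signals) & signals > min_signal
  if (sum(use) < require_n_points) return(list(adc = NaN, s0 = NaN))
  x <- b_values[use]
  if (length(unique(x)) < 2) return(list(adc = NaN, s0 = NaN))
  y <- log(signals[use])
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)       # mm^2/s (negated)
  list(adc = -slope * 1e6, s0 = exp(mean(y) - slope * mean(x)))
}

#' Two-point mono-exponential ADC
#'
#' The clinical two-b-value estimator
#' `ADC = ln(S_low / S_high) / (b_high - b_low)`, returned in um^2/s.
#' Vectorised over all arguments. Nonpositive signals give NaN; noisy data
#' may legitimately yield negative ADCs, which are returned (callers flag
#' them).
#'
#' @param s_low,s_high Signals at the lower and higher b-value.
#' @param b_low,b_high Diffusion weightings, s/mm^2, `b_high > b_low`.
#' @return ADC in um^2/s (NaN where unusable).
#' @export
#' @examples
#' fit_adc_twopoint(1000, 1000 * exp(-1.1), 0, 1000) # 1100
fit_adc_twopoint <- function(s_low, s_high, b_low, b_high) {
  if (any(b_high <= b_low)) abort("`b_high` must exceed `b_low`.")
  bad <- !is.finite(s_low) | !is.finite(s_high) | s_low <= 0 | s_high <= 0
  ratio <- ifelse(bad, 1, s_low / s_high)
  out <- log(ratio) / (b_high - b_low) * 1e6
  out[bad] <- NaN
  out
}

#' Options for voxelwise ADC map fitting
#'
#' @param method `"loglinear"` (all b-values, OLS on ln S — the phantom
#'   protocol's map) or `"two_point"` (lowest and highest b — the clinical
#'   protocol's map).
#' @param min_signal Signal threshold below which a voxel's b-point is
#'   excluded (>= 0).
#' @param require_n_points Minimum usable b-points per voxel (>= 2).
#' @return A `fit_options` list.
#' @export
fit_options <- function(method = c("loglinear", "two_point"),
                        min_signal = 0, require_n_points = 2) {
  method <- arg_match(method)
  check_number(min_signal, "min_signal", 0)
  if (require_n_points < 2) abort("`require_n_points` must be >= 2.")
  structure(list(method = method, min_signal = min_signal,
                 require_n_points = as.integer(require_n_points)),
            class = "fit_options")
}

#' Compute a voxelwise ADC map from a DWI series
#'
#' Applies the chosen fit to every voxel. The log-linear method uses all
#' usable b-points; the two-point method uses the lowest and highest
#' b-value. Unfittable voxels are NaN. Fitting is vectorised by grouping
#' voxels that share the same usable-point pattern and solving the
#' closed-form normal equations per group.
#'
#' @param series A `dwi_series`.
#' @param options A [fit_options()] object (or a method string).
#' @return An `adc_map` object: `values` and `s0_map` 3-D arrays (um^2/s and
#'   signal units), `method`, `b_values`, `exam_id`, plus `n_flagged`
#'   (unfittable or negative-ADC voxels).
#' @export
compute_adc_map <- function(series, options = fit_options()) {
  stopifnot(inherits(series, "dwi_series"))
  if (is.character(options)) options <- fit_options(options)
  b <- series$params$b_values
  if (length(b) < 2) abort("ADC fitting needs at least 2 b-values.")
  shp <- dim(series$signal)[1:3]
  V <- matrix(series$signal, nrow = prod(shp), ncol = length(b))

  if (options$method == "two_point") {
    i <- c(1L, length(b))
    s_lo <- V[, i[1]]; s_hi <- V[, i[2]]
    ok <- is.finite(s_lo) & is.finite(s_hi) &
      s_lo > options$min_signal & s_hi > options$min_signal
    adc <- rep(NaN, nrow(V)); s0 <- rep(NaN, nrow(V))
    adc[ok] <- fit_adc_twopoint(s_lo[ok], s_hi[ok], b[i[1]], b[i[2]])
    s0[ok] <- s_lo[ok] * exp(b[i[1]] * adc[ok] * 1e-6)
    b_used <- b[i]
  } else {
    usable <- is.finite(V) & V > options$min_signal
    adc <- rep(NaN, nrow(V)); s0 <- rep(NaN, nrow(V))
    pattern <- usable %*% (2^(seq_along(b) - 1))
    for (p in unique(pattern[rowSums(usable) >= options$require_n_points])) {
      rows <- which(pattern == p)
      cols <- which(bitwAnd(p, 2^(seq_along(b) - 1)) > 0)
      if (length(cols) < options$require_n_points ||
          length(unique(b[cols])) < 2) next
      x <- b[cols]
      Y <- log(V[rows, cols, drop = FALSE])
      xc <- x - mean(x)
      slope <- (Y %*% xc) / sum(xc^2)
      adc[rows] <- -slope * 1e6
      s0[rows] <- exp(rowMeans(Y) - slope * mean(x))
    }
    b_used <- b
  }

  structure(
    list(values = array(adc, shp), s0_map = array(s0, shp),
         method = options$method, b_values = b_used,
         exam_id = series$exam_id,
         n_flagged = sum(!is.finite(adc) | adc <= 0)),
    class = "adc_map"
  )
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> %s fit of '%s' (%s voxels), b = [%s]; %d flagged\n",
              x$method, x$exam_id, paste(dim(x$values), collapse = " x "),
              paste(x$b_values, collapse = ", "), x$n_flagged))
  invisible(x)
}
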