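#' ADC bias against the ground truth
#'
#' `bias = mu - DC_true`; `%bias = 100 * (mu - DC_true) / DC_true`, where mu
#' is the VOI-mean ADC and DC_true the reference diffusivity of the vial
#' (1100 um^2/s for the central 0% PVP water vial).
#'
#' @param mu Measured VOI-mean ADC, um^2/s.
#' @param dc_true Reference ADC, um^2/s (> 0).
#' @return Tibble with `bias` (um^2/s) and `percent_bias` (%).
#' @export
#' @examples
#' adc_bias(1078, 1100) # bias -22, percent_bias -2
adc_bias <- function(mu, dc_true) {
  if (any(dc_true <= 0)) abort("`dc_true` must be positive.")
  tibble::tibble(bias = mu - dc_true,
                 percent_bias = 100 * (mu - dc_true) / dc_true)
}

#' Repeatability: pooled within-group SD, RC and wCV
#'
#' The within-subject standard deviation `sigma_w` is the square root of the
#' unweighted mean of within-group sample variances (each with an n - 1
#' denominator); groups with fewer than 2 observations are dropped. The
#' repeatability coefficient is `RC = 2.77 * sigma_w` (the literal profile
#' constant, approximately 1.96 * sqrt(2)) and the within-subject
#' coefficient of variation is `wCV = 100 * sigma_w / mu` with mu the grand
#' mean over all qualifying observations.
#'
#' @param data Data frame of repeated measurements.
#' @param value Column of measured values (um^2/s), tidy-selected.
#' @param group Column identifying the repeated unit (vial, patient).
#' @return One-row tibble: `n_groups`, `n_obs`, `mean`, `sigma_w`, `rc`,
#'   `wcv` (units um^2/s for `rc`, % for `wcv`).
#' @export
#' @examples
#' df <- data.frame(vial = rep("a", 4), adc = c(1100, 1102, 1099, 1101))
#' repeatability(df, adc, vial)
repeatability <- function(data, value, group) {
  df <- dplyr::transmute(data, .value = {{ value }}, .group = {{ group }})
  counts <- table(df$.group)
  df <- df[df$.group %in% names(counts)[counts >= 2], , drop = FALSE]
  if (nrow(df) == 0) {
    abort("Repeatability needs at least one group with >= 2 observations.")
  }
  if (any(df$.value <= 0)) abort("Repeatability values must be positive.")
  vars <- tapply(df$.value, df$.group, var)
  sigma_w <- sqrt(mean(vars))
  mu <- mean(df$.value)
  tibble::tibble(n_groups = length(vars), n_obs = nrow(df), mean = mu,
                 sigma_w = sigma_w, rc = 2.77 * sigma_w,
                 wcv = 100 * sigma_w / mu)
}

#' Repeatability parameters from a published mean and SD
#'
#' Recomputes RC and wCV from summary statistics alone (`RC = 2.77 * sigma`,
#' `wCV = 100 * sigma / mu`), as when auditing a printed QA table that
#' reports mean +/- SD per tissue and scanner.
#'
#' @param mu Mean value (um^2/s). Vectorised.
#' @param sigma Within-subject SD (um^2/s). Vectorised.
#' @return Tibble with `mean`, `sigma_w`, `rc`, `wcv`.
#' @export
#' @examples
#' repeatability_from_summary(801.4, 16.2) # rc 44.9, wcv 2.0 at 1 d.p.
repeatability_from_summary <- function(mu, sigma) {
  if (any(mu <= 0) || any(sigma < 0)) {
    abort("`mu` must be positive and `sigma` nonnegative.")
  }
  tibble::tibble(mean = mu, sigma_w = sigma, rc = 2.77 * sigma,
                 wcv = 100 * sigma / mu)
}

#' Linearity of measured ADC against reference diffusivity
#'
#' Fits `mu = beta0 + beta1 * DC_true` by ordinary least squares across
#' vials and reports the slope with its 95% confidence interval
#' (t-quantile, n - 2 degrees of freedom) and R-squared. Conformance
#' requires R^2 above 0.90 and the slope interval inside 0.95-1.05.
#'
#' @param data Data frame with one row per vial.
#' @param dc_true Column of reference ADCs (>= 3 distinct values).
#' @param mu Column of measured VOI-mean ADCs.
#' @param conf_level Confidence level for the slope interval.
#' @return An object of class `linearity_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `slope_ci` (lo, hi), `n`, and the underlying
#'   `data`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
linearity <- function(data, dc_true, mu, conf_level = 0.95) {
  df <- dplyr::transmute(data, dc_true = {{ dc_true }}, mu = {{ mu }})
  if (nrow(df) < 3 || length(unique(df$dc_true)) < 3) {
    abort("Linearity needs >= 3 points with >= 3 distinct reference values.")
  }
  fit <- lm(mu ~ dc_true, data = df)
  # exact affine data triggers summary.lm's "essentially perfect fit"
  # warning; that regime is expected here (noiseless phantom)
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients["dc_true", "Std. Error"]
  tq <- qt(1 - (1 - conf_level) / 2, df = nrow(df) - 2)
  slope <- unname(coef(fit)["dc_true"])
  structure(
    list(slope = slope, intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = sm$r.squared,
         slope_ci = c(lo = slope - tq * se, hi = slope + tq * se),
         conf_level = conf_level, n = nrow(df), data = df),
    class = "linearity_fit"
  )
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf(
    "<linearity_fit> n = %d: slope %.3f [%.3f, %.3f], intercept %.1f, R^2 %.4f\n",
    x$n, x$slope, x$slope_ci[["lo"]], x$slope_ci[["hi"]], x$intercept,
    x$r_squared))
  invisible(x)
}

#' Maximum b-value dependence of the ADC
#'
#' From two-point ADC estimates computed against the minimum b-value
#' (one estimate per higher b), returns the maximum relative deviation from
#' their average: `100 * max_b |ADC_b - mean(ADC)| / mean(ADC)`. Requires at
#' least two estimates; a protocol with a single nonzero b-value cannot
#' evaluate the metric and yields `evaluable = FALSE` with value `NA`.
#'
#' @param data Data frame with one row per higher b-value.
#' @param b Column of b-values (s/mm^2).
#' @param adc Column of VOI-mean two-point ADCs (um^2/s).
#' @return Tibble with `max_dependence_pct`, `n_b`, `evaluable`.
#' @export
#' @examples
#' df <- data.frame(b = c(500, 1000, 1500, 2000),
#'                  adc = c(1000, 1000, 1020, 1000))
#' bvalue_dependence(df, b, adc) # 1.4925...%
bvalue_dependence <- function(data, b, adc) {
  df <- dplyr::transmute(data, b = {{ b }}, adc = {{ adc }})
  adc <- df$adc
  if (length(adc) < 2) {
    return(tibble::tibble(max_dependence_pct = NA_real_,
                          n_b = length(adc), evaluable = FALSE))
  }
  m <- mean(adc)
  tibble::tibble(max_dependence_pct = 100 * max(abs(adc - m)) / m,
                 n_b = length(adc), evaluable = TRUE)
}

#' Random measurement error
#'
#' `100 * sigma / mu` from the spatial VOI statistics of the central-vial
#' ADC map of a single exam: the within-VOI coefficient of variation.
#'
#' @param voi A [voi_statistics()] row, or a numeric mean via `mu =`/`sigma =`.
#' @param mu,sigma Alternative scalar interface.
#' @return Random error in percent.
#' @export
random_error <- function(voi = NULL, mu = NULL, sigma = NULL) {
  if (!is.null(voi)) {
    mu <- voi$mean; sigma <- voi$sd
  }
  if (any(mu <= 0)) abort("VOI mean must be positive.")
  100 * sigma / mu
}

#' Noise image from two repeated b = 0 acquisitions
#'
#' The difference method: `|rep1 - rep2| / sqrt(2)` voxelwise, which has the
#' same expected magnitude as the per-acquisition noise when the two repeats
#' are independent and identically distributed.
#'
#' @param b0_rep1,b0_rep2 Same-shape numeric arrays (b = 0 volumes of two
#'   repeats).
#' @return Array of the same shape.
#' @export
make_noise_image <- function(b0_rep1, b0_rep2) {
  if (!identical(dim(b0_rep1), dim(b0_rep2))) {
    abort("Repeated b = 0 volumes must have identical shapes.")
  }
  abs(b0_rep1 - b0_rep2) / sqrt(2)
}

#' Signal-to-noise ratio by the difference method
#'
#' Ratio of the in-mask spatial mean of the b = 0 signal image to the
#' in-mask spatial mean of the [make_noise_image()] volume. A zero noise
#' mean (e.g. noiseless simulation) makes the SNR infinite and not
#' evaluable.
#'
#' @param signal_b0 b = 0 signal volume.
#' @param noise_image Noise volume from [make_noise_image()].
#' @param mask Logical array selecting the ROI.
#' @return Tibble with `snr` and `evaluable`.
#' @export
snr <- function(signal_b0, noise_image, mask) {
  if (!identical(dim(signal_b0), dim(noise_image)) ||
      !identical(dim(signal_b0), dim(mask))) {
    abort("`signal_b0`, `noise_image` and `mask` shapes must match.")
  }
  if (!any(mask)) abort("SNR mask is empty.")
  noise_mean <- mean(noise_image[mask])
  if (noise_mean == 0) {
    return(tibble::tibble(snr = NA_real_, evaluable = FALSE))
  }
  tibble::tibble(snr = mean(signal_b0[mask]) / noise_mean, evaluable = TRUE)
}
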