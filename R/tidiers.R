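#' Tidy a linearity fit
#'
#' @param x A `linearity_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `conf.low`, `conf.high` (slope only).
#' @method tidy linearity_fit
#' @export
tidy.linearity_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "dc_true"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, x$slope_ci[["lo"]]),
    conf.high = c(NA_real_, x$slope_ci[["hi"]])
  )
}

#' @rdname tidy.linearity_fit
#' @return `glance()` returns a one-row tibble with `r.squared`, `slope`,
#'   `nobs`.
#' @method glance linearity_fit
#' @export
glance.linearity_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope, nobs = x$n)
}

#' Tidy a phantom QA run
#'
#' @param x A `phantom_qa` object.
#' @param ... Unused.
#' @return The conformance verdict tibble (`metric`, `value`, `claim`,
#'   `units`, `passed`).
#' @method tidy phantom_qa
#' @export
tidy.phantom_qa <- function(x, ...) {
  tibble::as_tibble(x$conformance)
}

#' @rdname tidy.phantom_qa
#' @return `glance()` returns overall verdicts and headline metrics.
#' @method glance phantom_qa
#' @export
glance.phantom_qa <- function(x, ...) {
  m <- setNames(x$metrics$value, x$metrics$metric)
  tibble::tibble(
    overall_pass = attr(x$conformance, "overall_pass"),
    protocol_overall = attr(x$protocol, "overall"),
    adc_bias_pct = m[["adc_bias_pct"]],
    wcv_short_term = m[["wcv_short_term"]],
    snr_b0 = m[["snr_b0"]]
  )
}
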