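#' Plot one slice of an ADC map
#'
#' @param object An `adc_map`.
#' @param slice Slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster of the slice, in um^2/s.
#' @method autoplot adc_map
#' @export
autoplot.adc_map <- function(object, slice = NULL, ...) {
  slice <- slice %||% ceiling(dim(object$values)[1] / 2)
  sl <- object$values[slice, , ]
  df <- tidyr::expand_grid(row = seq_len(nrow(sl)), col = seq_len(ncol(sl)))
  df$adc <- as.vector(t(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$adc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = expression(ADC ~ (mu * m^2 / s))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("ADC map (%s fit), slice %d",
                                  object$method, slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot measured ADC against reference diffusivity
#'
#' Scatter of per-vial measured means against ground truth with the OLS
#' line and the identity for reference.
#'
#' @param object A `linearity_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot linearity_fit
#' @export
autoplot.linearity_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dc_true, y = .data$mu)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(DC[true] ~ (mu * m^2 / s)),
      y = expression(measured ~ ADC ~ (mu * m^2 / s)),
      title = sprintf("Linearity: slope %.3f, R² %.4f",
                      object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a conformance report
#'
#' One tile per metric coloured by verdict.
#'
#' @param object A `conformance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conformance_report
#' @export
autoplot.conformance_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- sprintf("%.3g", df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = 1, y = .data$metric,
                                   fill = .data$passed)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_manual(values = c(pass = "#7fbf7b", fail = "#d73027",
                                          not_evaluable = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "verdict",
                  title = "QIBA claim conformance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
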