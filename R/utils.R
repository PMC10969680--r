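#' Round half away from zero
#'
#' Reported QC tables round half-up (so 44.85 prints as 44.9), unlike base
#' [round()]'s round-half-even. Used for display only; all computations keep
#' full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.945, 1) # 2.9
#' round_half_up(44.85, 1) # 44.9
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared numeric validation helper
check_number <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) ||
      (strict && x <= lower) || (!strict && x < lower)) {
    cmp <- if (strict) ">" else ">="
    abort(sprintf("`%s` must be a single finite number %s %s.", name, cmp, lower))
  }
  invisible(x)
}

# seed-scoped evaluation: NULL seed runs unseeded
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
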