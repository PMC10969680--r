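#' Load the QIBA claim specifications
#'
#' Reads the versioned claims file shipped with the package (or a user
#' override) into a claims list for [check_claims()]. Each claim carries a
#' metric name, a comparator (`abs_le`, `le`, `lt`, `ge`, `gt`, `ci_within`,
#' `range`) and its threshold(s).
#'
#' @param path Optional path to a YAML claims file; defaults to the shipped
#'   profile transcription.
#' @return A `claims_spec` list with `version` and `claims`.
#' @export
qiba_claims <- function(path = NULL) {
  path <- path %||% system.file("extdata", "qiba_claims.yaml",
                                package = "dwiqc", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  valid <- c("abs_le", "le", "lt", "ge", "gt", "ci_within", "range")
  for (cl in raw$claims) {
    if (is.null(cl$metric) || is.null(cl$cmp) || !(cl$cmp %in% valid)) {
      abort(sprintf("Malformed claim entry for metric '%s'.",
                    cl$metric %||% "?"))
    }
    if (cl$cmp %in% c("ci_within", "range")) {
      if (is.null(cl$lo) || is.null(cl$hi) || cl$lo >= cl$hi) {
        abort(sprintf("Claim '%s': range comparator needs lo < hi.", cl$metric))
      }
    } else if (is.null(cl$threshold)) {
      abort(sprintf("Claim '%s': missing threshold.", cl$metric))
    }
  }
  structure(list(version = raw$version, claims = raw$claims),
            class = "claims_spec")
}

eval_claim <- function(claim, value, lo = NA_real_, hi = NA_real_) {
  if (is.na(value) && claim$cmp != "ci_within") return("not_evaluable")
  ok <- switch(claim$cmp,
    abs_le = abs(value) <= claim$threshold,
    le = value <= claim$threshold,
    lt = value < claim$threshold,
    ge = value >= claim$threshold,
    gt = value > claim$threshold,
    range = value >= claim$lo && value <= claim$hi,
    ci_within = {
      if (is.na(lo) || is.na(hi)) return("not_evaluable")
      lo >= claim$lo && hi <= claim$hi
    }
  )
  if (isTRUE(ok)) "pass" else "fail"
}

#' Check computed metrics against the QIBA claims
#'
#' Joins a metric table to the claim specifications and assigns a tri-state
#' verdict per metric: `pass`, `fail`, or `not_evaluable` (metric `NA`, e.g.
#' b-value dependence under a two-b-value protocol, or no matching claim).
#' The overall verdict passes iff no metric fails; `not_evaluable` never
#' fails the exam.
#'
#' @param metrics Tibble with columns `metric`, `value` and (for interval
#'   claims such as the linearity slope) `lo`, `hi`.
#' @param claims A [qiba_claims()] object.
#' @return A `conformance_report`: tibble of verdicts with attributes
#'   `overall_pass` and `claims_version`. Metrics without a claim are
#'   flagged `not_evaluable` with `claim = NA`.
#' @export
#' @examples
#' m <- tibble::tibble(metric = "adc_bias_pct", value = -2.3)
#' check_claims(m, qiba_claims())
check_claims <- function(metrics, claims = qiba_claims()) {
  stopifnot(inherits(claims, "claims_spec"))
  if (!all(c("metric", "value") %in% names(metrics))) {
    abort("`metrics` needs columns `metric` and `value`.")
  }
  if (!("lo" %in% names(metrics))) metrics$lo <- NA_real_
  if (!("hi" %in% names(metrics))) metrics$hi <- NA_real_
  by_name <- setNames(claims$claims, purrr::map_chr(claims$claims, "metric"))

  rows <- purrr::pmap_dfr(
    metrics[, c("metric", "value", "lo", "hi")],
    function(metric, value, lo, hi) {
      cl <- by_name[[metric]]
      if (is.null(cl)) {
        return(tibble::tibble(metric = metric, value = value,
                              claim = NA_character_, units = NA_character_,
                              passed = "not_evaluable"))
      }
      claim_txt <- if (cl$cmp %in% c("ci_within", "range")) {
        sprintf("%s [%g, %g]", cl$cmp, cl$lo, cl$hi)
      } else {
        sprintf("%s %g", cl$cmp, cl$threshold)
      }
      tibble::tibble(metric = metric, value = value, claim = claim_txt,
                     units = cl$units %||% "",
                     passed = eval_claim(cl, value, lo, hi))
    })

  structure(rows, class = c("conformance_report", class(rows)),
            overall_pass = !any(rows$passed == "fail"),
            claims_version = claims$version)
}

#' @export
print.conformance_report <- function(x, ...) {
  cat(sprintf("<conformance_report> claims %s — overall: %s\n",
              attr(x, "claims_version") %||% "?",
              if (attr(x, "overall_pass")) "PASS" else "FAIL"))
  NextMethod()
}

#' Load a tiered acquisition-protocol specification
#'
#' Reads the shipped protocol YAML for a profile (`qiba_phantom` is a
#' single-tier compliance spec; `clinical_brain` has ideal / target /
#' acceptable tiers). Missing tiers inherit downward and the loader
#' validates tier monotonicity for every numeric rule: any value meeting
#' ideal must also meet target and acceptable.
#'
#' @param profile `"qiba_phantom"` or `"clinical_brain"`, or ignored when
#'   `path` is given.
#' @param path Optional path to a custom protocol YAML.
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(profile = c("qiba_phantom", "clinical_brain"),
                          path = NULL) {
  if (is.null(path)) {
    profile <- arg_match(profile)
    path <- system.file("extdata", paste0("protocol_", profile, ".yaml"),
                        package = "dwiqc", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  params <- purrr::map(raw$parameters, function(p) {
    if (is.null(p$acceptable)) {
      abort(sprintf("Parameter '%s' lacks an acceptable rule.", p$parameter))
    }
    p$target <- p$target %||% p$acceptable
    p$ideal <- p$ideal %||% p$target
    check_tier_monotone(p)
    p
  })
  structure(list(profile = raw$profile, parameters = params),
            class = "protocol_spec")
}

rule_interval <- function(rule) {
  s <- isTRUE(rule$strict)
  switch(rule$cmp,
    min = c(rule$value + s * 1e-9, Inf),
    max = c(-Inf, rule$value - s * 1e-9),
    range = c(rule$lo, rule$hi),
    eq = c(rule$value, rule$value),
    NULL
  )
}

check_tier_monotone <- function(p) {
  iv <- list(ideal = rule_interval(p$ideal), target = rule_interval(p$target),
             acceptable = rule_interval(p$acceptable))
  pairs <- list(c("ideal", "target"), c("target", "acceptable"))
  for (pr in pairs) {
    a <- iv[[pr[1]]]; b <- iv[[pr[2]]]
    if (!is.null(a) && !is.null(b) && (a[1] < b[1] || a[2] > b[2])) {
      abort(sprintf(
        "Parameter '%s': tier '%s' is not nested within '%s' (non-monotone spec).",
        p$parameter, pr[1], pr[2]))
    }
  }
  invisible(p)
}

satisfies_rule <- function(rule, value) {
  s <- isTRUE(rule$strict)
  switch(rule$cmp,
    eq = isTRUE(all(abs(value - rule$value) < 1e-9)),
    min = if (s) all(value > rule$value) else all(value >= rule$value),
    max = if (s) all(value < rule$value) else all(value <= rule$value),
    range = all(value >= rule$lo & value <= rule$hi),
    set_eq = length(value) == length(rule$value) &&
      isTRUE(all(abs(sort(as.numeric(value)) -
                       sort(as.numeric(rule$value))) < 1e-9)),
    `in` = all(value %in% rule$value),
    abort(sprintf("Unknown protocol comparator '%s'.", rule$cmp))
  )
}

extract_param <- function(params, key) {
  derived <- switch(key,
    b_max = max(params$b_values),
    matrix_freq = params$matrix[1],
    matrix_phase = params$matrix[2],
    NULL)
  if (!is.null(derived)) return(derived)
  params[[key]] %||% params$extras[[key]]
}

#' Check an exam's acquisition parameters against a protocol tier spec
#'
#' Labels every parameter with the highest tier it satisfies (`ideal`,
#' `target`, `acceptable`), or `non_conformant`, `waived` (a recorded
#' deviation, e.g. a vendor forcing NEX 1), or `unknown` when the metadata
#' lacks the parameter. Overall compliance requires every parameter at
#' least acceptable (waivers excepted); any unknown parameter makes the
#' overall verdict `not_evaluable`.
#'
#' @param params An [acquisition_params()] object.
#' @param spec A [protocol_spec()] (or profile name).
#' @param waivers Character vector of parameter names whose deviations are
#'   waived rather than failed.
#' @return A `protocol_report` tibble (`parameter`, `value`, `tier`) with
#'   attributes `overall` (`"compliant"`, `"non_compliant"`,
#'   `"not_evaluable"`) and `profile`.
#' @export
#' @examples
#' rep <- check_protocol_compliance(clinical_brain_protocol(),
#'                                  protocol_spec("clinical_brain"))
#' attr(rep, "overall")
check_protocol_compliance <- function(params, spec = protocol_spec("qiba_phantom"),
                                      waivers = character()) {
  stopifnot(inherits(params, "acquisition_params"))
  if (is.character(spec)) spec <- protocol_spec(spec)

  rows <- purrr::map_dfr(spec$parameters, function(p) {
    value <- extract_param(params, p$extract)
    if (is.null(value) || all(is.na(value))) {
      return(tibble::tibble(parameter = p$parameter, value = NA_character_,
                            tier = "unknown"))
    }
    tier <- if (satisfies_rule(p$ideal, value)) "ideal"
      else if (satisfies_rule(p$target, value)) "target"
      else if (satisfies_rule(p$acceptable, value)) "acceptable"
      else if (p$parameter %in% waivers) "waived"
      else "non_conformant"
    tibble::tibble(parameter = p$parameter,
                   value = paste(format(value), collapse = " x "),
                   tier = tier)
  })

  overall <- if (any(rows$tier == "unknown")) "not_evaluable"
    else if (any(rows$tier == "non_conformant")) "non_compliant"
    else "compliant"
  structure(rows, class = c("protocol_report", class(rows)),
            overall = overall, profile = spec$profile)
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report> profile '%s' — overall: %s\n",
              attr(x, "profile"), attr(x, "overall")))
  NextMethod()
}
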