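test_that("claim verdicts honour the printed comparators, including boundaries", {
  claims <- qiba_claims()
  m <- tibble::tibble(
    metric = c("adc_bias_pct", "wcv_short_term", "rc_short_term",
               "max_bvalue_dependence_pct", "snr_b0"),
    value = c(-2.3, 0.5, 15, NA_real_, 45))
  rep <- check_claims(m, claims)
  verdict <- setNames(rep$passed, rep$metric)
  expect_equal(verdict[["adc_bias_pct"]], "pass")       # |−2.3| <= 3.6
  expect_equal(verdict[["wcv_short_term"]], "pass")     # <= passes at 0.5
  expect_equal(verdict[["rc_short_term"]], "fail")      # strict < fails at 15
  expect_equal(verdict[["max_bvalue_dependence_pct"]], "not_evaluable")
  expect_equal(verdict[["snr_b0"]], "pass")             # >= passes at 45
  expect_false(attr(rep, "overall_pass"))               # the RC failure

  # not-evaluable alone never fails the exam
  m2 <- tibble::tibble(metric = c("adc_bias_pct", "max_bvalue_dependence_pct"),
                       value = c(-0.4, NA_real_))
  expect_true(attr(check_claims(m2, claims), "overall_pass"))

  # wCV above the bound fails
  m3 <- tibble::tibble(metric = "wcv_short_term", value = 0.6)
  expect_equal(check_claims(m3, claims)$passed, "fail")
})

test_that("interval claims use the slope confidence interval, not the point estimate", {
  claims <- qiba_claims()
  inside <- tibble::tibble(metric = "slope", value = 0.98, lo = 0.96, hi = 1.01)
  straddle <- tibble::tibble(metric = "slope", value = 0.98, lo = 0.94, hi = 1.01)
  expect_equal(check_claims(inside, claims)$passed, "pass")
  expect_equal(check_claims(straddle, claims)$passed, "fail")
  # missing CI -> not evaluable
  noci <- tibble::tibble(metric = "slope", value = 0.98)
  expect_equal(check_claims(noci, claims)$passed, "not_evaluable")
})

test_that("malformed claim files are rejected and unmatched metrics flagged", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("version: x", "claims:",
               "  - metric: foo", "    cmp: frobnicate",
               "    threshold: 1"), bad)
  expect_error(qiba_claims(bad), "Malformed")

  rep <- check_claims(tibble::tibble(metric = "no_such_metric", value = 1),
                      qiba_claims())
  expect_equal(rep$passed, "not_evaluable")
  expect_true(is.na(rep$claim))
})

test_that("clinical protocol tiers match the published tier table", {
  spec <- protocol_spec("clinical_brain")
  p <- clinical_brain_protocol()
  rep <- check_protocol_compliance(p, spec)
  tier <- setNames(rep$tier, rep$parameter)
  expect_equal(tier[["tr_ms"]], "target")          # 3000 ms: target, not ideal
  expect_equal(tier[["gap_mm"]], "acceptable")     # 2 mm gap
  expect_equal(tier[["slice_thickness_mm"]], "target")
  expect_equal(tier[["matrix_frequency"]], "acceptable") # 128
  expect_equal(tier[["nex"]], "acceptable")        # single average
  expect_equal(tier[["highest_b_value"]], "ideal") # b = 1000
  expect_equal(attr(rep, "overall"), "compliant")
})

test_that("QIBA phantom protocol is compliant as shipped; deviations can be waived", {
  spec <- protocol_spec("qiba_phantom")
  rep <- check_protocol_compliance(qiba_phantom_protocol(), spec)
  expect_equal(attr(rep, "overall"), "compliant")

  # NEX forced to 1 on one platform: non-compliant unless waived
  p1 <- qiba_phantom_protocol(nex = 1)
  rep_fail <- check_protocol_compliance(p1, spec)
  expect_equal(attr(rep_fail, "overall"), "non_compliant")
  rep_waived <- check_protocol_compliance(p1, spec, waivers = "nex")
  expect_equal(rep_waived$tier[rep_waived$parameter == "nex"], "waived")
  expect_equal(attr(rep_waived, "overall"), "compliant")

  # wrong b-ladder is flagged
  pb <- qiba_phantom_protocol(b_values = c(0, 1000))
  repb <- check_protocol_compliance(pb, spec)
  expect_equal(repb$tier[repb$parameter == "b_values"], "non_conformant")
})

test_that("missing metadata yields unknown parameters and a not-evaluable overall", {
  p <- qiba_phantom_protocol()
  p$tr_ms <- NULL
  rep <- check_protocol_compliance(p, protocol_spec("qiba_phantom"))
  expect_equal(rep$tier[rep$parameter == "tr_ms"], "unknown")
  expect_equal(attr(rep, "overall"), "not_evaluable")
})

test_that("shipped tier specs are monotone and non-monotone specs are refused", {
  # loading validates nesting for both shipped profiles
  expect_s3_class(protocol_spec("qiba_phantom"), "protocol_spec")
  expect_s3_class(protocol_spec("clinical_brain"), "protocol_spec")

  bad <- tempfile(fileext = ".yaml")
  writeLines(c(
    "profile: broken", "parameters:",
    "  - parameter: tr_ms", "    extract: tr_ms",
    "    ideal: {cmp: min, value: 5000}",
    "    target: {cmp: range, lo: 3000, hi: 5000}",
    "    acceptable: {cmp: range, lo: 3000, hi: 5000}"), bad)
  expect_error(protocol_spec(path = bad), "non-monotone")
})
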