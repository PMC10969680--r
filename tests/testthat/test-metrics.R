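test_that("ADC bias is the (percent) difference to the reference diffusivity", {
  expect_equal(adc_bias(1100, 1100), tibble::tibble(bias = 0, percent_bias = 0))
  b <- adc_bias(1078, 1100)
  expect_equal(b$bias, -22)
  expect_equal(b$percent_bias, -2)
  expect_error(adc_bias(1000, 0), "positive")
})

test_that("repeatability pools within-group variances and applies the profile identities", {
  # two groups with sample variances 4 and 16 -> sigma_w = sqrt(10)
  df <- data.frame(
    g = rep(c("a", "b"), each = 3),
    v = c(100 - 2, 100, 100 + 2, 200 - 4, 200, 200 + 4))
  expect_equal(var(df$v[1:3]), 4)
  expect_equal(var(df$v[4:6]), 16)
  r <- repeatability(df, v, g)
  expect_equal(r$sigma_w, sqrt(10), tolerance = 1e-12)
  expect_equal(r$rc, 2.77 * r$sigma_w)        # identity RC = 2.77 sigma_w
  expect_equal(r$wcv, 100 * r$sigma_w / r$mean)

  # duplicated data has zero within-group spread
  dup <- data.frame(g = rep(1:4, each = 2), v = rep(c(9, 8, 7, 6), each = 2))
  expect_equal(repeatability(dup, v, g)$sigma_w, 0)

  # all-singleton grouping is not a repeatability design
  expect_error(repeatability(data.frame(g = 1:3, v = 4:6), v, g), ">= 2")

  # invariant under group relabeling
  df2 <- df
  df2$g <- rep(c("z9", "q1"), each = 3)
  expect_equal(repeatability(df2, v, g)[, -(1:2)], r[, -(1:2)])
})

test_that("summary-statistics route reproduces printed QA table arithmetic", {
  # white-matter row: mean 801.4, SD 16.2 -> RC 44.9, wCV 2.0 at 1 d.p.
  r <- repeatability_from_summary(801.4, 16.2)
  expect_equal(round_half_up(r$rc, 1), 44.9)
  expect_equal(round_half_up(r$wcv, 1), 2.0)
})

test_that("linearity fit matches a hand-checkable OLS oracle with t-based CI", {
  # exact identity: slope 1, intercept 0, R^2 = 1, degenerate CI
  d <- data.frame(dc = c(300, 600, 900, 1200, 1500))
  d$mu <- d$dc
  f <- linearity(d, dc, mu)
  expect_equal(f$slope, 1, tolerance = 1e-10)
  expect_equal(f$intercept, 0, tolerance = 1e-8)
  expect_equal(f$r_squared, 1)
  expect_equal(unname(f$slope_ci), c(1, 1), tolerance = 1e-8)

  # exact proportional miscalibration
  d$mu <- 0.98 * d$dc
  f2 <- linearity(d, dc, mu)
  expect_equal(f2$slope, 0.98, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1)

  # 3-point case vs the independent lm/confint oracle
  d3 <- data.frame(dc = 1:3, mu = c(1, 2.1, 2.9))
  f3 <- linearity(d3, dc, mu)
  oracle <- lm(mu ~ dc, data = d3)
  ci <- confint(oracle, "dc", level = 0.95)
  expect_equal(f3$slope, unname(coef(oracle)["dc"]), tolerance = 1e-12)
  expect_equal(unname(f3$slope_ci), unname(ci[1, ]), tolerance = 1e-10)
  expect_equal(f3$r_squared, summary(oracle)$r.squared, tolerance = 1e-12)

  expect_error(linearity(data.frame(dc = c(1, 2), mu = c(1, 2)), dc, mu),
               ">= 3")
  expect_error(linearity(data.frame(dc = rep(1, 4), mu = 1:4), dc, mu),
               "distinct")

  td <- tidy(f3)
  expect_equal(td$estimate[td$term == "dc_true"], f3$slope)
  expect_equal(glance(f3)$r.squared, f3$r_squared)
})

test_that("b-value dependence is the max relative deviation from the per-b mean", {
  eq <- data.frame(b = c(500, 1000, 2000), adc = rep(1100, 3))
  expect_equal(bvalue_dependence(eq, b, adc)$max_dependence_pct, 0)

  d <- data.frame(b = c(500, 1000, 1500, 2000),
                  adc = c(1000, 1000, 1020, 1000))
  r <- bvalue_dependence(d, b, adc)
  expect_equal(r$max_dependence_pct, 100 * 15 / 1005, tolerance = 1e-12)

  # a single nonzero b cannot evaluate the metric
  one <- data.frame(b = 1000, adc = 1050)
  r1 <- bvalue_dependence(one, b, adc)
  expect_false(r1$evaluable)
  expect_true(is.na(r1$max_dependence_pct))
})

test_that("random error is the within-VOI coefficient of variation", {
  expect_equal(random_error(mu = 1100, sigma = 0), 0)
  expect_equal(random_error(mu = 1100, sigma = 11), 1)
  expect_error(random_error(mu = -1, sigma = 1), "positive")
  voi <- tibble::tibble(mean = 1000, sd = 17)
  expect_equal(random_error(voi), 1.7)
})

test_that("difference-method noise image and SNR behave analytically and under MC", {
  a <- array(100, c(2, 4, 4))
  expect_true(all(make_noise_image(a, a) == 0))
  expect_equal(make_noise_image(a, a + 2)[1], 2 / sqrt(2))
  expect_error(make_noise_image(a, array(0, c(2, 4, 5))), "shape")

  # Monte-Carlo oracle: mean |n1 - n2| / sqrt(2) for Gaussian sigma = 5
  set.seed(99)
  n <- 1e5
  r1 <- array(450 + rnorm(n, 0, 5), c(1, n, 1))
  r2 <- array(450 + rnorm(n, 0, 5), c(1, n, 1))
  ni <- make_noise_image(r1, r2)
  expect_equal(mean(ni), 5 * sqrt(2 / pi), tolerance = 0.02)

  mask <- array(TRUE, dim(ni))
  s <- snr(r1, ni, mask)
  expect_true(s$evaluable)
  expect_equal(s$snr, 450 / (5 * sqrt(2 / pi)), tolerance = 0.02)

  # claim-boundary arithmetic: signal mean 450 over noise mean 10 -> 45
  sig <- array(450, c(1, 10, 1)); noi <- array(10, c(1, 10, 1))
  expect_equal(snr(sig, noi, array(TRUE, c(1, 10, 1)))$snr, 45)

  # zero noise -> not evaluable
  z <- snr(sig, array(0, c(1, 10, 1)), array(TRUE, c(1, 10, 1)))
  expect_false(z$evaluable)
})
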