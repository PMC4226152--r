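test_that("intercept-only fits reduce to closed-form maximum likelihood", {
  counts <- c(3L, 7L, 5L, 12L, 9L)
  f <- fit_frequency_glm(counts, family = "poisson")
  expect_equal(unname(f$coefficients), log(mean(counts)))

  # one observation per subject: LN intercept is the mean log magnitude
  d <- rss_data(data.frame(subject = 1:200,
                           magnitude = sample_magnitudes(baseline_mag_ln(),
                                                         200, seed = 55)))
  st <- subject_table(d)
  m <- fit_magnitude_model(d, ~1, family = "lognormal")
  expect_equal(unname(m$coefficients), mean(log(st$mbar)))

  s <- fit_sums_glm(st$S, family = "LN")
  expect_equal(unname(s$coefficients), mean(log(st$S)))
})

test_that("frequency GLM recovers generating effects and flags over-dispersion", {
  set.seed(61)
  J <- 5000
  x <- rep(0:1, each = J / 2)
  mu <- exp(log(10) + 0.3 * x)
  counts <- stats::rnbinom(J, size = 10, mu = mu)
  fit <- fit_frequency_glm(counts, cbind(x = x), family = "negbin")
  expect_lt(abs(fit$coefficients[["x"]] - 0.3), 3 * fit$standard_errors[["x"]])
  expect_equal(fit$dispersion$theta, 10, tolerance = 0.2)

  # Poisson fit to negbin(0.5, 10) data: Pearson chi-square/df near 1/(1-pi) = 2
  pfit <- fit_frequency_glm(stats::rnbinom(5000, size = 10, mu = 10),
                            family = "poisson")
  expect_equal(pfit$pearson_dispersion, 2, tolerance = 0.15)

  expect_error(fit_frequency_glm(c(1.5, 2)), "integers")
})

test_that("magnitude model recovers effects and orders likelihoods correctly", {
  cfg <- fixture_config(J = 2000, mag = mag_lognormal(6.81, 0.447),
                        beta = c(x = 0.25), seed = 77)
  d <- generate_fixture(cfg)
  fit <- fit_magnitude_model(d, ~x, family = "lognormal")
  expect_lt(abs(fit$coefficients[["x"]] - 0.25), 3 * fit$standard_errors[["x"]])

  # log-normal data: the LN likelihood dominates the exponential's
  d2 <- generate_fixture(fixture_config(J = 1500, mag = baseline_mag_ln(),
                                        seed = 78))
  ln <- fit_magnitude_model(d2, ~1, family = "lognormal")
  ex <- fit_magnitude_model(d2, ~1, family = "exponential")
  expect_gt(ln$log_likelihood, ex$log_likelihood)

  expect_error(
    fit_magnitude_model(toy_two_subject(), ~1, family = "banana"))
})

test_that("fitted sums coefficients match the additivity prediction at large J", {
  cfg <- fixture_config(J = 4000, alpha = c(x = 0.2), beta = c(x = 0.3),
                        mag = baseline_mag_ln(), seed = 88)
  d <- generate_fixture(cfg)
  st <- subject_table(d)
  sfit <- fit_sums_glm(st$S, st["x"], family = "LN")
  expect_lt(abs(sfit$coefficients[["x"]] - 0.5), 3 * sfit$standard_errors[["x"]])

  ffit <- fit_frequency_glm(st$n, st["x"], family = "negbin")
  mfit <- fit_magnitude_model(d, ~x, family = "lognormal")
  pred <- predict_sums_coefficients(ffit, mfit)
  se_comb <- sqrt(ffit$standard_errors[["x"]]^2 + mfit$standard_errors[["x"]]^2 +
                    sfit$standard_errors[["x"]]^2)
  expect_lt(abs(pred[["x"]] - sfit$coefficients[["x"]]), 3 * se_comb)

  # GG and LN estimates agree within their joint intervals
  gfit <- fit_sums_glm(st$S, st["x"], family = "GG")
  expect_lt(abs(gfit$coefficients[["x"]] - sfit$coefficients[["x"]]),
            2 * sqrt(gfit$standard_errors[["x"]]^2 + sfit$standard_errors[["x"]]^2))
})

test_that("the additivity predictor sums shared coefficients and passes through others", {
  expect_equal(predict_sums_coefficients(c(x = 0.135), c(x = 0.111)),
               c(x = 0.246))
  expect_equal(predict_sums_coefficients(c(x = -0.069), c(x = 0.306)),
               c(x = 0.237))
  expect_equal(predict_sums_coefficients(c(x = 0), c(x = 0)), c(x = 0))
  out <- predict_sums_coefficients(c(a = 0.1), c(b = 0.2))
  expect_equal(out, c(a = 0.1, b = 0.2))
  fake <- structure(list(coefficients = c(x = 1), link = "identity"),
                    class = "rss_fit")
  expect_error(predict_sums_coefficients(fake, c(x = 0.1)), "log links")
})

test_that("likelihood never decreases when the true predictor is added", {
  cfg <- fixture_config(J = 500, beta = c(x = 0.3), mag = baseline_mag_ln(),
                        seed = 91)
  d <- generate_fixture(cfg)
  m0 <- fit_magnitude_model(d, ~1, family = "lognormal")
  m1 <- fit_magnitude_model(d, ~x, family = "lognormal")
  expect_gte(m1$log_likelihood, m0$log_likelihood)
  st <- subject_table(d)
  s0 <- fit_sums_glm(st$S, family = "LN")
  s1 <- fit_sums_glm(st$S, st["x"], family = "LN")
  expect_gte(s1$log_likelihood, s0$log_likelihood)
})

test_that("mixed-engine magnitude fit agrees with the subject-level fit", {
  skip_if_not_installed("lme4")
  cfg <- fixture_config(J = 300, beta = c(x = 0.25), mag = baseline_mag_ln(),
                        sigma_upsilon = 0.2, seed = 95)
  d <- generate_fixture(cfg)
  a <- fit_magnitude_model(d, ~x, family = "lognormal")
  b <- fit_magnitude_model(d, ~x, family = "lognormal", engine = "mixed")
  expect_lt(abs(a$coefficients[["x"]] - b$coefficients[["x"]]),
            2 * sqrt(a$standard_errors[["x"]]^2 + b$standard_errors[["x"]]^2))
})
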