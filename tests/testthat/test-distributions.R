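test_that("negative binomial (probability, scale) parameterization gives the stated moments", {
  spec <- negbin_from_prob_scale(0.5, 10)
  expect_equal(spec$params$theta, 10)
  expect_equal(spec$params$omega_sq, 20)

  # theta = phi pi / (1 - pi), omega^2 = phi pi / (1 - pi)^2
  spec2 <- negbin_from_prob_scale(0.25, 6)
  expect_equal(spec2$params$theta, 2)
  expect_equal(spec2$params$omega_sq, 8 / 3)
  draws <- sample_frequencies(spec2, 1e6, seed = 42)
  expect_moments_match(draws, natural_moments(spec2))

  # degenerate limit pi -> 0
  tiny <- negbin_from_prob_scale(1e-9, 10)
  expect_lt(tiny$params$theta, 1e-7)
  expect_lt(tiny$params$omega_sq, 1e-7)

  expect_error(negbin_from_prob_scale(0, 10), "pi")
  expect_error(negbin_from_prob_scale(1.2, 10), "pi")
  expect_error(negbin_from_prob_scale(0.5, -1), "phi")
})

test_that("over-dispersion ratio of the negative binomial is 1/(1-pi)", {
  for (pi in c(0.1, 0.5, 0.9)) {
    s <- negbin_from_prob_scale(pi, 7)
    expect_equal(s$params$omega_sq / s$params$theta, 1 / (1 - pi))
    expect_gt(s$params$omega_sq, s$params$theta)
  }
})

test_that("frequency pmfs are proper distributions and sampling matches moments", {
  specs <- list(freq_poisson(10), negbin_from_prob_scale(0.5, 10),
                freq_poisson_gamma(10, 10))
  for (s in specs) {
    p <- freq_pmf(s, 0:400)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    draws <- sample_frequencies(s, 1e6, seed = 7)
    expect_moments_match(draws, natural_moments(s))
  }
  # poisson variance equals mean
  mo <- natural_moments(freq_poisson(10))
  expect_equal(unname(mo["sd"]^2), unname(mo["mean"]))
  # all-zero degenerate draw
  expect_true(all(sample_frequencies(freq_poisson(0), 100, seed = 1) == 0))
  # vanishing mixing variance collapses the gamma-mixed Poisson onto Poisson
  d <- sample_frequencies(freq_poisson_gamma(1e8, 10), 2e5, seed = 9)
  expect_equal(stats::var(d) / mean(d), 1, tolerance = 0.02)
  # sampling is reproducible under a fixed seed
  expect_identical(sample_frequencies(baseline_freq(), 50, seed = 3),
                   sample_frequencies(baseline_freq(), 50, seed = 3))
})

test_that("magnitude families sample positive values matching closed-form moments", {
  expect_length(sample_magnitudes(baseline_mag_gg(), 0), 0)
  specs <- list(baseline_mag_gg(), baseline_mag_ln(),
                mag_exponential(1000), mag_invgauss(1000, 4000))
  for (s in specs) {
    draws <- sample_magnitudes(s, 1e6, seed = 11)
    expect_true(all(draws > 0))
    expect_moments_match(draws, natural_moments(s))
  }
  # printed closed forms
  expect_equal(natural_moments(baseline_mag_gg()), c(mean = 1000, sd = 500))
  expect_equal(unname(natural_moments(baseline_mag_ln())["mean"]),
               exp(6.81 + 0.447^2 / 2))
  mo <- natural_moments(mag_exponential(123))
  expect_equal(unname(mo["mean"]), unname(mo["sd"]))
})

test_that("conditional sum laws follow the closure rules", {
  g1 <- conditional_sum_law(baseline_mag_gg(), 1)
  expect_equal(g1$params, list(shape = 4, scale = 250))
  g5 <- conditional_sum_law(baseline_mag_gg(), 5)
  expect_equal(g5$params, list(shape = 20, scale = 250))
  ig <- conditional_sum_law(mag_invgauss(2, 5), 3)
  expect_equal(ig$params, list(theta = 6, kappa = 45))
  e <- conditional_sum_law(mag_exponential(100), 4)
  expect_equal(e$params, list(shape = 4, scale = 100))
  expect_equal(conditional_sum_law(baseline_mag_ln(), 3)$family, "none")
  expect_error(conditional_sum_law(baseline_mag_gg(), 0), "n")
})

test_that("closure laws agree with brute-force n-fold convolutions", {
  for (n in c(2, 5, 10)) {
    s <- simulate_nfold_sums(baseline_mag_gg(), n, 2e4, seed = 100 + n)
    law <- conditional_sum_law(baseline_mag_gg(), n)
    ks <- suppressWarnings(stats::ks.test(s, law$cdf))
    expect_gt(ks$p.value, 0.01)
  }
  for (n in c(2, 5)) {
    ig <- mag_invgauss(1000, 4000)
    s <- simulate_nfold_sums(ig, n, 2e4, seed = 200 + n)
    law <- conditional_sum_law(ig, n)
    ks <- suppressWarnings(stats::ks.test(s, law$cdf))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("effects in SD units shift the natural mean with the secondary parameter held", {
  nb <- baseline_freq()
  expect_identical(apply_effect(nb, 0), nb)
  shifted <- apply_effect(nb, 0.8)
  expect_equal(unname(natural_moments(shifted)["mean"]), 10 + 0.8 * sqrt(20))
  expect_equal(shifted$params$phi, 10)

  g <- apply_effect(baseline_mag_gg(), -0.5)
  expect_equal(g$params$shape, 4)
  expect_equal(g$params$scale, 187.5)
  expect_equal(unname(natural_moments(g)["mean"]), 750)

  ln <- apply_effect(baseline_mag_ln(), 0.5)
  expect_equal(ln$params$sdlog, 0.447)
  m0 <- natural_moments(baseline_mag_ln())
  expect_equal(unname(natural_moments(ln)["mean"]),
               unname(m0["mean"] + 0.5 * m0["sd"]))

  expect_error(apply_effect(baseline_mag_gg(), -2.5), "non-positive")
})

test_that("specifications round-trip through config files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  for (s in list(baseline_freq(), freq_poisson_gamma(10, 10),
                 baseline_mag_ln(), mag_invgauss(3, 7))) {
    write_spec_config(s, path)
    expect_equal(read_spec_config(path), s, tolerance = 1e-12)
  }
})
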