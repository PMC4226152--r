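# shared fixtures: the study's baseline specifications and small helpers

baseline_freq <- function() negbin_from_prob_scale(0.5, 10)
baseline_mag_ln <- function() mag_lognormal(6.81, 0.447)
baseline_mag_gg <- function() mag_gamma(4, 250)

# Monte Carlo standard error of a sample SD (via the fourth central moment)
se_of_sd <- function(x) {
  n <- length(x)
  m4 <- mean((x - mean(x))^4)
  s2 <- stats::var(x)
  sqrt(max(m4 - s2^2 * (n - 3) / (n - 1), 0) / n) / (2 * sqrt(s2))
}

expect_moments_match <- function(draws, mo, k = 4) {
  se_mean <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mo["mean"]), k * se_mean)
  expect_lt(abs(stats::sd(draws) - mo["sd"]), k * se_of_sd(draws))
}

# n-fold convolution of a magnitude spec by brute-force simulation
simulate_nfold_sums <- function(spec, n, reps, seed) {
  z <- sample_magnitudes(spec, n * reps, seed = seed)
  colSums(matrix(z, nrow = n))
}

toy_two_subject <- function() {
  rss_data(data.frame(subject = c("A", "A", "B"),
                      magnitude = c(100, 200, 50)))
}
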