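# ---- Type I error and power study engine ------------------------------------

#' Define a two-condition power/Type-I-error scenario
#'
#' One cell of the simulation study grid: a control condition at the baseline
#' frequency and magnitude distributions, and a treatment condition with the
#' effects applied through [apply_effect()] (natural-scale mean shifted by
#' the effect size times the baseline SD, secondary parameter held). The
#' baselines are the study's calibration: negative binomial counts with
#' event probability 0.5 and scale 10 (mean 10, variance 20), and magnitudes
#' with natural mean ~1000 and SD ~500 — log-normal(6.81, 0.447) or
#' gamma(shape 4, scale 250), typical of human response times in
#' milliseconds.
#'
#' @param n_per_condition Subjects per condition (the study used 25, 50,
#'   100, 200).
#' @param effect_magnitude,effect_frequency Effect sizes in baseline SD
#'   units (the study used 0, +-0.2, +-0.5, +-0.8).
#' @param reps Monte Carlo replicates (the study used 10,000; 2,000 is a
#'   practical reduced gate).
#' @param magnitude_family Generating magnitude family, `"lognormal"` or
#'   `"gamma"`.
#' @param fitted_model Family used for the magnitude and sums fits, `"LN"`
#'   or `"GG"`.
#' @param alpha_level Two-sided significance level.
#' @param seed Optional integer seed.
#' @param freq_baseline,mag_baseline Override the baseline specs.
#' @return A `power_scenario` configuration.
#' @export
power_scenario <- function(n_per_condition, effect_magnitude = 0,
                           effect_frequency = 0, reps = 10000,
                           magnitude_family = c("lognormal", "gamma"),
                           fitted_model = c("LN", "GG"),
                           alpha_level = 0.05, seed = NULL,
                           freq_baseline = negbin_from_prob_scale(0.5, 10),
                           mag_baseline = NULL) {
  magnitude_family <- match.arg(magnitude_family)
  fitted_model <- match.arg(fitted_model)
  stopifnot(n_per_condition >= 2, reps >= 1, alpha_level > 0, alpha_level < 1)
  if (is.null(mag_baseline))
    mag_baseline <- if (magnitude_family == "lognormal")
      mag_lognormal(6.81, 0.447) else mag_gamma(4, 250)
  structure(list(
    n_per_condition = n_per_condition,
    effect_magnitude = effect_magnitude, effect_frequency = effect_frequency,
    reps = reps, magnitude_family = magnitude_family,
    fitted_model = fitted_model, alpha_level = alpha_level, seed = seed,
    freq_baseline = freq_baseline, mag_baseline = mag_baseline),
    class = "power_scenario")
}

#' Run one power/Type-I-error scenario
#'
#' Per replicate: draw counts and magnitudes for both conditions, then fit
#' the three models and record two-sided Wald significance of the condition
#' coefficient in each — the frequency model (negative binomial GLM), the
#' magnitude model (log-link fit of the per-subject mean magnitudes in the
#' chosen family), and the sums model (LN: linear model on log sums; GG:
#' gamma GLM) with zero-count subjects dropped from the magnitude and sums
#' fits. Fits use closed-form two-group equivalents of the GLMs (verified
#' against [MASS::glm.nb()] and [stats::glm()] in the test suite).
#'
#' @param config A `power_scenario`.
#' @return A `power_result`: `rejection_rate`, `mc_se` (binomial SE),
#'   `reps_effective`, `mean_estimate` (average fitted condition
#'   coefficient) per submodel, and the configuration.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "power_scenario"))
  N <- config$n_per_condition
  f0 <- config$freq_baseline
  f1 <- apply_effect(f0, config$effect_frequency)
  m0 <- config$mag_baseline
  m1 <- apply_effect(m0, config$effect_magnitude)
  gg <- config$fitted_model == "GG"

  draw_mag <- function(spec, tot) {
    p <- spec$params
    if (spec$family == "lognormal") stats::rlnorm(tot, p$meanlog, p$sdlog)
    else if (spec$family == "gamma") stats::rgamma(tot, p$shape, scale = p$scale)
    else sample_magnitudes(spec, tot)
  }

  with_seed(config$seed, {
    rej <- matrix(NA, config$reps, 3,
                  dimnames = list(NULL, c("magnitude", "frequency", "sums")))
    est <- rej
    for (r in seq_len(config$reps)) {
      n0 <- sample_frequencies(f0, N)
      n1 <- sample_frequencies(f1, N)
      z0 <- draw_mag(m0, sum(n0))
      z1 <- draw_mag(m1, sum(n1))
      S0 <- if (any(n0 > 0))
        rowsum(z0, rep.int(which(n0 > 0), n0[n0 > 0]))[, 1] else numeric(0)
      S1 <- if (any(n1 > 0))
        rowsum(z1, rep.int(which(n1 > 0), n1[n1 > 0]))[, 1] else numeric(0)
      mb0 <- S0 / n0[n0 > 0]
      mb1 <- S1 / n1[n1 > 0]
      fm <- if (gg) fast_gamma_2group(mb0, mb1) else
        fast_lognormal_2group(log(mb0), log(mb1))
      ff <- fast_negbin_2group(n0, n1)
      fs <- if (gg) fast_gamma_2group(S0, S1) else
        fast_lognormal_2group(log(S0), log(S1))
      est[r, ] <- c(fm[1], ff[1], fs[1])
      rej[r, ] <- c(fm[3], ff[3], fs[3]) < config$alpha_level
    }
    eff <- colSums(!is.na(rej))
    rate <- colSums(rej, na.rm = TRUE) / eff
    structure(list(
      rejection_rate = rate,
      mc_se = sqrt(rate * (1 - rate) / eff),
      reps_effective = eff,
      mean_estimate = colMeans(est, na.rm = TRUE),
      config = config),
      class = "power_result")
  })
}

#' @export
print.power_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<power_result: N=%d/condition, d_mag=%g, d_freq=%g, %s magnitudes, %s fits, %d reps>\n",
    cfg$n_per_condition, cfg$effect_magnitude, cfg$effect_frequency,
    cfg$magnitude_family, cfg$fitted_model, cfg$reps))
  tab <- data.frame(rejection = x$rejection_rate, mc_se = x$mc_se,
                    reps = x$reps_effective, mean_coef = x$mean_estimate)
  print(tab, digits = 4)
  invisible(x)
}

#' Run a grid of scenarios and tabulate rejection rates
#'
#' Executes each configured scenario and assembles the rejection rates in
#' the study's table layout: one row per (generating family, fitted family,
#' sample size, effect pair), with the magnitude, frequency, and sums
#' rejection rates and their Monte Carlo SEs as columns. An empty effect
#' grid (all zero effects) yields a pure Type-I-error table.
#'
#' @param grid A list of `power_scenario` objects.
#' @return Data frame of class `power_table`.
#' @export
make_tables <- function(grid) {
  stopifnot(length(grid) >= 1, all(vapply(grid, inherits, TRUE, "power_scenario")))
  rows <- lapply(grid, function(cfg) {
    res <- run_scenario(cfg)
    data.frame(
      magnitude_family = cfg$magnitude_family, fitted_model = cfg$fitted_model,
      N = cfg$n_per_condition, d_mag = cfg$effect_magnitude,
      d_freq = cfg$effect_frequency, reps = cfg$reps,
      magnitude = res$rejection_rate[["magnitude"]],
      frequency = res$rejection_rate[["frequency"]],
      sums = res$rejection_rate[["sums"]],
      magnitude_se = res$mc_se[["magnitude"]],
      frequency_se = res$mc_se[["frequency"]],
      sums_se = res$mc_se[["sums"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_table", "data.frame")
  out
}

#' Standard scenario grids of the simulation study
#'
#' Helpers producing the scenario lists behind the study's tables: the null
#' (Type I error) grid over sample sizes and both generating/fitted family
#' combinations; single-effect grids (magnitude-only, frequency-only);
#' opposing equal effects; and same-direction effect pairs.
#'
#' @param reps Replicates per cell.
#' @param seed Base seed; each cell derives its own sub-seed.
#' @param sample_sizes Per-condition sample sizes.
#' @param effects Effect magnitudes for the single-effect grids.
#' @return A list of `power_scenario` objects.
#' @name scenario_grids
NULL

cell_seed <- function(seed, i) if (is.null(seed)) NULL else (seed + 7919L * i) %% 2147483629L

#' @rdname scenario_grids
#' @export
type1_grid <- function(reps = 10000, seed = NULL,
                       sample_sizes = c(25, 50, 100, 200)) {
  cells <- expand.grid(N = sample_sizes,
                       fam = c("lognormal", "gamma"),
                       fit = c("LN", "GG"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    power_scenario(cells$N[i], 0, 0, reps = reps,
                   magnitude_family = cells$fam[i], fitted_model = cells$fit[i],
                   seed = cell_seed(seed, i)))
}

#' @rdname scenario_grids
#' @param which `"magnitude"` or `"frequency"` for the single-effect grids.
#' @export
single_effect_grid <- function(which = c("magnitude", "frequency"),
                               reps = 10000, seed = NULL,
                               sample_sizes = c(25, 50, 100, 200),
                               effects = c(0.2, 0.5, 0.8, -0.2, -0.5, -0.8)) {
  which <- match.arg(which)
  cells <- expand.grid(N = sample_sizes, d = effects, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    power_scenario(cells$N[i],
                   effect_magnitude = if (which == "magnitude") cells$d[i] else 0,
                   effect_frequency = if (which == "frequency") cells$d[i] else 0,
                   reps = reps, seed = cell_seed(seed, i)))
}

#' @rdname scenario_grids
#' @export
opposing_effects_grid <- function(reps = 10000, seed = NULL,
                                  sample_sizes = c(25, 50, 100, 200),
                                  effects = c(0.2, 0.5, 0.8)) {
  cells <- expand.grid(N = sample_sizes, d = effects,
                       mag_sign = c(1, -1), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    power_scenario(cells$N[i],
                   effect_magnitude = cells$mag_sign[i] * cells$d[i],
                   effect_frequency = -cells$mag_sign[i] * cells$d[i],
                   reps = reps, seed = cell_seed(seed, i)))
}

#' @rdname scenario_grids
#' @export
same_direction_grid <- function(reps = 10000, seed = NULL,
                                sample_sizes = c(25, 50),
                                effects = c(0.2, 0.5)) {
  cells <- expand.grid(N = sample_sizes, d_mag = effects, d_freq = effects,
                       sign = c(1, -1), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(cells)), function(i)
    power_scenario(cells$N[i],
                   effect_magnitude = cells$sign[i] * cells$d_mag[i],
                   effect_frequency = cells$sign[i] * cells$d_freq[i],
                   reps = reps, seed = cell_seed(seed, i)))
}
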