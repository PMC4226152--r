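# Short chains keep these runs fast; convergence warnings from the reduced
# settings are expected and suppressed where the check targets something else.

fit_quiet <- function(model, ...) suppressWarnings(run_mcmc(model, ...))

test_that("model building enumerates the expected parameter sets", {
  d <- generate_fixture(fixture_config(J = 25, seed = 70, alpha = c(x = 0.2),
                                       beta = c(x = 0.1)))
  m <- build_model(d, ~x, ~x, family = "GG")
  mon <- stoppedsums:::jags_monitors(m)
  expect_setequal(mon, c("alpha", "b0", "beta", "q", "qm",
                         "lambda", "mu", "muS", "sigma_ups"))
  expect_equal(colnames(m$X), c("(Intercept)", "x"))
  expect_equal(colnames(m$Y), "x")

  # three-level structure: one frequency coefficient vector incl. round
  # covariates, per-round magnitude intercepts
  d3 <- generate_fixture(fixture_config(
    J = 20, levels = 3, rounds = 4, seed = 71,
    alpha = c(d1 = 0.1, d2 = 0, x1 = 0, x2 = 0, f = 0.1, t = -0.1),
    beta = c(d1 = 0.1, d2 = 0, x1 = 0, x2 = 0.1, f = 0, t = 0),
    predictors = data.frame(d1 = rep(c(1, 0), 10), d2 = rep(c(0, 1), 10),
                            x1 = stats::rnorm(20), x2 = stats::rnorm(20)),
    round_predictors = data.frame(f = c(1, 1, 0, 0), t = c(1, 0, 1, 0)),
    mag = mag_lognormal(6.81, 0.447)))
  m3 <- build_model(d3, ~ d1 + d2 + x1 + x2 + f + t, ~ d1 + d2 + x1 + x2 + f + t,
                    family = "LN")
  expect_equal(ncol(m3$X), 7)  # alpha_0 ... alpha_6
  expect_equal(m3$K, 4)        # beta_01 ... beta_04
  expect_equal(ncol(m3$Y), 6)  # beta_1 ... beta_6
  expect_equal(m3$levels, 3L)
})

test_that("the joint log-density rejects points outside the support", {
  d <- generate_fixture(fixture_config(J = 15, seed = 72))
  m <- build_model(d, ~1, ~1, family = "GG")
  st <- m$st
  pars <- list(lambda = st$n, mu = log(st$mbar), alpha = log(mean(st$n)),
               b0 = mean(log(st$mbar)), q = 10, qm = 4, sigma_ups = 0.1)
  ld <- model_log_density(m, pars)
  expect_true(is.finite(ld))
  bad <- pars; bad$lambda[3] <- -0.5
  expect_identical(model_log_density(m, bad), -Inf)
  bad2 <- pars; bad2$q <- 0
  expect_identical(model_log_density(m, bad2), -Inf)
})

test_that("GG draws satisfy the sums-mean identity exactly", {
  d <- generate_fixture(fixture_config(J = 30, seed = 73, alpha = c(x = 0.2),
                                       beta = c(x = 0.1), sigma_upsilon = 0.1))
  m <- build_model(d, ~x, ~x, family = "GG")
  r <- fit_quiet(m, chains = 2, burn_in = 200, draws = 200, seed = 1, adapt = 150)
  M <- as.matrix(r$draws)
  U <- nrow(m$st)
  gap <- M[, paste0("muS[", 1:U, "]")] - M[, paste0("mu[", 1:U, "]")] -
    log(M[, paste0("lambda[", 1:U, "]")])
  expect_lt(max(abs(gap)), 1e-12)
})

test_that("null synthetic data give a sums coefficient consistent with zero", {
  d <- generate_fixture(fixture_config(J = 120, seed = 74, alpha = c(x = 0),
                                       beta = c(x = 0), sigma_upsilon = 0.05,
                                       mag = mag_lognormal(6.81, 0.447)))
  m <- build_model(d, ~x, ~x, family = "LN")
  r <- fit_quiet(m, chains = 2, burn_in = 400, draws = 500, seed = 2, adapt = 200)
  om <- r$summary["omega_c", ]
  expect_lt(abs(om$mean), 2 * om$se)
})

test_that("DIC is deterministic, additive, and zero-complexity at a point mass", {
  d <- generate_fixture(fixture_config(J = 25, seed = 75, alpha = c(x = 0.2),
                                       beta = c(x = 0.1)))
  m <- build_model(d, ~x, ~x, family = "GG")
  r <- fit_quiet(m, chains = 2, burn_in = 200, draws = 200, seed = 3, adapt = 150)
  d1 <- compute_dic(r, "sums")
  d2 <- compute_dic(r, "sums")
  expect_identical(d1, d2)
  expect_equal(d1[["DIC"]], d1[["Dbar"]] + d1[["pD"]])

  # a degenerate posterior (every draw identical) has pD = 0, DIC = Dbar
  M <- as.matrix(r$draws)
  flat <- M[rep(1, 50), ]
  deg <- r
  deg$draws <- coda::mcmc.list(coda::mcmc(flat), coda::mcmc(flat))
  dd <- compute_dic(deg, "magnitude")
  expect_equal(dd[["pD"]], 0, tolerance = 1e-8)
  expect_equal(dd[["DIC"]], dd[["Dbar"]], tolerance = 1e-8)
})

test_that("DIC prefers the effect model in the layer carrying the effect", {
  wins <- vapply(1:5, function(i) {
    d <- generate_fixture(fixture_config(J = 60, seed = 500 + i,
                                         beta = c(x = 0.35),
                                         mag = mag_lognormal(6.81, 0.447),
                                         sigma_upsilon = 0.02))
    m_null <- build_model(d, ~1, ~1, family = "LN")
    m_eff <- build_model(d, ~1, ~x, family = "LN")
    r_null <- fit_quiet(m_null, chains = 2, burn_in = 250, draws = 250,
                        seed = i, adapt = 150)
    r_eff <- fit_quiet(m_eff, chains = 2, burn_in = 250, draws = 250,
                       seed = i, adapt = 150)
    compute_dic(r_eff, "magnitude")[["DIC"]] <
      compute_dic(r_null, "magnitude")[["DIC"]]
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})

test_that("posterior predictions track the data and ignore row order", {
  d <- generate_fixture(fixture_config(J = 50, seed = 76, alpha = c(x = 0.2),
                                       beta = c(x = 0.15), sigma_upsilon = 0.1))
  m <- build_model(d, ~x, ~x, family = "GG")
  r <- fit_quiet(m, chains = 2, burn_in = 300, draws = 400, seed = 4, adapt = 200)
  pp <- posterior_predict(r, d)
  expect_gt(stats::cor(pp$S, pp$pred_S)^2, 0.99)
  expect_gt(stats::cor(pp$n, pp$pred_n)^2, 0.9)

  # shuffling observation rows leaves the unit-level fit identical
  df <- as.data.frame(d)
  dshuf <- rss_data(df[sample.int(nrow(df)), ], predictors = "x")
  mshuf <- build_model(dshuf, ~x, ~x, family = "GG")
  rshuf <- fit_quiet(mshuf, chains = 2, burn_in = 300, draws = 400, seed = 4,
                     adapt = 200)
  # same posterior up to Monte Carlo noise once units are matched by subject
  # (subject_table presents units in order of appearance)
  ps <- posterior_predict(rshuf)
  ps <- ps[match(pp$subject, ps$subject), ]
  expect_gt(stats::cor(ps$pred_S, pp$pred_S), 0.999)
  expect_equal(ps$pred_S, pp$pred_S, tolerance = 0.03, ignore_attr = TRUE)

  expect_error(posterior_predict(r, toy_two_subject()), "does not match")
})

test_that("a three-level GG fit reproduces cell-level sums almost exactly", {
  d3 <- generate_fixture(fixture_config(J = 30, levels = 3, rounds = 3,
                                        seed = 77, alpha = c(x = 0.1),
                                        beta = c(x = 0.1),
                                        beta0k = c(6.7, 6.8, 6.9),
                                        sigma_upsilon = 0.1))
  m3 <- build_model(d3, ~x, ~x, family = "GG")
  r3 <- fit_quiet(m3, chains = 2, burn_in = 300, draws = 300, seed = 5,
                  adapt = 200)
  pp <- posterior_predict(r3)
  expect_gt(stats::cor(pp$S, pp$pred_S)^2, 0.99)
  # derived per-round sums intercepts exist
  expect_true(all(paste0("omega0[", 1:3, "]") %in% rownames(r3$summary)))
})

test_that("observation-level predictors extend the model consistently", {
  d <- generate_fixture(fixture_config(J = 60, seed = 78, alpha = c(x = 0.1),
                                       beta = c(x = 0.1), sigma_upsilon = 0.05,
                                       mag = mag_lognormal(6.81, 0.447)))
  df <- as.data.frame(d)
  set.seed(79)
  df$w <- stats::rnorm(nrow(df))
  dw <- rss_data(df, predictors = "x")
  m0 <- build_model(dw, ~x, ~x, family = "LN")
  mw <- extend_with_observation_predictors(m0, "w")
  expect_error(extend_with_observation_predictors(m0, matrix(1, 3, 1)),
               "one row per observation")

  # with all-zero observation predictors the extended density differs from
  # the unextended one only by the random-coefficient layer's own factor:
  # the data likelihood is unchanged
  mzero <- extend_with_observation_predictors(
    m0, matrix(0, nrow(df), 1, dimnames = list(NULL, "w0col")))
  st <- m0$st
  base <- list(lambda = st$n, mu = log(st$mbar), alpha = c(2.3, 0.1),
               b0 = 6.8, beta = 0.1, q = 10, sigma_ups = 0.1,
               sigma_z = 0.45, sigma_s = 0.5, w0 = 9.1, omega_c = 0.2)
  ext <- c(base, list(delta = matrix(0.7, nrow(st), 1), eta_w = 0.4,
                      sigma_w = 0.3))
  delta_layer <- sum(stats::dnorm(0.7, 0.4, 0.3, log = TRUE)) * nrow(st)
  expect_equal(model_log_density(mzero, ext, include_priors = FALSE),
               model_log_density(m0, base, include_priors = FALSE) + delta_layer)

  # the per-subject sums term equals the summed observation effects
  W <- mw$W
  delta <- matrix(stats::rnorm(nrow(st)), ncol = 1)
  tau <- W[, 1] * delta[mw$cell, 1]
  expect_equal(drop(rowsum(tau, mw$cell)), drop(mw$wbar * delta),
               ignore_attr = TRUE)
})

test_that("an observation-level effect is detected, shrunk toward the joint compromise", {
  # the magnitude layer identifies eta_p (truth 0.2 here) while the sums
  # layer's per-subject predictor-sum term implies a much smaller slope for
  # the same data, so the joint posterior settles between the two; the
  # detection must be unambiguous and on the magnitude layer's side
  cfg <- fixture_config(J = 150, seed = 80, alpha = c(x = 0),
                        beta = c(x = 0), sigma_upsilon = 0.05,
                        mag = mag_lognormal(6.81, 0.447))
  d <- generate_fixture(cfg)
  df <- as.data.frame(d)
  set.seed(81)
  df$w <- stats::rnorm(nrow(df))
  df$magnitude <- df$magnitude * exp(0.2 * df$w)  # eta_p = 0.2
  dw <- rss_data(df, predictors = "x")
  mw <- extend_with_observation_predictors(build_model(dw, ~x, ~x, family = "LN"),
                                           "w")
  r <- fit_quiet(mw, chains = 2, burn_in = 300, draws = 300, seed = 6,
                 adapt = 200)
  ew <- r$summary["eta_w", ]
  expect_gt(ew$lower, 0.05)
  expect_gt(ew$mean, 0.08)
  expect_lt(ew$mean, 0.2)
})

test_that("Bayesian and simulation-bootstrap estimates agree on shared data", {
  d <- generate_fixture(fixture_config(J = 100, seed = 82, alpha = c(x = 0.2),
                                       beta = c(x = 0.15), sigma_upsilon = 0.05,
                                       mag = mag_lognormal(6.81, 0.447)))
  st <- subject_table(d)
  m <- build_model(d, ~x, ~x, family = "LN")
  r <- fit_quiet(m, chains = 2, burn_in = 500, draws = 600, seed = 7, adapt = 200)

  ffit <- fit_frequency_glm(st$n, st["x"])
  mfit <- fit_magnitude_model(d, ~x, family = "lognormal")
  f0 <- negbin_from_mean_dispersion(exp(ffit$coefficients[[1]]),
                                    ffit$dispersion$theta)
  f1 <- negbin_from_mean_dispersion(exp(sum(ffit$coefficients)),
                                    ffit$dispersion$theta)
  m0 <- mag_lognormal(mfit$coefficients[[1]], 0.447)
  m1 <- mag_lognormal(sum(mfit$coefficients), 0.447)
  boot <- bootstrap_sums_glm(list(a = f0, b = f1), list(a = m0, b = m1),
                             groups = factor(rep(c("a", "b"), each = 50)),
                             runs = 500, family = "LN", seed = 8)
  bayes_om <- r$summary["omega_c", ]
  boot_se <- stats::sd(boot$draws[, "group_b"])
  expect_lt(abs(bayes_om$mean - boot$mean[["group_b"]]),
            3 * sqrt(bayes_om$se^2 + boot_se^2))
})
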