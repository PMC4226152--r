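# ---- Bayesian hierarchical estimation ---------------------------------------
#
# The joint model integrates the three layers with shared parameters:
#   frequency:  n_u ~ Poisson(lambda_u), lambda_u ~ gamma(q, q / exp(eta_u)),
#               eta_u = X alpha                      (gamma-mixed Poisson)
#   magnitude:  LN: z_i ~ logN(mu_u, sigma^2); GG: z_i ~ gamma(q_m, q_m/exp(mu_u))
#               mu_u ~ N(ups_u, sigma_ups^2), ups_u = beta_0[round] + Y beta
#   sums:       GG: S_u ~ gamma(lambda_u q_m, lambda_u q_m / exp(muS_u)) with
#                   the identity muS_u = mu_u + log(lambda_u) holding exactly
#                   in every draw, so omega = alpha + beta is derived;
#               LN: S_u ~ logN(muS_u, sigma_s^2) with its own coefficients
#                   muS_u = omega_0[round] + XY omega.
# The two-level model is the one-round special case of the three-level code.
# Sampling is delegated to JAGS; summaries, R-hat, DIC, and predictions are
# computed from the monitored draws.

#' Prior configuration for the hierarchical model
#'
#' Diffuse defaults in the BUGS tradition: Normal(0, sd 100) on all
#' regression coefficients, Gamma(0.01, 0.01) on the gamma shapes `q` and
#' `q_m`, and Gamma(0.01, 0.01) on the precisions of every variance
#' component.
#'
#' @param coef_sd Prior SD of regression coefficients.
#' @param shape_rate,shape_shape Gamma prior (shape, rate) on `q`, `q_m`.
#' @param prec_shape,prec_rate Gamma prior on precisions.
#' @export
prior_config <- function(coef_sd = 100, shape_shape = 0.01, shape_rate = 0.01,
                         prec_shape = 0.01, prec_rate = 0.01) {
  structure(list(coef_prec = 1 / coef_sd^2, shape_shape = shape_shape,
                 shape_rate = shape_rate, prec_shape = prec_shape,
                 prec_rate = prec_rate), class = "prior_config")
}

#' Build the integrated hierarchical model
#'
#' Assembles the joint frequency + magnitude + sums model for a two-level
#' (observations in subjects) or three-level (observations in rounds in
#' subjects) dataset. The frequency layer uses one coefficient vector across
#' rounds; the magnitude and (LN) sums layers get per-round intercepts in
#' the three-level case.
#'
#' @param data An `rss_data` object (with a round column for three-level).
#' @param frequency RHS formula of frequency predictors over the unit table
#'   (e.g. `~ x`); intercept always included.
#' @param magnitude RHS formula of magnitude predictors; the intercept(s)
#'   are per-round parameters.
#' @param family `"LN"` or `"GG"`.
#' @param sums RHS formula for the LN sums layer; defaults to the union of
#'   the frequency and magnitude predictors. Ignored for GG, whose sums
#'   coefficients are derived.
#' @param priors A [prior_config()].
#' @return An object of class `rss_model` whose joint log-density is
#'   computable via [model_log_density()] and which [run_mcmc()] samples.
#' @export
build_model <- function(data, frequency = ~1, magnitude = ~1,
                        family = c("LN", "GG"), sums = NULL,
                        priors = prior_config()) {
  family <- match.arg(family)
  if (!inherits(data, "rss_data")) stop("`data` must be an rss_data", call. = FALSE)
  r <- rss_roles(data)
  st <- subject_table(data)
  levels_n <- if (is.null(r$round)) 2L else 3L
  K <- if (levels_n == 2L) 1L else length(unique(st$round))
  round_idx <- if (levels_n == 2L) rep(1L, nrow(st)) else
    as.integer(factor(st$round))

  X <- stats::model.matrix(frequency, st)
  Yf <- stats::model.matrix(magnitude, st)
  Y <- Yf[, setdiff(colnames(Yf), "(Intercept)"), drop = FALSE]
  if (is.null(sums))
    sums <- stats::reformulate(
      c("1", union(setdiff(colnames(X), "(Intercept)"), colnames(Y))))
  XYf <- stats::model.matrix(sums, st)
  XY <- XYf[, setdiff(colnames(XYf), "(Intercept)"), drop = FALSE]

  # observation -> unit index
  df <- as.data.frame(data)
  key_obs <- if (levels_n == 2L) as.character(df[[r$subject]]) else
    paste(df[[r$subject]], df[[r$round]], sep = "\r")
  key_unit <- if (levels_n == 2L) as.character(st$subject) else
    paste(st$subject, st$round, sep = "\r")
  cell <- match(key_obs, key_unit)

  structure(list(
    family = family, levels = levels_n, K = K, priors = priors,
    data = data, st = st, round_idx = round_idx, cell = cell,
    z = df[[r$magnitude]], X = X, Y = Y, XY = XY,
    W = NULL, wbar = NULL,
    frequency = frequency, magnitude = magnitude, sums = sums),
    class = "rss_model")
}

#' Add observation-level predictors to the magnitude and sums layers
#'
#' Extends the magnitude layer with an observation effect
#' `tau_i = sum_p delta_p[subject] w_pi`, where each `delta_p` is a random
#' coefficient around a fixed effect, and the sums layer with the matching
#' per-unit term built from the per-subject predictor sums `wbar`.
#'
#' @param model An `rss_model` (two-level).
#' @param w Character vector of observation-level column names in the
#'   model's dataset, or a numeric matrix with one row per observation.
#' @return The extended `rss_model`.
#' @export
extend_with_observation_predictors <- function(model, w) {
  stopifnot(inherits(model, "rss_model"))
  if (model$levels != 2L)
    stop("observation-level predictors are supported for two-level models",
         call. = FALSE)
  df <- as.data.frame(model$data)
  W <- if (is.character(w)) {
    miss <- setdiff(w, names(df))
    if (length(miss)) stop("no such columns: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    as.matrix(df[w])
  } else as.matrix(w)
  if (nrow(W) != length(model$z))
    stop("`w` must have one row per observation", call. = FALSE)
  if (is.null(colnames(W))) colnames(W) <- paste0("w", seq_len(ncol(W)))
  model$W <- W
  model$wbar <- rowsum(W, model$cell)  # per-subject predictor sums
  model
}

# ---- JAGS code generation ---------------------------------------------------

jags_code <- function(model) {
  gg <- model$family == "GG"
  Q <- ncol(model$Y); R <- ncol(model$XY); Pw <- if (is.null(model$W)) 0L else ncol(model$W)
  pr <- model$priors
  cp <- format(pr$coef_prec, scientific = TRUE)
  mag_lp <- if (Pw > 0) "mu[cell[i]] + tau[i]" else "mu[cell[i]]"
  lines <- c(
    "model {",
    "  for (u in 1:U) {",
    "    nobs[u] ~ dpois(lambda[u])",
    "    lambda[u] ~ dgamma(q, q / exp(eta[u]))",
    "    eta[u] <- inprod(X[u,], alpha)",
    "    mu[u] ~ dnorm(ups[u], prec_ups)",
    if (Q > 0) "    ups[u] <- b0[rnd[u]] + inprod(Y[u,], beta)"
    else       "    ups[u] <- b0[rnd[u]]",
    "  }",
    "  for (i in 1:Nz) {",
    if (gg) paste0("    z[i] ~ dgamma(qm, qm / exp(", mag_lp, "))")
    else    paste0("    z[i] ~ dlnorm(", mag_lp, ", prec_z)"),
    if (Pw > 0) "    tau[i] <- inprod(W[i,], delta[cell[i],])",
    "  }",
    if (gg) c(
      "  for (u in 1:U) {",
      "    muS[u] <- mu[u] + log(lambda[u])",
      "    S[u] ~ dgamma(lambda[u] * qm, lambda[u] * qm / exp(muS[u]))",
      "  }"
    ) else c(
      "  for (u in 1:U) {",
      paste0("    muS[u] <- w0[rnd[u]]",
             if (R > 0) " + inprod(XY[u,], omega_c)",
             if (Pw > 0) " + inprod(wbar[u,], eta_w)"),
      "    S[u] ~ dlnorm(muS[u], prec_s)",
      "  }"
    ),
    sprintf("  for (k in 1:P) { alpha[k] ~ dnorm(0, %s) }", cp),
    if (Q > 0) sprintf("  for (k in 1:Q) { beta[k] ~ dnorm(0, %s) }", cp),
    sprintf("  for (k in 1:K) { b0[k] ~ dnorm(0, %s) }", cp),
    if (!gg) sprintf("  for (k in 1:K) { w0[k] ~ dnorm(0, %s) }", cp),
    if (!gg && R > 0) sprintf("  for (k in 1:R) { omega_c[k] ~ dnorm(0, %s) }", cp),
    if (Pw > 0) c(
      sprintf("  for (p in 1:Pw) { eta_w[p] ~ dnorm(0, %s) }", cp),
      "  for (p in 1:Pw) { prec_w[p] ~ dgamma(%s, %s) }" |>
        sprintf(pr$prec_shape, pr$prec_rate),
      "  for (j in 1:U) { for (p in 1:Pw) { delta[j,p] ~ dnorm(eta_w[p], prec_w[p]) } }"
    ),
    sprintf("  q ~ dgamma(%s, %s)", pr$shape_shape, pr$shape_rate),
    if (gg) sprintf("  qm ~ dgamma(%s, %s)", pr$shape_shape, pr$shape_rate)
    else c(sprintf("  prec_z ~ dgamma(%s, %s)", pr$prec_shape, pr$prec_rate),
           sprintf("  prec_s ~ dgamma(%s, %s)", pr$prec_shape, pr$prec_rate),
           "  sigma_z <- 1 / sqrt(prec_z)",
           "  sigma_s <- 1 / sqrt(prec_s)"),
    sprintf("  prec_ups ~ dgamma(%s, %s)", pr$prec_shape, pr$prec_rate),
    "  sigma_ups <- 1 / sqrt(prec_ups)",
    "}")
  paste(lines[!vapply(lines, is.null, TRUE)], collapse = "\n")
}

jags_data <- function(model) {
  st <- model$st
  dat <- list(U = nrow(st), Nz = length(model$z), K = model$K,
              nobs = st$n, S = st$S, z = model$z,
              cell = model$cell, rnd = model$round_idx,
              X = model$X, P = ncol(model$X))
  if (ncol(model$Y) > 0) { dat$Y <- model$Y; dat$Q <- ncol(model$Y) }
  if (model$family == "LN" && ncol(model$XY) > 0) {
    dat$XY <- model$XY; dat$R <- ncol(model$XY)
  }
  if (!is.null(model$W)) {
    dat$W <- model$W; dat$wbar <- model$wbar; dat$Pw <- ncol(model$W)
  }
  dat
}

jags_inits <- function(model, chain, seed) {
  st <- model$st
  gg <- model$family == "GG"
  ini <- list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = (if (is.null(seed)) 1L else seed) + 1000L * chain,
    lambda = pmax(st$n, 0.5),
    mu = log(st$mbar),
    alpha = c(log(mean(st$n)), rep(0, ncol(model$X) - 1)),
    b0 = rep(mean(log(st$mbar)), model$K),
    q = 2, prec_ups = 4)
  if (ncol(model$Y) > 0) ini$beta <- rep(0, ncol(model$Y))
  if (gg) ini$qm <- 2 else {
    ini$prec_z <- 1; ini$prec_s <- 1
    ini$w0 <- rep(mean(log(st$S)), model$K)
    if (ncol(model$XY) > 0) ini$omega_c <- rep(0, ncol(model$XY))
  }
  if (!is.null(model$W)) {
    ini$eta_w <- rep(0, ncol(model$W))
    ini$prec_w <- rep(4, ncol(model$W))
    ini$delta <- matrix(0, nrow(st), ncol(model$W))
  }
  ini
}

jags_monitors <- function(model) {
  gg <- model$family == "GG"
  mon <- c("alpha", "b0", if (ncol(model$Y) > 0) "beta",
           "q", "lambda", "mu", "muS", "sigma_ups")
  mon <- c(mon, if (gg) "qm" else c("w0", if (ncol(model$XY) > 0) "omega_c",
                                    "sigma_z", "sigma_s"))
  if (!is.null(model$W)) mon <- c(mon, "eta_w", "delta")
  mon
}

# ---- MCMC -------------------------------------------------------------------

#' Sample the hierarchical model posterior
#'
#' Runs JAGS with the requested chains, burn-in, and post-burn-in draws,
#' then summarizes the posterior: mean, SD, 95% credible interval, and
#' split-free Gelman-Rubin R-hat per parameter. A warning is raised when any
#' monitored parameter has R-hat above 1.05.
#'
#' @param model An `rss_model` from [build_model()].
#' @param chains Number of chains, >= 2.
#' @param burn_in Burn-in iterations per chain.
#' @param draws Kept iterations per chain.
#' @param seed Optional integer seed (drives both inits and samplers).
#' @param adapt Adaptation iterations.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `rss_posterior`: `draws` (a [coda::mcmc.list]
#'   including the derived sums coefficients), `summary` (data frame with
#'   `mean`, `se`, `lower`, `upper`, `rhat`), `dic` (per submodel, see
#'   [compute_dic()]), the model, and sampler settings.
#' @export
run_mcmc <- function(model, chains = 2, burn_in = 5000, draws = 10000,
                     seed = NULL, adapt = 500, quiet = TRUE) {
  stopifnot(inherits(model, "rss_model"))
  if (chains < 2) stop("use at least 2 chains (R-hat needs them)", call. = FALSE)
  if (burn_in < 0) stop("`burn_in` must be non-negative", call. = FALSE)
  inits <- lapply(seq_len(chains), function(ch) jags_inits(model, ch, seed))
  jm <- tryCatch(
    rjags::jags.model(textConnection(jags_code(model)), data = jags_data(model),
                      inits = inits, n.chains = chains, n.adapt = adapt,
                      quiet = quiet),
    error = function(e) stop("JAGS model setup failed: ", conditionMessage(e),
                             call. = FALSE))
  if (burn_in > 0) stats::update(jm, burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(jm, jags_monitors(model), n.iter = draws,
                              progress.bar = "none")
  samp <- append_derived_omega(model, samp)

  sm <- summarize_posterior(samp)
  high <- sm$rhat[is.finite(sm$rhat)] > 1.05
  if (any(high))
    warning(sum(high), " parameter(s) with R-hat > 1.05; inspect convergence",
            call. = FALSE)
  res <- structure(list(draws = samp, summary = sm, model = model,
                        chains = chains, burn_in = burn_in, n_draws = draws,
                        seed = seed),
                   class = "rss_posterior")
  res$dic <- list(frequency = compute_dic(res, "frequency"),
                  magnitude = compute_dic(res, "magnitude"),
                  sums = compute_dic(res, "sums"))
  res
}

# For the GG family the sums coefficients are derived draw-by-draw from the
# additivity identity implied by muS = mu + log(lambda).
# JAGS names a monitored length-1 vector node without brackets
node_col <- function(stem, i, n) if (n == 1) stem else paste0(stem, "[", i, "]")

append_derived_omega <- function(model, samp) {
  if (model$family != "GG") return(samp)
  a_names <- colnames(model$X)
  b_names <- colnames(model$Y)
  out <- lapply(samp, function(ch) {
    M <- as.matrix(ch)
    add <- list()
    for (k in seq_len(model$K)) {
      nm <- if (model$K == 1) "omega0" else paste0("omega0[", k, "]")
      add[[nm]] <- M[, node_col("alpha", 1, length(a_names))] +
        M[, node_col("b0", k, model$K)]
    }
    shared <- union(setdiff(a_names, "(Intercept)"), b_names)
    for (nm in shared) {
      v <- 0
      ia <- match(nm, a_names); ib <- match(nm, b_names)
      if (!is.na(ia)) v <- v + M[, node_col("alpha", ia, length(a_names))]
      if (!is.na(ib)) v <- v + M[, node_col("beta", ib, length(b_names))]
      add[[paste0("omega[", nm, "]")]] <- v
    }
    A <- do.call(cbind, add)
    coda::mcmc(cbind(M, A), start = stats::start(ch), thin = coda::thin(ch))
  })
  coda::mcmc.list(out)
}

summarize_posterior <- function(samp) {
  M <- as.matrix(samp)
  qs <- apply(M, 2, stats::quantile, probs = c(0.025, 0.975))
  rhat <- vapply(colnames(M), function(p) {
    v <- tryCatch(
      coda::gelman.diag(samp[, p, drop = FALSE], autoburnin = FALSE,
                        multivariate = FALSE)$psrf[1, 1],
      error = function(e) NA_real_)
    if (is.na(v) && stats::sd(M[, p]) == 0) v <- 1
    v
  }, numeric(1))
  data.frame(mean = colMeans(M), se = apply(M, 2, stats::sd),
             lower = qs[1, ], upper = qs[2, ], rhat = rhat)
}

#' @export
print.rss_posterior <- function(x, ...) {
  cat(sprintf("<rss_posterior: %s %d-level model, %d chains x %d draws>\n",
              x$model$family, x$model$levels, x$chains, x$n_draws))
  keep <- !grepl("^(lambda|mu|muS|delta)\\[", rownames(x$summary))
  print(round(x$summary[keep, ], 4))
  invisible(x)
}

# ---- deviance / DIC ---------------------------------------------------------

layer_deviance <- function(model, par, submodel) {
  st <- model$st
  g <- function(stem, n) {
    if (n == 1 && stem %in% names(par)) return(par[[stem]])
    par[paste0(stem, "[", seq_len(n), "]")]
  }
  U <- nrow(st)
  switch(submodel,
    frequency = {
      lambda <- g("lambda", U)
      -2 * sum(stats::dpois(st$n, lambda, log = TRUE))
    },
    magnitude = {
      mu <- g("mu", U)[model$cell]
      if (!is.null(model$W)) {
        delta <- matrix(par[paste0("delta[",
          rep(seq_len(U), ncol(model$W)), ",",
          rep(seq_len(ncol(model$W)), each = U), "]")], U)
        mu <- mu + rowSums(model$W * delta[model$cell, , drop = FALSE])
      }
      if (model$family == "GG") {
        qm <- par[["qm"]]
        -2 * sum(stats::dgamma(model$z, shape = qm, rate = qm / exp(mu), log = TRUE))
      } else
        -2 * sum(stats::dlnorm(model$z, mu, par[["sigma_z"]], log = TRUE))
    },
    sums = {
      muS <- g("muS", U)
      if (model$family == "GG") {
        sh <- g("lambda", U) * par[["qm"]]
        -2 * sum(stats::dgamma(st$S, shape = sh, rate = sh / exp(muS), log = TRUE))
      } else
        -2 * sum(stats::dlnorm(st$S, muS, par[["sigma_s"]], log = TRUE))
    },
    stop("unknown submodel: ", submodel))
}

#' Deviance Information Criterion per submodel
#'
#' `Dbar` is the posterior mean of the deviance (-2 log likelihood) of the
#' chosen layer; `pD = Dbar - D(posterior means)` is the effective parameter
#' count; `DIC = Dbar + pD`. Computed from the monitored draws, so repeated
#' calls on the same result are identical.
#'
#' @param result An `rss_posterior`.
#' @param submodel `"frequency"`, `"magnitude"`, or `"sums"`.
#' @return Named vector `c(Dbar, pD, DIC)`.
#' @export
compute_dic <- function(result, submodel = c("frequency", "magnitude", "sums")) {
  stopifnot(inherits(result, "rss_posterior"))
  submodel <- match.arg(submodel)
  M <- as.matrix(result$draws)
  devs <- apply(M, 1, function(row) layer_deviance(result$model, row, submodel))
  dbar <- mean(devs)
  dhat <- layer_deviance(result$model, colMeans(M), submodel)
  c(Dbar = dbar, pD = dbar - dhat, DIC = 2 * dbar - dhat)
}

# ---- posterior prediction ---------------------------------------------------

#' Posterior-mean predictions per unit
#'
#' Case-level predictions incorporating the unit random effects (`lambda_u`,
#' `mu_u`): expected frequency, expected mean magnitude, and expected sum
#' for every subject (or subject-round cell), averaged over the posterior
#' draws on the natural scale.
#'
#' @param result An `rss_posterior`.
#' @param data Optional `rss_data`; must be the dataset the model was built
#'   on (identity is checked), present for interface symmetry.
#' @return Data frame with observed `n`, `mbar`, `S` and `pred_n`,
#'   `pred_mbar`, `pred_S` per unit.
#' @export
posterior_predict <- function(result, data = NULL) {
  stopifnot(inherits(result, "rss_posterior"))
  model <- result$model
  if (!is.null(data)) {
    if (!inherits(data, "rss_data")) stop("`data` must be an rss_data", call. = FALSE)
    if (!isTRUE(all.equal(as.data.frame(data), as.data.frame(model$data),
                          check.attributes = FALSE)))
      stop("`data` does not match the dataset the model was fitted to",
           call. = FALSE)
  }
  st <- model$st
  U <- nrow(st)
  M <- as.matrix(result$draws)
  cols <- function(stem) M[, paste0(stem, "[", seq_len(U), "]"), drop = FALSE]
  lam <- cols("lambda"); mu <- cols("mu"); muS <- cols("muS")
  if (model$family == "GG") {
    pred_mbar <- colMeans(exp(mu))
    pred_S <- colMeans(exp(muS))
  } else {
    s2z <- M[, "sigma_z"]^2; s2s <- M[, "sigma_s"]^2
    pred_mbar <- colMeans(exp(mu + s2z / 2))
    pred_S <- colMeans(exp(muS + s2s / 2))
  }
  out <- st[, intersect(c("subject", "round", "n", "S", "mbar"), names(st))]
  out$pred_n <- colMeans(lam)
  out$pred_mbar <- pred_mbar
  out$pred_S <- pred_S
  out
}

# ---- joint log density ------------------------------------------------------

#' Joint log-density of the hierarchical model at a parameter point
#'
#' Evaluates the unnormalized posterior log-density (likelihood of all three
#' layers plus, optionally, the priors) at a named parameter point. Any
#' parameter outside its support (non-positive `lambda`, shapes, or
#' variances) gives `-Inf`.
#'
#' @param model An `rss_model`.
#' @param pars Named list: `lambda`, `mu` (length-U vectors), `alpha`, `b0`,
#'   optionally `beta`, and the family's dispersion parameters (`q` plus
#'   `qm` for GG; `q`, `sigma_z`, `sigma_s`, `w0`, optionally `omega_c` for
#'   LN), `sigma_ups`, and for extended models `delta`, `eta_w`, `sigma_w`.
#' @param include_priors Include the prior terms (default `TRUE`).
#' @return Scalar log-density (`-Inf` outside the support).
#' @export
model_log_density <- function(model, pars, include_priors = TRUE) {
  stopifnot(inherits(model, "rss_model"))
  st <- model$st
  gg <- model$family == "GG"
  need <- c("lambda", "mu", "alpha", "b0", "q", "sigma_ups",
            if (gg) "qm" else c("sigma_z", "sigma_s", "w0"))
  miss <- setdiff(need, names(pars))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  lambda <- pars$lambda; mu <- pars$mu; q <- pars$q
  pos <- c(lambda, q, pars$sigma_ups,
           if (gg) pars$qm else c(pars$sigma_z, pars$sigma_s))
  if (any(!is.finite(pos)) || any(pos <= 0)) return(-Inf)
  eta <- drop(model$X %*% pars$alpha)
  ups <- pars$b0[model$round_idx] +
    (if (ncol(model$Y) > 0) drop(model$Y %*% pars$beta) else 0)
  mu_obs <- mu[model$cell]
  if (!is.null(model$W))
    mu_obs <- mu_obs + rowSums(model$W * pars$delta[model$cell, , drop = FALSE])
  ld <- sum(stats::dgamma(lambda, shape = q, rate = q / exp(eta), log = TRUE)) +
    sum(stats::dpois(st$n, lambda, log = TRUE)) +
    sum(stats::dnorm(mu, ups, pars$sigma_ups, log = TRUE))
  if (gg) {
    qm <- pars$qm
    muS <- mu + log(lambda)
    ld <- ld + sum(stats::dgamma(model$z, shape = qm,
                                 rate = qm / exp(mu_obs), log = TRUE)) +
      sum(stats::dgamma(st$S, shape = lambda * qm,
                        rate = lambda * qm / exp(muS), log = TRUE))
  } else {
    muS <- pars$w0[model$round_idx] +
      (if (ncol(model$XY) > 0) drop(model$XY %*% pars$omega_c) else 0) +
      (if (!is.null(model$W)) drop(model$wbar %*% pars$eta_w) else 0)
    ld <- ld + sum(stats::dlnorm(model$z, mu_obs, pars$sigma_z, log = TRUE)) +
      sum(stats::dlnorm(st$S, muS, pars$sigma_s, log = TRUE))
  }
  if (!is.null(model$W))
    ld <- ld + sum(stats::dnorm(pars$delta,
                                matrix(pars$eta_w, nrow(pars$delta),
                                       ncol(pars$delta), byrow = TRUE),
                                matrix(pars$sigma_w, nrow(pars$delta),
                                       ncol(pars$delta), byrow = TRUE),
                                log = TRUE))
  if (include_priors) {
    pr <- model$priors
    sdc <- 1 / sqrt(pr$coef_prec)
    coefs <- c(pars$alpha, pars$b0, if (!is.null(pars$beta)) pars$beta,
               if (!gg) c(pars$w0, if (!is.null(pars$omega_c)) pars$omega_c),
               if (!is.null(model$W)) pars$eta_w)
    ld <- ld + sum(stats::dnorm(coefs, 0, sdc, log = TRUE)) +
      stats::dgamma(q, pr$shape_shape, pr$shape_rate, log = TRUE) +
      stats::dgamma(1 / pars$sigma_ups^2, pr$prec_shape, pr$prec_rate, log = TRUE)
    if (gg) ld <- ld + stats::dgamma(pars$qm, pr$shape_shape, pr$shape_rate, log = TRUE)
    else ld <- ld +
      stats::dgamma(1 / pars$sigma_z^2, pr$prec_shape, pr$prec_rate, log = TRUE) +
      stats::dgamma(1 / pars$sigma_s^2, pr$prec_shape, pr$prec_rate, log = TRUE)
  }
  ld
}
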