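# ---- frequentist GLM layer --------------------------------------------------
#
# All three layers (frequency, magnitude, sums) use the log link, so a shared
# predictor's sums coefficient is predicted by adding its frequency and
# magnitude coefficients. Wald tests use the normal reference distribution
# throughout, matching the summary conventions of count GLMs.

new_rss_fit <- function(coefficients, se, family, link, n_units,
                        log_likelihood = NA_real_, dispersion = NULL,
                        extra = list()) {
  stopifnot(identical(names(coefficients), names(se)), all(se > 0))
  z <- coefficients / se
  structure(c(list(
    coefficients = coefficients, standard_errors = se,
    wald_z = z, wald_p = 2 * stats::pnorm(-abs(z)),
    log_likelihood = log_likelihood, family = family, link = link,
    n_units = n_units, dispersion = dispersion), extra),
    class = "rss_fit")
}

#' @export
print.rss_fit <- function(x, ...) {
  cat(sprintf("<rss_fit: %s (%s link), %d units, logLik %.2f>\n",
              x$family, x$link, x$n_units, x$log_likelihood))
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    z = x$wald_z, p = signif(x$wald_p, 3))
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.rss_fit <- function(object, ...) object$coefficients

as_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.data.frame(X)) X <- stats::model.matrix(~., X)
  if (!is.matrix(X)) X <- cbind(x = X)
  if (!"(Intercept)" %in% colnames(X)) X <- cbind("(Intercept)" = 1, X)
  if (nrow(X) != n) stop("design has ", nrow(X), " rows; expected ", n, call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  X
}

# ---- frequency GLM ----------------------------------------------------------

#' Fit the frequency (count) model
#'
#' Log-link Poisson or negative binomial regression of per-subject counts on
#' subject-level predictors. The negative binomial dispersion is estimated by
#' maximum likelihood jointly with the coefficients (via [MASS::glm.nb()]).
#' The Pearson dispersion statistic (chi-square / df) is reported for either
#' family as an over-dispersion diagnostic.
#'
#' @param counts Non-negative integer counts, one per subject.
#' @param X Predictor matrix or data frame (an intercept is added if absent),
#'   or `NULL` for an intercept-only model.
#' @param family `"negbin"` (default) or `"poisson"`.
#' @return An `rss_fit` with coefficients, standard errors, two-sided Wald
#'   p-values, log-likelihood, and dispersion information.
#' @export
fit_frequency_glm <- function(counts, X = NULL, family = c("negbin", "poisson")) {
  family <- match.arg(family)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  X <- as_design(X, length(counts))
  fit <- if (family == "poisson") {
    stats::glm.fit(X, counts, family = stats::poisson("log"))
  } else {
    dat <- data.frame(.y = counts)
    tryCatch(
      suppressWarnings(MASS::glm.nb(.y ~ X - 1, data = dat)),
      error = function(e) stop("negative binomial fit failed: ",
                               conditionMessage(e), call. = FALSE))
  }
  if (family == "poisson") {
    if (!fit$converged) stop("Poisson fit did not converge", call. = FALSE)
    est <- fit$coefficients
    mu <- fit$fitted.values
    cov <- chol2inv(chol(crossprod(X * sqrt(mu))))
    se <- sqrt(diag(cov))
    ll <- sum(stats::dpois(counts, mu, log = TRUE))
    disp <- NULL
  } else {
    est <- stats::coef(fit)
    names(est) <- colnames(X)
    se <- sqrt(diag(stats::vcov(fit)))
    mu <- stats::fitted(fit)
    ll <- as.numeric(stats::logLik(fit))
    disp <- list(theta = fit$theta, theta_se = fit$SE.theta)
  }
  names(est) <- names(se) <- colnames(X)
  vfun <- if (family == "poisson") mu else mu * (1 + mu / disp$theta)
  pearson <- sum((counts - mu)^2 / vfun) / (length(counts) - ncol(X))
  new_rss_fit(est, se, family, "log", length(counts), ll,
              dispersion = disp, extra = list(pearson_dispersion = pearson))
}

# ---- magnitude model --------------------------------------------------------

#' Fit the magnitude (severity) model
#'
#' Two-level model for the per-subject mean magnitudes: the analysis unit is
#' the subject (or subject-round cell), whose mean magnitude is modeled with
#' a log link. The default `"subject_means"` engine fits the log-normal
#' family as a linear model on the log of the per-unit means, the gamma
#' family as a gamma GLM (log link) on the means, and the exponential family
#' as a gamma GLM with unit shape. The opt-in `"mixed"` engine fits an
#' observation-level random-intercept model via lme4 (log-normal:
#' `lmer(log z ~ X + (1 | subject))`; gamma: `glmer` with a Gamma log-link).
#'
#' The reported log-likelihood is the observation-level likelihood of the
#' family at the fitted fixed-effects locations (dispersion at its ML value),
#' so that competing families can be compared on the same data.
#'
#' @param data An `rss_data` object.
#' @param formula RHS formula for unit-level predictors, e.g. `~ x` (default
#'   intercept-only).
#' @param family `"lognormal"`, `"gamma"`, or `"exponential"`.
#' @param engine `"subject_means"` (default) or `"mixed"`.
#' @return An `rss_fit`.
#' @export
fit_magnitude_model <- function(data, formula = ~1,
                                family = c("lognormal", "gamma", "exponential"),
                                engine = c("subject_means", "mixed")) {
  family <- match.arg(family)
  engine <- match.arg(engine)
  if (!inherits(data, "rss_data")) stop("`data` must be an rss_data", call. = FALSE)
  st <- subject_table(data)
  r <- rss_roles(data)
  z <- as.data.frame(data)[[r$magnitude]]

  if (engine == "mixed") return(fit_magnitude_mixed(data, formula, family))

  X <- stats::model.matrix(formula, st)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  if (family == "lognormal") {
    y <- log(st$mbar)
    fit <- stats::lm.fit(X, y)
    est <- fit$coefficients
    sigma2 <- sum(fit$residuals^2) / fit$df.residual
    se <- sqrt(diag(chol2inv(chol(crossprod(X))) * sigma2))
  } else {
    shape_known <- if (family == "exponential") 1 else NULL
    g <- stats::glm.fit(X, st$mbar, family = stats::Gamma("log"))
    if (!g$converged) stop("gamma magnitude fit did not converge", call. = FALSE)
    est <- g$coefficients
    mu <- g$fitted.values
    dispersion <- if (is.null(shape_known))
      sum((st$mbar - mu)^2 / mu^2) / g$df.residual else 1
    se <- sqrt(diag(chol2inv(chol(crossprod(X))) * dispersion))
  }
  names(est) <- names(se) <- colnames(X)

  # observation-level likelihood at the fixed-effects locations
  obs_lp <- rep.int(drop(X %*% est), st$n)
  ll <- switch(family,
    lognormal = {
      res <- log(z) - obs_lp
      s2 <- mean(res^2)
      sum(stats::dlnorm(z, obs_lp, sqrt(s2), log = TRUE))
    },
    gamma = {
      sh <- gamma_shape_ml(z, obs_lp)
      sum(stats::dgamma(z, shape = sh, rate = sh / exp(obs_lp), log = TRUE))
    },
    exponential = sum(stats::dexp(z, rate = exp(-obs_lp), log = TRUE))
  )
  new_rss_fit(est, se, family, "log", nrow(st), ll)
}

# ML gamma shape given log-means (one-dimensional Newton on the profile score)
gamma_shape_ml <- function(z, log_mu) {
  dev <- mean(log(z) - log_mu - z / exp(log_mu))  # = E[log(z/mu) - z/mu]
  sh <- 0.5 / (-dev - 1 + 1e-12)                  # moment-style start
  sh <- max(sh, 0.01)
  for (i in 1:50) {
    score <- log(sh) + 1 - digamma(sh) + dev
    info <- 1 / sh - trigamma(sh)
    step <- score / info
    shn <- sh - step
    if (shn <= 0) shn <- sh / 2
    if (abs(shn - sh) < 1e-10 * sh) { sh <- shn; break }
    sh <- shn
  }
  sh
}

fit_magnitude_mixed <- function(data, formula, family) {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("the mixed engine requires the lme4 package", call. = FALSE)
  r <- rss_roles(data)
  df <- as.data.frame(data)
  df$.subj <- if (is.null(r$round)) df[[r$subject]] else
    interaction(df[[r$subject]], df[[r$round]], drop = TRUE)
  rhs <- paste(deparse(formula[[2]]), collapse = "")
  if (family == "lognormal") {
    f <- stats::as.formula(paste("log(", r$magnitude, ") ~", rhs, "+ (1 | .subj)"))
    m <- lme4::lmer(f, data = df, REML = FALSE)
  } else if (family == "gamma") {
    f <- stats::as.formula(paste(r$magnitude, "~", rhs, "+ (1 | .subj)"))
    m <- lme4::glmer(f, data = df, family = stats::Gamma("log"))
  } else stop("mixed engine supports lognormal and gamma only", call. = FALSE)
  est <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  names(se) <- names(est)
  new_rss_fit(est, se, family, "log", length(unique(df$.subj)),
              as.numeric(stats::logLik(m)),
              extra = list(mixed_model = m))
}

# ---- sums GLM ---------------------------------------------------------------

#' Fit the sums model
#'
#' Log-link GLM for the per-subject sums `S_j`. The LN family is a linear
#' model on `log(S)` (the sums treated as approximately log-normal); the GG
#' family is a gamma GLM with log link. Subjects with zero counts must be
#' excluded before calling (their sum is zero and has no log).
#'
#' @param sums Strictly positive per-subject sums.
#' @param X Predictor matrix or data frame (intercept added if absent), or
#'   `NULL` for intercept-only.
#' @param family `"LN"` (default) or `"GG"`.
#' @return An `rss_fit`.
#' @export
fit_sums_glm <- function(sums, X = NULL, family = c("LN", "GG")) {
  family <- match.arg(family)
  if (any(sums <= 0) || anyNA(sums))
    stop("`sums` must be strictly positive (drop zero-count subjects first)",
         call. = FALSE)
  X <- as_design(X, length(sums))
  if (family == "LN") {
    y <- log(sums)
    fit <- stats::lm.fit(X, y)
    est <- fit$coefficients
    sigma2 <- sum(fit$residuals^2) / fit$df.residual
    se <- sqrt(diag(chol2inv(chol(crossprod(X))) * sigma2))
    s2ml <- mean(fit$residuals^2)
    ll <- sum(stats::dlnorm(sums, drop(X %*% est), sqrt(s2ml), log = TRUE))
    disp <- list(sigma = sqrt(sigma2))
  } else {
    g <- stats::glm.fit(X, sums, family = stats::Gamma("log"))
    if (!g$converged) stop("gamma sums fit did not converge", call. = FALSE)
    est <- g$coefficients
    mu <- g$fitted.values
    dispersion <- sum((sums - mu)^2 / mu^2) / g$df.residual
    se <- sqrt(diag(chol2inv(chol(crossprod(X))) * dispersion))
    sh <- gamma_shape_ml(sums, log(mu))
    ll <- sum(stats::dgamma(sums, shape = sh, rate = sh / mu, log = TRUE))
    disp <- list(pearson_dispersion = dispersion, shape_ml = sh)
  }
  names(est) <- names(se) <- colnames(X)
  new_rss_fit(est, se, family, "log", length(sums), ll, dispersion = disp)
}

# ---- coefficient additivity -------------------------------------------------

#' Predict sums-model coefficients from frequency and magnitude coefficients
#'
#' Under shared log links, a predictor appearing in both the frequency and
#' magnitude models has sums-model coefficient `omega = alpha + beta`.
#' Predictors present in only one model pass through unchanged.
#'
#' @param alpha Named numeric vector of frequency coefficients, or an
#'   `rss_fit` from [fit_frequency_glm()].
#' @param beta Named numeric vector of magnitude coefficients, or an
#'   `rss_fit` from [fit_magnitude_model()].
#' @return Named numeric vector of predicted sums coefficients over the union
#'   of predictor names.
#' @examples
#' predict_sums_coefficients(c(x = 0.135), c(x = 0.111))  # x = 0.246
#' @export
predict_sums_coefficients <- function(alpha, beta) {
  get_coefs <- function(v, nm) {
    if (inherits(v, "rss_fit")) {
      if (!identical(v$link, "log"))
        stop("coefficient additivity requires log links; ", nm, " uses ",
             v$link, call. = FALSE)
      v <- v$coefficients
    }
    if (is.null(names(v)) && length(v) == 1L) names(v) <- "(Intercept)"
    if (is.null(names(v))) stop("`", nm, "` must be named", call. = FALSE)
    v
  }
  a <- get_coefs(alpha, "alpha")
  b <- get_coefs(beta, "beta")
  nms <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(nms)), nms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

# ---- fast two-group fits (power engine backbone) ----------------------------
#
# Closed-form equivalents of the two-condition log-link fits: coefficients
# are log group means; the negative binomial size is profiled out by ML
# (MASS::theta.ml), giving Wald z-tests identical to glm.nb / glm summaries.
# Each returns c(estimate, se, p) for the condition coefficient.

fast_negbin_2group <- function(n0, n1) {
  m0 <- mean(n0); m1 <- mean(n1)
  if (m0 <= 0 || m1 <= 0) return(c(NA_real_, NA_real_, NA_real_))
  mu <- c(rep.int(m0, length(n0)), rep.int(m1, length(n1)))
  th <- tryCatch(
    as.numeric(suppressWarnings(MASS::theta.ml(c(n0, n1), mu, limit = 25))),
    error = function(e) 1e6)  # under-dispersed sample: Poisson limit
  w0 <- length(n0) * m0 * th / (th + m0)
  w1 <- length(n1) * m1 * th / (th + m1)
  b1 <- log(m1) - log(m0)
  se <- sqrt(1 / w0 + 1 / w1)
  c(b1, se, 2 * stats::pnorm(-abs(b1 / se)))
}

fast_lognormal_2group <- function(y0, y1) {
  # gaussian linear model of log outcomes on a binary condition
  n0 <- length(y0); n1 <- length(y1)
  if (n0 < 2 || n1 < 2) return(c(NA_real_, NA_real_, NA_real_))
  b1 <- mean(y1) - mean(y0)
  s2 <- (sum((y0 - mean(y0))^2) + sum((y1 - mean(y1))^2)) / (n0 + n1 - 2)
  se <- sqrt(s2 * (1 / n0 + 1 / n1))
  c(b1, se, 2 * stats::pnorm(-abs(b1 / se)))
}

fast_gamma_2group <- function(y0, y1) {
  # gamma GLM (log link) with Pearson dispersion, as summary.glm reports
  n0 <- length(y0); n1 <- length(y1)
  if (n0 < 2 || n1 < 2) return(c(NA_real_, NA_real_, NA_real_))
  m0 <- mean(y0); m1 <- mean(y1)
  phi <- (sum((y0 - m0)^2) / m0^2 + sum((y1 - m1)^2) / m1^2) / (n0 + n1 - 2)
  b1 <- log(m1) - log(m0)
  se <- sqrt(phi * (1 / n0 + 1 / n1))
  c(b1, se, 2 * stats::pnorm(-abs(b1 / se)))
}
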