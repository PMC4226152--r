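# ---- frequency model specifications -----------------------------------------

new_freq_spec <- function(family, params, coefficients = NULL,
                          predictors = NULL, link = "log") {
  structure(
    list(family = family, params = params, coefficients = coefficients,
         predictors = predictors, link = link),
    class = c(paste0("freq_", family), "freq_spec", "rss_spec")
  )
}

#' Negative binomial frequency specification from event probability and scale
#'
#' Constructs a negative binomial count model parameterized by an event
#' probability `pi` and scale (size) `phi`, the convention in which the
#' expected frequency is `theta = phi * pi / (1 - pi)` and the variance is
#' `omega_sq = phi * pi / (1 - pi)^2`. The variance always exceeds the mean by
#' the factor `1 / (1 - pi)`, which is how the family represents
#' over-dispersed counts.
#'
#' @param pi Event probability, in (0, 1).
#' @param phi Scale (size) parameter, > 0.
#' @return A `freq_spec` object with fields `theta` (mean) and `omega_sq`
#'   (variance) precomputed.
#' @seealso [negbin_from_mean_dispersion()] for the (mean, size) convention,
#'   [natural_moments()], [sample_frequencies()].
#' @examples
#' spec <- negbin_from_prob_scale(0.5, 10)
#' spec$params$theta     # 10
#' spec$params$omega_sq  # 20
#' @export
negbin_from_prob_scale <- function(pi, phi) {
  if (!is.numeric(pi) || length(pi) != 1L || is.na(pi) || pi <= 0 || pi >= 1)
    stop("`pi` must be a single probability strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi <= 0)
    stop("`phi` must be a single positive scale parameter", call. = FALSE)
  theta <- phi * pi / (1 - pi)
  omega_sq <- phi * pi / (1 - pi)^2
  new_freq_spec("negbin",
                list(pi = pi, phi = phi, theta = theta, omega_sq = omega_sq))
}

#' Negative binomial frequency specification from mean and dispersion
#'
#' Converter for the (mean, size) parameterization: `theta` is the expected
#' count and `phi` the size (dispersion) parameter, so that the variance is
#' `theta + theta^2 / phi`. Internally stored in the (probability, scale)
#' convention, with `pi = theta / (phi + theta)`.
#'
#' @param theta Expected count, > 0.
#' @param phi Size parameter, > 0.
#' @export
negbin_from_mean_dispersion <- function(theta, phi) {
  if (theta <= 0) stop("`theta` must be positive", call. = FALSE)
  if (phi <= 0) stop("`phi` must be positive", call. = FALSE)
  negbin_from_prob_scale(theta / (phi + theta), phi)
}

#' Poisson frequency specification
#'
#' @param lambda Expected count, >= 0.
#' @export
freq_poisson <- function(lambda) {
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  new_freq_spec("poisson", list(lambda = lambda))
}

#' Poisson-gamma (gamma-mixed Poisson) frequency specification
#'
#' The Poisson rate is itself gamma distributed with shape `q` and rate
#' `q / eta`, so the marginal count mean is `eta` and the marginal variance is
#' `eta + eta^2 / q`. As `q` grows the mixing variance vanishes and the family
#' collapses to Poisson. This is the frequency layer used by the Bayesian
#' hierarchical estimator.
#'
#' @param q Mixing shape, > 0.
#' @param eta Mixing mean (expected count), > 0.
#' @export
freq_poisson_gamma <- function(q, eta) {
  if (q <= 0) stop("`q` must be positive", call. = FALSE)
  if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
  new_freq_spec("poisson_gamma", list(q = q, eta = eta, r = q / eta))
}

#' Poisson-log-normal frequency specification
#'
#' The Poisson rate is log-normal with log-scale mean `meanlog` and SD
#' `sdlog`. Provided for completeness among the over-dispersed count families;
#' no conditional-sum closure is claimed for it.
#'
#' @param meanlog,sdlog Log-scale mean and SD of the mixing distribution.
#' @export
freq_poisson_lognormal <- function(meanlog, sdlog) {
  if (sdlog < 0) stop("`sdlog` must be non-negative", call. = FALSE)
  new_freq_spec("poisson_lognormal", list(meanlog = meanlog, sdlog = sdlog))
}

#' Degenerate frequency specification (fixed count)
#'
#' Every subject receives exactly `n` observations. Useful for collapsing the
#' sums distribution onto the magnitude distribution (n = 1) and in tests.
#'
#' @param n Fixed non-negative integer count.
#' @export
freq_fixed <- function(n) {
  if (n < 0 || n != round(n)) stop("`n` must be a non-negative integer", call. = FALSE)
  new_freq_spec("fixed", list(n = as.integer(n)))
}

# ---- magnitude model specifications -----------------------------------------

new_mag_spec <- function(family, params, link = "log") {
  structure(
    list(family = family, params = params, link = link),
    class = c(paste0("mag_", family), "mag_spec", "rss_spec")
  )
}

#' Magnitude (severity) model specifications
#'
#' Constructors for the positive-magnitude families: exponential (by its
#' mean), gamma (shape, scale), log-normal (log-scale mean and SD), and
#' inverse Gaussian (location `theta` = mean, shape `kappa`). All use the log
#' link in the modeling layers.
#'
#' @param mean Exponential mean, > 0.
#' @param shape,scale Gamma shape and scale, > 0.
#' @param meanlog,sdlog Log-normal log-scale mean and SD (`sdlog` > 0).
#' @param theta,kappa Inverse Gaussian mean and shape, > 0. With this
#'   parameterization the variance is `theta^3 / kappa`.
#' @return A `mag_spec` object.
#' @name mag_spec
NULL

#' @rdname mag_spec
#' @export
mag_exponential <- function(mean) {
  if (mean <= 0) stop("exponential `mean` must be positive", call. = FALSE)
  new_mag_spec("exponential", list(mean = mean))
}

#' @rdname mag_spec
#' @export
mag_gamma <- function(shape, scale) {
  if (shape <= 0 || scale <= 0)
    stop("gamma `shape` and `scale` must be positive", call. = FALSE)
  new_mag_spec("gamma", list(shape = shape, scale = scale))
}

#' @rdname mag_spec
#' @export
mag_lognormal <- function(meanlog, sdlog) {
  if (sdlog <= 0) stop("log-normal `sdlog` must be positive", call. = FALSE)
  new_mag_spec("lognormal", list(meanlog = meanlog, sdlog = sdlog))
}

#' @rdname mag_spec
#' @export
mag_invgauss <- function(theta, kappa) {
  if (theta <= 0 || kappa <= 0)
    stop("inverse Gaussian `theta` and `kappa` must be positive", call. = FALSE)
  new_mag_spec("invgauss", list(theta = theta, kappa = kappa))
}

# ---- moments ----------------------------------------------------------------

#' Natural-scale mean and standard deviation of a model specification
#'
#' Closed-form first two moments of a frequency or magnitude specification on
#' the natural (observation) scale.
#'
#' @param spec A `freq_spec` or `mag_spec`.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @examples
#' natural_moments(mag_gamma(4, 250))              # 1000, 500
#' natural_moments(negbin_from_prob_scale(0.5, 10)) # 10, sqrt(20)
#' @export
natural_moments <- function(spec) UseMethod("natural_moments")

#' @export
natural_moments.freq_spec <- function(spec) {
  p <- spec$params
  mv <- switch(spec$family,
    poisson = c(p$lambda, p$lambda),
    negbin = c(p$theta, p$omega_sq),
    poisson_gamma = c(p$eta, p$eta + p$eta^2 / p$q),
    poisson_lognormal = {
      m <- exp(p$meanlog + p$sdlog^2 / 2)
      c(m, m + m^2 * (exp(p$sdlog^2) - 1))
    },
    fixed = c(p$n, 0),
    stop("unknown frequency family: ", spec$family)
  )
  c(mean = mv[1], sd = sqrt(mv[2]))
}

#' @export
natural_moments.mag_spec <- function(spec) {
  p <- spec$params
  mv <- switch(spec$family,
    exponential = c(p$mean, p$mean^2),
    gamma = c(p$shape * p$scale, p$shape * p$scale^2),
    lognormal = {
      m <- exp(p$meanlog + p$sdlog^2 / 2)
      c(m, m^2 * (exp(p$sdlog^2) - 1))
    },
    invgauss = c(p$theta, p$theta^3 / p$kappa),
    stop("unknown magnitude family: ", spec$family)
  )
  c(mean = mv[1], sd = sqrt(mv[2]))
}

#' Probability mass function of a frequency specification
#'
#' @param spec A `freq_spec`.
#' @param n Vector of non-negative integer counts.
#' @return `Pr(N = n)` for each element of `n`.
#' @export
freq_pmf <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    poisson = stats::dpois(n, p$lambda),
    negbin = stats::dnbinom(n, size = p$phi, mu = p$theta),
    poisson_gamma = stats::dnbinom(n, size = p$q, mu = p$eta),
    fixed = as.numeric(n == p$n),
    stop("no closed-form pmf for frequency family: ", spec$family)
  )
}

# ---- sampling ---------------------------------------------------------------

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && abs(seed) >= 2^31)
    stop("`seed` must be a 32-bit integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw subject counts from a frequency specification
#'
#' @param spec A `freq_spec`.
#' @param J Number of subjects (draws), >= 1.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's random state is left untouched.
#' @return Integer vector of `J` non-negative counts.
#' @export
sample_frequencies <- function(spec, J, seed = NULL) {
  if (!inherits(spec, "freq_spec")) stop("`spec` must be a freq_spec", call. = FALSE)
  if (J < 1) stop("`J` must be at least 1", call. = FALSE)
  p <- spec$params
  with_seed(seed, switch(spec$family,
    poisson = stats::rpois(J, p$lambda),
    negbin = stats::rnbinom(J, size = p$phi, mu = p$theta),
    poisson_gamma = stats::rpois(J, stats::rgamma(J, shape = p$q, rate = p$q / p$eta)),
    poisson_lognormal = stats::rpois(J, stats::rlnorm(J, p$meanlog, p$sdlog)),
    fixed = rep.int(p$n, J),
    stop("cannot sample frequency family: ", spec$family)
  ))
}

# Inverse Gaussian sampler (Michael, Schucany & Haas transformation).
rinvgauss_ms <- function(n, mean, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Draw magnitudes from a magnitude specification
#'
#' @param spec A `mag_spec`.
#' @param n Number of draws, >= 0 (`n = 0` returns an empty vector).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` strictly positive magnitudes.
#' @export
sample_magnitudes <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "mag_spec")) stop("`spec` must be a mag_spec", call. = FALSE)
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (n == 0) return(numeric(0))
  p <- spec$params
  with_seed(seed, switch(spec$family,
    exponential = stats::rexp(n, rate = 1 / p$mean),
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    invgauss = rinvgauss_ms(n, p$theta, p$kappa),
    stop("cannot sample magnitude family: ", spec$family)
  ))
}

# ---- conditional-sum closure ------------------------------------------------

#' Distribution of the sum of n magnitudes, conditional on the count
#'
#' For families closed under convolution at fixed n, returns the law of
#' `S = Z_1 + ... + Z_n`: gamma magnitudes `gamma(shape, scale)` sum to
#' `gamma(n * shape, scale)` (the exponential is the shape-1 special case),
#' and inverse Gaussian `IG(theta, kappa)` magnitudes sum to
#' `IG(n * theta, n^2 * kappa)`. Log-normal magnitudes have no closed-form
#' sum; the returned law has family `"none"`.
#'
#' @param spec A `mag_spec`.
#' @param n Count of summed magnitudes, >= 1.
#' @return An object of class `sum_law` with fields `family` and `params`,
#'   and (when closed-form) distribution functions `cdf` and `quantile`.
#' @export
conditional_sum_law <- function(spec, n) {
  if (!inherits(spec, "mag_spec")) stop("`spec` must be a mag_spec", call. = FALSE)
  if (n < 1 || n != round(n)) stop("`n` must be an integer >= 1", call. = FALSE)
  p <- spec$params
  law <- switch(spec$family,
    gamma = list(family = "gamma",
                 params = list(shape = n * p$shape, scale = p$scale)),
    exponential = list(family = "gamma",
                       params = list(shape = n, scale = p$mean)),
    invgauss = list(family = "invgauss",
                    params = list(theta = n * p$theta, kappa = n^2 * p$kappa)),
    lognormal = list(family = "none", params = list()),
    stop("unknown magnitude family: ", spec$family)
  )
  law$n <- n
  if (law$family == "gamma") {
    law$cdf <- function(q) stats::pgamma(q, shape = law$params$shape, scale = law$params$scale)
    law$quantile <- function(pr) stats::qgamma(pr, shape = law$params$shape, scale = law$params$scale)
  } else if (law$family == "invgauss") {
    law$cdf <- function(q) pinvgauss_ms(q, law$params$theta, law$params$kappa)
  }
  class(law) <- "sum_law"
  law
}

# IG cdf (standard form in the mean/shape parameterization)
pinvgauss_ms <- function(q, mean, shape) {
  ifelse(q <= 0, 0,
    stats::pnorm(sqrt(shape / q) * (q / mean - 1)) +
      exp(2 * shape / mean) * stats::pnorm(-sqrt(shape / q) * (q / mean + 1)))
}

# ---- effect application (standard-deviation units) --------------------------

#' Shift a specification's natural-scale mean by an effect in SD units
#'
#' Implements the effect operationalization of the simulation study: the new
#' natural-scale mean is `m0 + d * s0`, where `(m0, s0)` are the baseline
#' natural moments, with the family's secondary parameter held fixed. The
#' negative binomial holds its scale `phi` and re-solves the event
#' probability; the log-normal holds `sdlog` and re-solves `meanlog`; the
#' gamma holds its shape and rescales; the exponential and Poisson have a
#' single parameter.
#'
#' @param spec A `freq_spec` or `mag_spec`.
#' @param d Effect size in baseline standard-deviation units.
#' @return A shifted specification of the same family.
#' @export
apply_effect <- function(spec, d) UseMethod("apply_effect")

shifted_mean <- function(spec, d) {
  mo <- natural_moments(spec)
  m <- mo["mean"] + d * mo["sd"]
  if (m <= 0)
    stop("effect d = ", d, " drives the mean non-positive", call. = FALSE)
  unname(m)
}

#' @export
apply_effect.freq_spec <- function(spec, d) {
  if (d == 0) return(spec)
  m <- shifted_mean(spec, d)
  p <- spec$params
  switch(spec$family,
    negbin = negbin_from_mean_dispersion(m, p$phi),
    poisson = freq_poisson(m),
    poisson_gamma = freq_poisson_gamma(p$q, m),
    stop("apply_effect is not defined for frequency family: ", spec$family)
  )
}

#' @export
apply_effect.mag_spec <- function(spec, d) {
  if (d == 0) return(spec)
  m <- shifted_mean(spec, d)
  p <- spec$params
  switch(spec$family,
    lognormal = mag_lognormal(log(m) - p$sdlog^2 / 2, p$sdlog),
    gamma = mag_gamma(p$shape, m / p$shape),
    exponential = mag_exponential(m),
    invgauss = mag_invgauss(m, p$kappa),
    stop("apply_effect is not defined for magnitude family: ", spec$family)
  )
}

# ---- serialization ----------------------------------------------------------

#' Read and write model specifications as structured config files
#'
#' Specifications round-trip through a YAML config with keys `kind`
#' (`"frequency"` or `"magnitude"`), `family`, `parameters`, `link`, and
#' optional `coefficients` / `predictors`.
#'
#' @param spec A `freq_spec` or `mag_spec`.
#' @param path File path.
#' @return `read_spec_config()` returns the reconstructed specification;
#'   `write_spec_config()` returns `path` invisibly.
#' @export
write_spec_config <- function(spec, path) {
  stopifnot(inherits(spec, "rss_spec"))
  cfg <- list(
    kind = if (inherits(spec, "freq_spec")) "frequency" else "magnitude",
    family = spec$family,
    link = spec$link,
    parameters = spec$params
  )
  if (!is.null(spec$coefficients)) cfg$coefficients <- as.list(spec$coefficients)
  if (!is.null(spec$predictors)) cfg$predictors <- spec$predictors
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_spec_config
#' @export
read_spec_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$parameters
  spec <- if (identical(cfg$kind, "frequency")) {
    switch(cfg$family,
      poisson = freq_poisson(p$lambda),
      negbin = negbin_from_prob_scale(p$pi, p$phi),
      poisson_gamma = freq_poisson_gamma(p$q, p$eta),
      poisson_lognormal = freq_poisson_lognormal(p$meanlog, p$sdlog),
      fixed = freq_fixed(p$n),
      stop("unknown frequency family in config: ", cfg$family)
    )
  } else if (identical(cfg$kind, "magnitude")) {
    switch(cfg$family,
      exponential = mag_exponential(p$mean),
      gamma = mag_gamma(p$shape, p$scale),
      lognormal = mag_lognormal(p$meanlog, p$sdlog),
      invgauss = mag_invgauss(p$theta, p$kappa),
      stop("unknown magnitude family in config: ", cfg$family)
    )
  } else stop("config `kind` must be 'frequency' or 'magnitude'", call. = FALSE)
  if (!is.null(cfg$coefficients)) spec$coefficients <- unlist(cfg$coefficients)
  if (!is.null(cfg$predictors)) spec$predictors <- cfg$predictors
  spec
}

#' @export
print.rss_spec <- function(x, ...) {
  kind <- if (inherits(x, "freq_spec")) "frequency" else "magnitude"
  cat(sprintf("<%s spec: %s>\n", kind, x$family))
  cat("  parameters:",
      paste(names(x$params), signif(unlist(x$params), 5), sep = " = ",
            collapse = ", "), "\n")
  if (x$family != "fixed") {
    mo <- natural_moments(x)
    cat(sprintf("  natural scale: mean %.4g, sd %.4g\n", mo["mean"], mo["sd"]))
  }
  invisible(x)
}
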