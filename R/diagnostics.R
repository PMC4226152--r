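# ---- sums-model diagnostics -------------------------------------------------

#' Log-scale residuals of a sums model
#'
#' `log(observed) - log(predicted)` per case; with a log link these are the
#' residuals on the linear-predictor scale, the natural scale on which to
#' screen for outliers and skew.
#'
#' @param observed,predicted Strictly positive vectors of equal length.
#' @param shapiro If `TRUE`, also attach a Shapiro-Wilk normality p-value
#'   (off by default; a screening aid, not part of the model).
#' @return Numeric residual vector (with attribute `shapiro_p` if requested).
#' @export
residuals_log_scale <- function(observed, predicted, shapiro = FALSE) {
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  if (any(observed <= 0) || any(predicted <= 0) || anyNA(observed) || anyNA(predicted))
    stop("values must be strictly positive and non-missing", call. = FALSE)
  res <- log(observed) - log(predicted)
  if (shapiro && length(res) >= 3)
    attr(res, "shapiro_p") <- stats::shapiro.test(res)$p.value
  res
}

#' Predicted-vs-observed correlations for means and sums
#'
#' @param observed_means,predicted_means Per-unit mean magnitudes.
#' @param observed_sums,predicted_sums Per-unit sums.
#' @return Named vector with the two Pearson correlations.
#' @export
prediction_correlations <- function(observed_means, predicted_means,
                                    observed_sums, predicted_sums) {
  c(means = stats::cor(observed_means, predicted_means),
    sums = stats::cor(observed_sums, predicted_sums))
}

#' Compare a simulated sums distribution against observed sums
#'
#' Side-by-side mean, SD, and quantiles for the model's simulated sums
#' distribution and the empirical sums, the primary informal diagnostic for
#' the sums model.
#'
#' @param simulated An `rss_sim` from [simulate_sums()], or a numeric vector
#'   of simulated sums.
#' @param observed Numeric vector of observed sums.
#' @param probs Quantile probabilities (defaults to the quartiles).
#' @return Data frame with rows `model` and `observed`.
#' @export
compare_quantiles <- function(simulated, observed, probs = c(0.25, 0.5, 0.75)) {
  sim <- if (inherits(simulated, "rss_sim")) as.vector(simulated$sums) else simulated
  if (!length(sim) || !length(observed)) stop("empty input", call. = FALSE)
  row <- function(x) c(stats::quantile(x, probs), mean = mean(x), sd = stats::sd(x))
  out <- as.data.frame(rbind(model = row(sim), observed = row(observed)))
  names(out)[seq_along(probs)] <- paste0("q", format(100 * probs, trim = TRUE))
  out
}

#' Pathology screening of bootstrap coefficient draws
#'
#' Per-coefficient location, skew, and outlier summary for bootstrap draws:
#' mean, median, adjusted Fisher-Pearson sample skewness, and the number of
#' draws lying more than 3 interquartile ranges from the median (the rule
#' used to flag overly influential replicates).
#'
#' @param draws An `rss_boot` from [bootstrap_sums_glm()], or a numeric
#'   matrix of draws (columns = coefficients), with at least 100 rows.
#' @return Data frame with one row per coefficient: `mean`, `median`,
#'   `skewness`, `n_outliers`.
#' @export
coefficient_pathology <- function(draws) {
  if (inherits(draws, "rss_boot")) draws <- draws$draws
  draws <- as.matrix(draws)
  if (nrow(draws) < 100)
    stop("need at least 100 draws for pathology screening", call. = FALSE)
  one <- function(x) {
    n <- length(x)
    m <- mean(x); s <- stats::sd(x)
    g1 <- mean((x - m)^3) / s^3
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)  # adjusted Fisher-Pearson
    iqr <- stats::IQR(x)
    med <- stats::median(x)
    c(mean = m, median = med, skewness = skew,
      n_outliers = if (iqr > 0) sum(abs(x - med) > 3 * iqr) else 0)
  }
  out <- as.data.frame(t(apply(draws, 2, one)))
  out$n_outliers <- as.integer(out$n_outliers)
  out
}
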