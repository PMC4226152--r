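# ---- simulation approximation of the sums distribution ----------------------

#' Simulate the distribution of randomly stopped sums
#'
#' Three-step generative loop, replicated `runs` times: draw `J` counts from
#' the frequency specification, draw that many magnitudes per subject, and
#' sum them. The resulting `runs x J` matrix is an empirical approximation of
#' the sums distribution; 10,000-20,000 runs give stable summaries.
#'
#' @param freq_spec A `freq_spec`.
#' @param mag_spec A `mag_spec`.
#' @param J Subjects per replicate, >= 1.
#' @param runs Number of replicates, >= 1.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `rss_sim` with fields `sums` (runs x J matrix;
#'   an entry is zero exactly when its drawn count was zero), `counts`
#'   (matching count matrix), `runs`, `seed`, and the two specs.
#' @export
simulate_sums <- function(freq_spec, mag_spec, J, runs = 10000, seed = NULL) {
  stopifnot(inherits(freq_spec, "freq_spec"), inherits(mag_spec, "mag_spec"),
            J >= 1, runs >= 1)
  with_seed(seed, {
    n <- sample_frequencies(freq_spec, J * runs)
    z <- sample_magnitudes(mag_spec, sum(n))
    sums <- numeric(J * runs)
    nz <- n > 0
    if (any(nz))
      sums[nz] <- rowsum(z, rep.int(seq_len(J * runs)[nz], n[nz]), reorder = TRUE)[, 1]
    structure(list(
      sums = matrix(sums, nrow = runs, ncol = J, byrow = TRUE),
      counts = matrix(n, nrow = runs, ncol = J, byrow = TRUE),
      runs = runs, J = J, seed = seed,
      freq_spec = freq_spec, mag_spec = mag_spec),
      class = "rss_sim")
  })
}

#' Summary statistics of a simulated sums distribution
#'
#' @param result An `rss_sim` from [simulate_sums()].
#' @param probs Quantile probabilities to tabulate.
#' @return A list with `mean`, `sd`, `quantiles`, and a monotone `quantile`
#'   function over all simulated sums.
#' @export
sums_summary <- function(result, probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(result, "rss_sim"))
  s <- as.vector(result$sums)
  if (!length(s)) stop("empty simulation result", call. = FALSE)
  list(mean = mean(s), sd = stats::sd(s),
       quantiles = stats::quantile(s, probs),
       quantile = function(p) stats::quantile(s, p, names = FALSE),
       n = length(s))
}

#' @export
print.rss_sim <- function(x, ...) {
  sm <- sums_summary(x)
  cat(sprintf("<rss_sim: %d runs x %d subjects (%s frequencies, %s magnitudes)>\n",
              x$runs, x$J, x$freq_spec$family, x$mag_spec$family))
  cat(sprintf("  sums: mean %.5g, sd %.5g; quartiles %.5g / %.5g / %.5g\n",
              sm$mean, sm$sd, sm$quantiles[1], sm$quantiles[2], sm$quantiles[3]))
  invisible(x)
}

# ---- parametric bootstrap of the sums GLM -----------------------------------

#' Bootstrap estimates of sums-model coefficients by simulation
#'
#' Parametric bootstrap of the sums GLM: in each replicate every subject's
#' sum is simulated from its group's frequency and magnitude specifications
#' (held fixed at the supplied values), the sums GLM is fitted to that
#' replicate (log-normal: linear model on log sums; GG: gamma GLM, log link),
#' and the coefficients are collected. Subjects drawing a zero count are
#' excluded from that replicate's fit; replicates whose fit is degenerate
#' (e.g. a condition entirely zero) are skipped and counted.
#'
#' @param freq_specs A single `freq_spec` shared by all subjects, or a list
#'   of specs named by the levels of `groups`.
#' @param mag_specs A single `mag_spec`, or a list named by group level.
#' @param groups Factor of length `J` assigning subjects to groups; `NULL`
#'   for a single group (intercept-only model).
#' @param J Number of subjects when `groups` is `NULL`.
#' @param runs Bootstrap replicates.
#' @param family Sums GLM family, `"LN"` or `"GG"`.
#' @param level Confidence level for the percentile intervals.
#' @param seed Optional integer seed.
#' @return An object of class `rss_boot`: `draws` (runs x coefficients),
#'   `mean`, `median`, `ci` (percentile), `level`, `runs_effective`,
#'   `runs_skipped`.
#' @export
bootstrap_sums_glm <- function(freq_specs, mag_specs, groups = NULL, J = NULL,
                               runs = 10000, family = c("LN", "GG"),
                               level = 0.95, seed = NULL) {
  family <- match.arg(family)
  if (is.null(groups)) {
    if (is.null(J)) stop("supply `groups` or `J`", call. = FALSE)
    groups <- factor(rep("all", J))
  }
  groups <- droplevels(as.factor(groups))
  J <- length(groups)
  lev <- levels(groups)
  as_spec_list <- function(specs, cls) {
    if (inherits(specs, cls)) specs <- stats::setNames(rep(list(specs), length(lev)), lev)
    if (!all(lev %in% names(specs)))
      stop("specs must be named by group level: ", paste(lev, collapse = ", "),
           call. = FALSE)
    specs
  }
  fspecs <- as_spec_list(freq_specs, "freq_spec")
  mspecs <- as_spec_list(mag_specs, "mag_spec")
  X <- if (length(lev) > 1) stats::model.matrix(~groups) else
    matrix(1, J, 1, dimnames = list(NULL, "(Intercept)"))
  colnames(X) <- sub("^groups", "group_", colnames(X))
  if (qr(X)$rank < ncol(X)) stop("degenerate design", call. = FALSE)

  with_seed(seed, {
    draws <- matrix(NA_real_, runs, ncol(X), dimnames = list(NULL, colnames(X)))
    skipped <- 0L
    gi <- split(seq_len(J), groups)
    for (r in seq_len(runs)) {
      S <- numeric(J)
      for (g in lev) {
        idx <- gi[[g]]
        n <- sample_frequencies(fspecs[[g]], length(idx))
        z <- sample_magnitudes(mspecs[[g]], sum(n))
        pos <- n > 0
        if (any(pos))
          S[idx[pos]] <- rowsum(z, rep.int(seq_along(idx)[pos], n[pos]))[, 1]
      }
      keep <- S > 0
      cf <- tryCatch({
        Xk <- X[keep, , drop = FALSE]
        if (qr(Xk)$rank < ncol(Xk)) stop("rank")
        if (family == "LN") stats::lm.fit(Xk, log(S[keep]))$coefficients
        else {
          g <- stats::glm.fit(Xk, S[keep], family = stats::Gamma("log"))
          if (!g$converged) stop("nc")
          g$coefficients
        }
      }, error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) skipped <- skipped + 1L else draws[r, ] <- cf
    }
    if (skipped > 0)
      warning(skipped, " of ", runs, " bootstrap replicates skipped (degenerate fit)",
              call. = FALSE)
    draws <- draws[stats::complete.cases(draws), , drop = FALSE]
    if (!nrow(draws)) stop("all bootstrap replicates failed", call. = FALSE)
    a <- (1 - level) / 2
    ci <- t(apply(draws, 2, stats::quantile, probs = c(a, 1 - a)))
    colnames(ci) <- c("lower", "upper")
    structure(list(draws = draws, mean = colMeans(draws),
                   median = apply(draws, 2, stats::median),
                   ci = ci, level = level,
                   runs_effective = nrow(draws), runs_skipped = skipped,
                   family = family),
              class = "rss_boot")
  })
}

#' @export
print.rss_boot <- function(x, ...) {
  cat(sprintf("<rss_boot: %s sums model, %d effective replicates (%d skipped)>\n",
              x$family, x$runs_effective, x$runs_skipped))
  tab <- data.frame(mean = x$mean, median = x$median,
                    lower = x$ci[, "lower"], upper = x$ci[, "upper"])
  print(tab, digits = 4)
  cat(sprintf("  percentile interval level: %g%%\n", 100 * x$level))
  invisible(x)
}
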