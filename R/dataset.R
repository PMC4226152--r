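# ---- long-format dataset container ------------------------------------------

#' Construct a randomly-stopped-sums dataset
#'
#' Wraps a long-format data frame (one row per magnitude observation) with the
#' column roles needed by the fitting machinery: a subject identifier, an
#' optional round identifier (three-level data), the positive magnitude, and
#' any predictor columns. Per-unit counts `n_j` and sums `S_j` are always
#' derived from the rows, never stored, so they cannot fall out of sync.
#'
#' @param df Data frame in long format.
#' @param subject Name of the subject identifier column.
#' @param round Optional name of the round identifier column.
#' @param magnitude Name of the magnitude column (strictly positive values).
#' @param predictors Character vector of predictor column names that are
#'   constant within subject (two-level) or within subject-round cell
#'   (three-level). Observation-level predictor columns need not be declared.
#' @param units Optional unit label for the magnitudes (metadata only).
#' @return An object of class `rss_data` (a data frame with role attributes).
#' @seealso [subject_table()], [read_rss_data()], [generate_fixture()]
#' @export
rss_data <- function(df, subject = "subject", round = NULL,
                     magnitude = "magnitude", predictors = NULL,
                     units = NULL) {
  df <- as.data.frame(df)
  needed <- c(subject, round, magnitude, predictors)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(needed))
    stop("duplicate column roles: ", paste(needed[duplicated(needed)], collapse = ", "),
         call. = FALSE)
  z <- df[[magnitude]]
  if (!is.numeric(z) || anyNA(z))
    stop("magnitude column must be numeric without NAs", call. = FALSE)
  bad <- which(z <= 0)
  if (length(bad))
    stop("non-positive magnitudes in rows: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  cell <- if (is.null(round)) df[[subject]] else
    interaction(df[[subject]], df[[round]], drop = TRUE)
  for (p in predictors) {
    nlev <- tapply(df[[p]], cell, function(v) length(unique(v)))
    if (any(nlev > 1))
      stop("predictor `", p, "` varies within its unit for: ",
           paste(utils::head(names(nlev)[nlev > 1], 5), collapse = ", "),
           call. = FALSE)
  }
  structure(df, class = c("rss_data", "data.frame"),
            subject_col = subject, round_col = round,
            magnitude_col = magnitude, predictor_cols = predictors,
            units = units)
}

rss_roles <- function(data) {
  list(subject = attr(data, "subject_col"), round = attr(data, "round_col"),
       magnitude = attr(data, "magnitude_col"),
       predictors = attr(data, "predictor_cols"), units = attr(data, "units"))
}

#' Per-unit summary of counts, sums, and means
#'
#' Aggregates an `rss_data` object to one row per subject (or subject-round
#' cell for three-level data) with the derived count `n`, sum `S`, mean
#' magnitude `mbar`, and the unit-level predictors.
#'
#' @param data An `rss_data` object.
#' @return Data frame with columns `subject` (, `round`), `n`, `S`, `mbar`,
#'   and the declared predictors.
#' @export
subject_table <- function(data) {
  if (!inherits(data, "rss_data")) stop("`data` must be an rss_data", call. = FALSE)
  r <- rss_roles(data)
  df <- as.data.frame(data)
  key <- if (is.null(r$round)) df[r$subject] else df[c(r$subject, r$round)]
  grp <- do.call(interaction, c(unname(key), drop = TRUE, lex.order = TRUE))
  idx <- !duplicated(grp)
  out <- key[idx, , drop = FALSE]
  names(out) <- c("subject", if (!is.null(r$round)) "round")
  ord <- grp[idx]
  out$n <- as.vector(table(grp)[as.character(ord)])
  out$S <- as.vector(rowsum(df[[r$magnitude]], grp)[as.character(ord), 1])
  out$mbar <- out$S / out$n
  for (p in r$predictors) out[[p]] <- df[[p]][idx]
  rownames(out) <- NULL
  out
}

#' @export
print.rss_data <- function(x, ...) {
  r <- rss_roles(x)
  st <- subject_table(x)
  cat(sprintf("<rss_data: %d observations, %d %s%s>\n", nrow(x), nrow(st),
              if (is.null(r$round)) "subjects" else "subject-round cells",
              if (is.null(r$units)) "" else paste0("; magnitudes in ", r$units)))
  cat(sprintf("  counts n: mean %.3g, var %.3g; sums S: mean %.4g, sd %.4g\n",
              mean(st$n), stats::var(st$n), mean(st$S), stats::sd(st$S)))
  if (length(r$predictors))
    cat("  predictors:", paste(r$predictors, collapse = ", "), "\n")
  invisible(x)
}

# ---- delimited I/O ----------------------------------------------------------

#' Read or write a long-format dataset as delimited text
#'
#' Comma-separated by default; a tab-separated file is detected from its
#' header line. Validation and role assignment are as in [rss_data()].
#'
#' @param path File path.
#' @inheritParams rss_data
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab.
#' @return An `rss_data` object.
#' @export
read_rss_data <- function(path, subject = "subject", round = NULL,
                          magnitude = "magnitude", predictors = NULL,
                          units = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  rss_data(df, subject = subject, round = round, magnitude = magnitude,
           predictors = predictors, units = units)
}

#' @rdname read_rss_data
#' @param data An `rss_data` object (or plain data frame) to write.
#' @export
write_rss_data <- function(data, path, sep = ",") {
  utils::write.table(as.data.frame(data), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- synthetic fixture generation -------------------------------------------

#' Configuration for a synthetic hierarchical dataset
#'
#' Defines the generative model realized by [generate_fixture()]: counts are
#' gamma-mixed Poisson (marginally negative binomial at the baseline), and
#' magnitudes are gamma or log-normal with a log-link linear predictor. The
#' baseline frequency and magnitude specifications carry the intercepts and
#' dispersion: a negative binomial `freq` with mean `theta` and size `phi`
#' becomes the mixing layer `lambda ~ gamma(phi, phi / exp(eta))` with
#' baseline `eta = log(theta)`; a `mag_gamma(shape, scale)` baseline implies
#' the GG magnitude layer with shape `q_m = shape`, a `mag_lognormal` baseline
#' the LN layer. Non-intercept coefficients `alpha` (frequency) and `beta`
#' (magnitude) act on the log scale through the named predictor columns.
#'
#' @param J Number of subjects.
#' @param freq Baseline frequency spec (`negbin`, `poisson_gamma`, or
#'   `poisson`).
#' @param mag Baseline magnitude spec (`gamma` or `lognormal`).
#' @param levels 2 or 3.
#' @param rounds Number of rounds per subject (three-level only).
#' @param alpha Named numeric vector of frequency coefficients (log scale),
#'   excluding the intercept, which comes from `freq`.
#' @param beta Named numeric vector of magnitude coefficients (log scale).
#' @param beta0k Optional vector of per-round magnitude intercepts (log
#'   scale, length `rounds`); defaults to the baseline intercept in every
#'   round.
#' @param sigma_upsilon SD of the subject (or cell) location `mu` around its
#'   linear predictor; 0 gives a purely fixed-effects generator.
#' @param predictors Optional data frame of subject-level predictor columns
#'   (`J` rows). Any coefficient name without a supplied column gets a
#'   balanced binary 0/1 column.
#' @param round_predictors Optional data frame of round-level predictor
#'   columns (`rounds` rows), used by coefficients named after its columns.
#' @param seed Integer seed; fixtures regenerate identically from the same
#'   configuration and seed.
#' @return A `fixture_config` object.
#' @export
fixture_config <- function(J, freq = negbin_from_prob_scale(0.5, 10),
                           mag = mag_gamma(4, 250), levels = 2, rounds = NULL,
                           alpha = NULL, beta = NULL, beta0k = NULL,
                           sigma_upsilon = 0, predictors = NULL,
                           round_predictors = NULL, seed = NULL) {
  stopifnot(J >= 1, levels %in% c(2, 3))
  if (levels == 3 && (is.null(rounds) || rounds < 2))
    stop("three-level fixtures need `rounds` >= 2", call. = FALSE)
  if (!freq$family %in% c("negbin", "poisson_gamma", "poisson"))
    stop("`freq` must be a negbin, poisson_gamma, or poisson spec", call. = FALSE)
  if (!mag$family %in% c("gamma", "lognormal"))
    stop("`mag` must be a gamma or lognormal spec", call. = FALSE)
  structure(list(J = J, freq = freq, mag = mag, levels = levels,
                 rounds = rounds, alpha = alpha, beta = beta, beta0k = beta0k,
                 sigma_upsilon = sigma_upsilon, predictors = predictors,
                 round_predictors = round_predictors, seed = seed),
            class = "fixture_config")
}

fixture_truth <- function(config) {
  f <- config$freq$params
  m <- config$mag$params
  freq_part <- switch(config$freq$family,
    negbin = list(q = f$phi, eta0 = log(f$theta)),
    poisson_gamma = list(q = f$q, eta0 = log(f$eta)),
    poisson = list(q = Inf, eta0 = log(f$lambda)))
  mag_part <- if (config$mag$family == "gamma")
    list(family = "GG", q_m = m$shape, mu0 = log(m$shape * m$scale), sigma = NA_real_)
  else
    list(family = "LN", q_m = NA_real_, mu0 = m$meanlog, sigma = m$sdlog)
  c(freq_part, mag_part,
    list(alpha = config$alpha, beta = config$beta, beta0k = config$beta0k,
         sigma_upsilon = config$sigma_upsilon))
}

#' Generate a synthetic dataset from a fixture configuration
#'
#' Draws a long-format dataset from the hierarchical generative model in
#' [fixture_config()]. The generating parameter values are attached as
#' attribute `"truth"` for recovery tests. Subjects (cells) with a zero count
#' contribute no rows.
#'
#' @param config A `fixture_config`.
#' @return An `rss_data` object with a `"truth"` attribute.
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, generate_fixture_impl(config))
}

generate_fixture_impl <- function(config) {
  tr <- fixture_truth(config)
  J <- config$J
  three <- config$levels == 3
  K <- if (three) config$rounds else 1L

  # subject-level predictor columns
  subj_pred <- config$predictors
  want <- union(names(config$alpha), names(config$beta))
  rp_names <- names(config$round_predictors)
  want_subj <- setdiff(want, rp_names)
  if (is.null(subj_pred)) subj_pred <- data.frame(row.names = seq_len(J))
  for (nm in setdiff(want_subj, names(subj_pred)))
    subj_pred[[nm]] <- rep_len(c(0, 1), J)
  if (nrow(subj_pred) && nrow(subj_pred) != J)
    stop("`predictors` must have J rows", call. = FALSE)

  rnd_pred <- config$round_predictors
  if (three && is.null(rnd_pred)) rnd_pred <- data.frame(row.names = seq_len(K))

  # unit table: one row per subject (x round)
  units <- data.frame(subject = rep(seq_len(J), each = K))
  if (three) units$round <- rep(seq_len(K), times = J)
  for (nm in names(subj_pred)) units[[nm]] <- subj_pred[[nm]][units$subject]
  if (three) for (nm in names(rnd_pred)) units[[nm]] <- rnd_pred[[nm]][units$round]

  lincomb <- function(coefs) {
    lp <- numeric(nrow(units))
    for (nm in names(coefs)) {
      if (!nm %in% names(units))
        stop("no predictor column for coefficient `", nm, "`", call. = FALSE)
      lp <- lp + coefs[[nm]] * units[[nm]]
    }
    lp
  }

  eta <- exp(tr$eta0 + lincomb(config$alpha))
  lambda <- if (is.infinite(tr$q)) eta else
    stats::rgamma(nrow(units), shape = tr$q, rate = tr$q / eta)
  n <- stats::rpois(nrow(units), lambda)

  ups0 <- if (three) {
    b0k <- if (is.null(config$beta0k)) rep(tr$mu0, K) else config$beta0k
    b0k[units$round]
  } else rep(tr$mu0, nrow(units))
  ups <- ups0 + lincomb(config$beta)
  mu <- stats::rnorm(nrow(units), ups, config$sigma_upsilon)

  tot <- sum(n)
  z <- if (tr$family == "GG")
    stats::rgamma(tot, shape = tr$q_m, rate = tr$q_m / exp(rep.int(mu, n)))
  else
    stats::rlnorm(tot, rep.int(mu, n), tr$sigma)

  rowrep <- rep.int(seq_len(nrow(units)), n)
  df <- units[rowrep, , drop = FALSE]
  df$magnitude <- z
  rownames(df) <- NULL
  preds <- setdiff(names(units), c("subject", "round"))
  out <- rss_data(df, subject = "subject",
                  round = if (three) "round" else NULL,
                  magnitude = "magnitude",
                  predictors = if (length(preds)) preds else NULL)
  attr(out, "truth") <- tr
  attr(out, "config") <- config
  out
}
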