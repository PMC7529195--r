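# Combining per-cohort heterogeneity results across studies.

#' Fisher's method for combining one-sided p-values
#'
#' \eqn{\chi^2 = -2\sum_i \log p_i} on \eqn{2K} degrees of freedom.
#' Underflowing p-values of 0 are clamped at 1e-300 with a warning.
#'
#' @param p Vector of per-cohort one-sided p-values in (0, 1].
#' @return List with `chisq`, `df`, and the combined `p_value`.
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped at 1e-300", call. = FALSE)
    p[p == 0] <- 1e-300
  }
  chisq <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Sample-size-weighted meta-analysis Z score
#'
#' Per-cohort signed z-scores \eqn{Z_i = sign(z_i)\Phi^{-1}(1 - p_i)} are
#' combined as \eqn{Z = \sum_i Z_i n_i / \sqrt{\sum_i n_i^2}} with the
#' one-sided upper-tail p-value. With z-scores supplied directly (the
#' default when `p` is omitted), \eqn{Z_i = z_i}.
#'
#' @param z Per-cohort heterogeneity z-scores (score minus expected null).
#' @param n Per-cohort sample sizes (> 0).
#' @param p Optional per-cohort one-sided p-values; when given, each
#'   \eqn{Z_i} is reconstructed from `p` with the sign of `z`.
#' @return List with the combined `z` and one-sided `p_value`.
#' @export
meta_z <- function(z, n, p = NULL) {
  stopifnot(length(z) >= 1, length(n) == length(z), all(n > 0))
  zi <- if (is.null(p)) z else sign(z) * stats::qnorm(1 - p)
  Z <- sum(zi * n) / sqrt(sum(n^2))
  list(z = Z, p_value = stats::pnorm(Z, lower.tail = FALSE))
}

#' Sum-of-scores heterogeneity test across cohorts
#'
#' Each cohort score has unit variance under its null, so the centred sum
#' \eqn{\sum_i (S_i - E_i)} has standard deviation \eqn{\sqrt{K}}; the
#' scaled sum is tested one-sided against N(0, 1).
#'
#' @param scores Per-cohort observed scores.
#' @param expected_nulls Per-cohort expected null scores.
#' @return List with the combined `z` and one-sided `p_value`.
#' @export
sum_scores <- function(scores, expected_nulls) {
  stopifnot(length(scores) >= 1, length(expected_nulls) == length(scores))
  z <- sum(scores - expected_nulls) / sqrt(length(scores))
  list(z = z, p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up procedure with per-rank critical values
#'
#' Sorted p-values \eqn{p_{(k)}} are compared with \eqn{(k/m)\,q}; the
#' step-up rule declares discoveries for every test at or below the largest
#' rank whose p-value passes its critical value. Unlike [stats::p.adjust()],
#' the per-rank critical values are returned alongside the flags, as
#' reported in study tables.
#'
#' @param p Vector of p-values.
#' @param q Target false-discovery rate in (0, 1).
#' @return A `data.frame` in the input order with `p`, `rank`,
#'   `critical_value` and logical `discovery`.
#' @export
benjamini_hochberg <- function(p, q) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1), q > 0, q < 1)
  m <- length(p)
  ord <- order(p)
  rk <- integer(m); rk[ord] <- seq_len(m)
  crit <- rk / m * q
  pass <- sort(p) <= seq_len(m) / m * q
  kmax <- if (any(pass)) max(which(pass)) else 0L
  data.frame(p = p, rank = rk, critical_value = crit,
             discovery = rk <= kmax)
}
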