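# The CLiP heterogeneity statistic for case/control genotype cohorts:
# SNP weights, the score, and the exact liability-threshold null computed by
# enumeration over genotype values.

#' Per-SNP summary statistics for heterogeneity scoring
#'
#' Assembles the per-SNP inputs of the test: effect-allele frequency, odds
#' ratio and liability-scale effect. Exactly one of `or` / `beta` may be
#' omitted; the missing one is derived through the odds-ratio/liability
#' conversion at the given prevalence. Alleles are oriented at construction
#' so every odds ratio is >= 1 (equivalently the liability effect is
#' non-negative): a SNP with `or < 1` has its counted allele flipped, i.e.
#' `or <- 1/or`, `af <- 1 - af`, and the liability effect re-derived from
#' the flipped odds ratio.
#'
#' @param snp_id Character SNP identifiers (unique).
#' @param af Effect-allele frequencies in (0, 1).
#' @param or Odds ratios (> 0), optional if `beta` is given.
#' @param beta Liability-scale effects, optional if `or` is given.
#' @param prevalence Disease prevalence used for the conversion.
#' @return A `data.frame` of class `summary_stats` with columns `snp_id`,
#'   `af`, `or`, `beta` and a logical `flipped`.
#' @export
summary_stats <- function(snp_id, af, or = NULL, beta = NULL, prevalence) {
  V <- check_probability(prevalence, "prevalence")
  af <- check_probability(af, "af")
  m <- length(af)
  snp_id <- as.character(snp_id)
  stopifnot(length(snp_id) == m, !anyDuplicated(snp_id))
  if (is.null(or) && is.null(beta))
    stop("supply at least one of `or` and `beta`", call. = FALSE)
  if (is.null(or)) or <- liability_to_or(beta, V)
  if (any(!is.finite(or)) || any(or <= 0))
    stop("odds ratios must be finite and positive", call. = FALSE)
  flip <- or < 1
  or[flip] <- 1 / or[flip]
  af[flip] <- 1 - af[flip]
  beta <- or_to_liability(or, V)
  out <- data.frame(snp_id = snp_id, af = af, or = or, beta = beta,
                    flipped = flip, stringsAsFactors = FALSE)
  attr(out, "prevalence") <- V
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' SNP weight from allele frequency and odds ratio
#'
#' The per-SNP weight of the heterogeneity score,
#' \deqn{w_j = \frac{p_j (1 - p_j)(\gamma_j - 1)}{(\gamma_j - 1) p_j + 1},}
#' largest for strong odds ratios at allele frequencies near 0.5. With
#' oriented alleles (\eqn{\gamma_j \ge 1}) the weight is non-negative.
#'
#' @param p Effect-allele frequency in (0, 1).
#' @param gamma Odds ratio (> 0).
#' @return Weight(s) \eqn{w_j}.
#' @export
snp_weight <- function(p, gamma) {
  check_probability(p, "p")
  if (any(gamma <= 0)) stop("odds ratios must be positive", call. = FALSE)
  den <- (gamma - 1) * p + 1
  if (any(den <= 0))
    stop("weight denominator (gamma - 1) p + 1 must be positive",
         call. = FALSE)
  p * (1 - p) * (gamma - 1) / den
}

# Case-conditional probability given one SNP (or a pair): the remaining PRS
# is absorbed into the normal residual, so the conditioning variance is
# 1 minus the variance contributed by the conditioned SNP(s) only.
.p_case_given <- function(x_centred_beta, cond_var, threshold) {
  stats::pnorm((x_centred_beta - threshold) / sqrt(1 - cond_var))
}

#' Expected case correlation of a SNP pair under homogeneous ascertainment
#'
#' Computes the exact expected Pearson correlation between two independent
#' SNPs among cases ascertained by the liability threshold model, by
#' enumerating genotype values in \{0, 1, 2\} and applying Bayes' theorem:
#' marginal moments use \eqn{P(X_j) P(Y=1|X_j)}, the cross moment uses the
#' independence prior \eqn{P(X_j)P(X_k)} with \eqn{P(Y=1|X_j,X_k)}. The
#' case probability conditions on the named SNP(s) only, with the rest of
#' the PRS absorbed into the normal residual. Both effects positive yields a
#' negative expected correlation — the ascertainment-induced anti-correlation
#' the statistic corrects for.
#'
#' @param beta_j,beta_k Liability-scale effects of the two SNPs.
#' @param p_j,p_k Effect-allele frequencies.
#' @param prevalence Disease prevalence.
#' @return The expected case correlation (scalar).
#' @export
expected_case_correlation <- function(beta_j, beta_k, p_j, p_k, prevalence) {
  mom <- .pair_case_moments(beta_j, beta_k, p_j, p_k,
                            check_probability(prevalence, "prevalence"))
  var_j <- mom$ex2_j - mom$ex_j^2
  var_k <- mom$ex2_k - mom$ex_k^2
  if (var_j <= 0 || var_k <= 0)
    stop("conditional variance is not positive", call. = FALSE)
  (mom$exjk - mom$ex_j * mom$ex_k) / sqrt(var_j * var_k)
}

# Enumerated case-conditional moments for one SNP pair.
.pair_case_moments <- function(beta_j, beta_k, p_j, p_k, V) {
  thr <- stats::qnorm(1 - V)
  g <- 0:2
  marg <- function(beta, p) {
    pri <- stats::dbinom(g, 2L, p)
    lik <- .p_case_given((g - 2 * p) * beta, beta^2 * 2 * p * (1 - p), thr)
    w <- pri * lik; w <- w / sum(w)
    list(ex = sum(g * w), ex2 = sum(g^2 * w))
  }
  mj <- marg(beta_j, p_j); mk <- marg(beta_k, p_k)
  gg <- expand.grid(xj = g, xk = g)
  pri <- stats::dbinom(gg$xj, 2L, p_j) * stats::dbinom(gg$xk, 2L, p_k)
  cond_var <- beta_j^2 * 2 * p_j * (1 - p_j) + beta_k^2 * 2 * p_k * (1 - p_k)
  if (cond_var >= 1)
    stop("the two SNPs jointly explain the whole liability variance",
         call. = FALSE)
  lik <- .p_case_given((gg$xj - 2 * p_j) * beta_j +
                         (gg$xk - 2 * p_k) * beta_k, cond_var, thr)
  w <- pri * lik; w <- w / sum(w)
  list(ex_j = mj$ex, ex2_j = mj$ex2, ex_k = mk$ex, ex2_k = mk$ex2,
       exjk = sum(gg$xj * gg$xk * w))
}

# Full M x M expected case-correlation matrix, de-duplicating identical
# (beta, p) parameter pairs so constant-architecture specs enumerate once.
expected_case_correlation_matrix <- function(stats_df, prevalence) {
  beta <- stats_df$beta; p <- stats_df$af; m <- length(beta)
  key <- paste(signif(beta, 12), signif(p, 12))
  uk <- unique(key); ki <- match(key, uk)
  R <- matrix(0, m, m)
  cache <- new.env(parent = emptyenv())
  for (j in seq_len(m - 1L)) for (k in (j + 1L):m) {
    ck <- paste(min(ki[j], ki[k]), max(ki[j], ki[k]))
    val <- cache[[ck]]
    if (is.null(val)) {
      val <- if (beta[j] == 0 || beta[k] == 0) 0 else
        expected_case_correlation(beta[j], beta[k], p[j], p[k], prevalence)
      cache[[ck]] <- val
    }
    R[j, k] <- R[k, j] <- val
  }
  diag(R) <- 1
  R
}

# Shared normalisation of the pairwise weighted sums.
.clip_denominator <- function(w, n_cases, n_controls) {
  w2 <- outer(w^2, w^2)
  sqrt((n_cases + n_controls) / (n_cases * n_controls) * upper_sum(w2))
}

#' Expected heterogeneity score of a homogeneous liability cohort
#'
#' The deterministic null of the test: pairwise expected case correlations
#' (see [expected_case_correlation()]) are plugged into the weighted
#' upper-triangle sum and scaled by the same sample-size normalisation as
#' the observed score. The value is negative whenever effects share a sign,
#' and grows in magnitude with sample size and variance explained.
#'
#' @param stats A [summary_stats()] table.
#' @param n_cases,n_controls Sample sizes entering the normalisation.
#' @param prevalence Disease prevalence; defaults to the one stored in
#'   `stats`.
#' @return The expected null score (scalar).
#' @export
expected_homogeneous_score <- function(stats, n_cases, n_controls,
                                       prevalence = attr(stats, "prevalence")) {
  stopifnot(inherits(stats, "summary_stats"))
  V <- check_probability(prevalence, "prevalence")
  ER <- expected_case_correlation_matrix(stats, V)
  w <- snp_weight(stats$af, stats$or)
  WW <- outer(w, w)
  upper_sum(WW * ER) / .clip_denominator(w, n_cases, n_controls)
}

#' CLiP heterogeneity score for a case/control genotype cohort
#'
#' Computes the weighted sum of case-minus-control SNP correlation
#' differences
#' \deqn{S = \frac{\sum_{j<k} w_j w_k (R_{jk} - R^0_{jk})}
#'   {\sqrt{\tfrac{N + N^0}{N N^0} \sum_{j<k} w_j^2 w_k^2}},}
#' which is asymptotically standard normal for independent SNPs sampled
#' identically in cases and controls. With `null = "liability"` the score is
#' tested against the expected score of a homogeneous liability-ascertained
#' cohort ([expected_homogeneous_score()]); with `null = "zero"` it is
#' tested against 0, the behaviour of the earlier BUHMBOX statistic. Either
#' way the reported z is `score - expected_null` and the p-value is the
#' one-sided upper tail: heterogeneity inflates the score upward only.
#'
#' SNPs are assumed approximately mutually uncorrelated among controls
#' (pruned of LD); a SNP with zero variance in either matrix is an error
#' naming the SNP, mirroring the exclusions such data require upstream.
#'
#' @param cases,controls Integer dosage matrices (individuals x SNPs) with
#'   matching columns in the order of `stats`.
#' @param stats A [summary_stats()] table with one row per column.
#' @param null `"liability"` (default) or `"zero"`.
#' @param prevalence Prevalence for the liability null; defaults to the one
#'   stored in `stats`.
#' @return A `clip_het` object: list with `score`, `expected_null`, `z`,
#'   `p_value`, the weight vector, both correlation matrices, and sample
#'   sizes.
#' @examples
#' V <- 0.01
#' mod <- disease_model("liability", V, rep(0.2, 20),
#'                      liability_effects = rep(beta_for_ve(0.03,
#'                                                          rep(0.2, 20)), 20))
#' st <- summary_stats(paste0("rs", 1:20), rep(0.2, 20),
#'                     beta = mod$liability_effects, prevalence = V)
#' coh <- make_misclassified_cohort(mod, 2000, 2000, 0.5, seed = 1)
#' clip_score(coh$cases, coh$controls, st)
#' @export
clip_score <- function(cases, controls, stats,
                       null = c("liability", "zero"),
                       prevalence = attr(stats, "prevalence")) {
  null <- match.arg(null)
  stopifnot(inherits(stats, "summary_stats"),
            is.matrix(cases), is.matrix(controls),
            ncol(cases) == nrow(stats), ncol(controls) == nrow(stats),
            nrow(cases) > 1, nrow(controls) > 1)
  for (side in c("cases", "controls")) {
    x <- if (side == "cases") cases else controls
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("SNP(s) with zero variance in ", side, ": ",
           paste(stats$snp_id[sds == 0], collapse = ", "), call. = FALSE)
  }
  N <- nrow(cases); N0 <- nrow(controls)
  R <- stats::cor(cases)
  R0 <- stats::cor(controls)
  w <- snp_weight(stats$af, stats$or)
  WW <- outer(w, w)
  den <- .clip_denominator(w, N, N0)
  score <- upper_sum(WW * (R - R0)) / den
  expected_null <- if (null == "liability") {
    V <- check_probability(prevalence, "prevalence")
    upper_sum(WW * expected_case_correlation_matrix(stats, V)) / den
  } else 0
  new_clip_het(score, expected_null,
               method = paste0("CLiP (", null, " null)"),
               weights = w, case_corr = R, control_corr = R0,
               n_cases = N, n_controls = N0, m = nrow(stats))
}

# Common result container for all score variants.
new_clip_het <- function(score, expected_null, method, weights = NULL,
                         case_corr = NULL, control_corr = NULL,
                         n_cases = NA, n_controls = NA, m = NA,
                         null_se = NULL) {
  z <- score - expected_null
  structure(list(score = score, expected_null = expected_null, z = z,
                 p_value = stats::pnorm(z, lower.tail = FALSE),
                 method = method, weights = weights, case_corr = case_corr,
                 control_corr = control_corr, n_cases = n_cases,
                 n_controls = n_controls, m_snps = m, null_se = null_se),
            class = "clip_het")
}

#' @export
print.clip_het <- function(x, digits = 4, ...) {
  cat(x$method, "heterogeneity test\n")
  cat("  SNPs/predictors:", x$m_snps, "  N:", x$n_cases,
      if (!is.na(x$n_controls)) paste0(" N0: ", x$n_controls), "\n")
  cat("  score:", signif(x$score, digits),
      "  expected null:", signif(x$expected_null, digits),
      if (!is.null(x$null_se)) paste0(" (MC se ", signif(x$null_se, 2), ")"),
      "\n")
  cat("  z:", signif(x$z, digits),
      "  one-sided p:", format.pval(x$p_value, digits = digits), "\n")
  invisible(x)
}
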