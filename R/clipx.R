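# CLiP-X: heterogeneity detection for continuous predictors (e.g. imputed
# expression), with mixture-derived pairwise weights and an analytic
# truncated-Gaussian null that accounts for predictor correlations shared
# between cases and controls.

#' Generative model for expression-mediated disease risk
#'
#' Predictors (genes) are linear functions of a shared set of binomial
#' SNPs plus normal noise; each gene has unit variance with a fraction
#' `vg2` explained by the SNPs, so genes are correlated among controls
#' through the shared SNP layer. A hidden liability
#' \eqn{Y^* = Z^T\alpha + \epsilon} with
#' \eqn{Var(\epsilon) = (1 - V_E^2)/V_E^2 \cdot Var(Z^T\alpha)} has unit
#' variance; individuals with \eqn{Y^* \ge T = \Phi^{-1}(1 - V)} are cases.
#'
#' By default SNP-gene effects are constant (every gene loads equally on
#' every SNP) and gene-trait effects are constant; custom `snp_gene_effects`
#' (L x M) are rescaled row-wise so each gene's genetic variance is `vg2`,
#' and custom `gene_trait_effects` are rescaled so
#' \eqn{Var(Z^T\alpha) = V_E^2}.
#'
#' @param n_snps Number of SNPs M.
#' @param n_genes Number of genes L.
#' @param vg2 Per-gene variance explained by SNPs, in (0, 1).
#' @param ve2 Liability variance explained by expression, in (0, 1).
#' @param prevalence Disease prevalence V.
#' @param allele_freqs SNP allele frequencies (scalar or length M).
#' @param snp_gene_effects Optional L x M SNP-gene effect matrix.
#' @param gene_trait_effects Optional length-L gene-trait effect vector.
#' @return An object of class `expression_model` carrying the resolved
#'   effect matrices, the prior gene covariance `sigma_z`, the gene-liability
#'   covariance `liab_cov`, and the threshold.
#' @export
expression_model <- function(n_snps, n_genes, vg2, ve2, prevalence,
                             allele_freqs = 0.5, snp_gene_effects = NULL,
                             gene_trait_effects = NULL) {
  check_probability(vg2, "vg2"); check_probability(ve2, "ve2")
  V <- check_probability(prevalence, "prevalence")
  p <- check_probability(rep_len(allele_freqs, n_snps), "allele_freqs")
  d <- 2 * p * (1 - p)
  B <- if (is.null(snp_gene_effects))
    matrix(sqrt(vg2 / sum(d)), n_genes, n_snps)
  else {
    stopifnot(dim(snp_gene_effects) == c(n_genes, n_snps))
    gvar <- drop(snp_gene_effects^2 %*% d)
    if (any(gvar == 0)) stop("a gene has no SNP effect", call. = FALSE)
    snp_gene_effects * sqrt(vg2 / gvar)
  }
  sigma_z <- B %*% (d * t(B)) + diag(1 - vg2, n_genes)
  alpha <- if (is.null(gene_trait_effects)) rep(1, n_genes)
           else rep_len(gene_trait_effects, n_genes)
  alpha <- alpha * sqrt(ve2 / drop(crossprod(alpha, sigma_z %*% alpha)))
  noise_var <- (1 - ve2) / ve2 * ve2    # Var(eps) so Var(Y*) = 1
  if (noise_var <= 0) stop("liability noise variance must be positive",
                           call. = FALSE)
  structure(list(n_snps = n_snps, n_genes = n_genes, vg2 = vg2, ve2 = ve2,
                 prevalence = V, allele_freqs = p,
                 snp_gene_effects = B, gene_trait_effects = alpha,
                 sigma_z = sigma_z,
                 liab_cov = drop(sigma_z %*% alpha),
                 eps_sd = sqrt(noise_var),
                 threshold = stats::qnorm(1 - V)),
            class = "expression_model")
}

#' Simulate case and control expression matrices
#'
#' Draws batches of SNPs and derived gene expression under an
#' [expression_model()], thresholds the hidden liability, and accumulates
#' threshold-passers as cases and threshold-failers as controls until both
#' cohorts are filled.
#'
#' @param spec An [expression_model()].
#' @param n_cases,n_controls Cohort sizes.
#' @param seed Optional integer seed.
#' @return An `expression_cohort`: list with numeric matrices `cases` and
#'   `controls` (individuals x genes) and the generating `spec`.
#' @export
simulate_expression_cohort <- function(spec, n_cases, n_controls,
                                       seed = NULL) {
  stopifnot(inherits(spec, "expression_model"), n_cases > 0, n_controls > 0)
  with_seed_if(seed, {
    L <- spec$n_genes
    got_ca <- 0L; got_co <- 0L
    acc_ca <- list(); acc_co <- list()
    batch <- as.integer(min(5e5, max(1e4, ceiling(2 * n_cases /
                                                    spec$prevalence))))
    # With a constant allele frequency and per-gene-constant SNP loadings,
    # genotypes enter every gene only through the total allele count, which
    # can be drawn directly as one binomial per individual.
    row_const <- apply(spec$snp_gene_effects, 1L,
                       function(r) length(unique(r)) == 1L)
    rank1 <- all(row_const) &&
      length(unique(spec$allele_freqs)) == 1L
    while (got_ca < n_cases || got_co < n_controls) {
      genetic <- if (rank1) {
        k <- stats::rbinom(batch, 2L * spec$n_snps, spec$allele_freqs[1L])
        outer(k - sum(2 * spec$allele_freqs), spec$snp_gene_effects[, 1L])
      } else {
        g <- sim_genotypes(batch, spec$allele_freqs)
        sweep(g, 2L, 2 * spec$allele_freqs) %*% t(spec$snp_gene_effects)
      }
      z <- genetic +
        matrix(stats::rnorm(batch * L, sd = sqrt(1 - spec$vg2)), batch, L)
      ystar <- drop(z %*% spec$gene_trait_effects) +
        stats::rnorm(batch, sd = spec$eps_sd)
      pass <- ystar >= spec$threshold
      if (got_ca < n_cases && any(pass))
        { acc_ca[[length(acc_ca) + 1L]] <- z[pass, , drop = FALSE]
          got_ca <- got_ca + sum(pass) }
      if (got_co < n_controls && any(!pass))
        { acc_co[[length(acc_co) + 1L]] <- z[!pass, , drop = FALSE]
          got_co <- got_co + sum(!pass) }
    }
    structure(list(cases = do.call(rbind, acc_ca)[seq_len(n_cases), ,
                                                  drop = FALSE],
                   controls = do.call(rbind, acc_co)[seq_len(n_controls), ,
                                                     drop = FALSE],
                   spec = spec, seed = seed),
              class = "expression_cohort")
  })
}

#' Expected whole-cohort correlation of a two-subgroup mixture
#'
#' Evaluates the expected Pearson correlation between two predictors over a
#' cohort mixing a control-like subgroup (proportion `pi`, moments
#' `mu_minus`, `sigma_minus`) with a case-like subgroup (moments `mu_plus`,
#' `sigma_plus`), writing every whole-cohort expectation as the mixture
#' combination \eqn{A_\pi(x, y) = \pi x + (1 - \pi) y} of subgroup
#' expectations. Within-subgroup cross moments default to the product of
#' means (uncorrelated within subgroup).
#'
#' @param pi Mixture proportion of the control-like subgroup, in [0, 1].
#' @param mu_minus,mu_plus Length-2 subgroup means of predictors (j, k).
#' @param sigma_minus,sigma_plus Length-2 subgroup standard deviations.
#' @param cross_minus,cross_plus Optional within-subgroup cross moments
#'   \eqn{E[Z_j Z_k]}.
#' @return The expected whole-cohort correlation (scalar).
#' @export
mixture_correlation <- function(pi, mu_minus, mu_plus, sigma_minus,
                                sigma_plus, cross_minus = NULL,
                                cross_plus = NULL) {
  stopifnot(pi >= 0, pi <= 1, length(mu_minus) == 2, length(mu_plus) == 2)
  if (any(c(sigma_minus, sigma_plus) <= 0))
    stop("subgroup standard deviations must be positive", call. = FALSE)
  if (is.null(cross_minus)) cross_minus <- prod(mu_minus)
  if (is.null(cross_plus)) cross_plus <- prod(mu_plus)
  A <- function(x, y) pi * x + (1 - pi) * y
  exy <- A(cross_minus, cross_plus)
  ex <- A(mu_minus[1L], mu_plus[1L]); ey <- A(mu_minus[2L], mu_plus[2L])
  vx <- A(sigma_minus[1L]^2 + mu_minus[1L]^2,
          sigma_plus[1L]^2 + mu_plus[1L]^2) - ex^2
  vy <- A(sigma_minus[2L]^2 + mu_minus[2L]^2,
          sigma_plus[2L]^2 + mu_plus[2L]^2) - ey^2
  if (vx <= 0 || vy <= 0) stop("degenerate mixture variance", call. = FALSE)
  (exy - ex * ey) / sqrt(vx * vy)
}

#' Pairwise weights for continuous predictors
#'
#' The pairwise weight of predictor pair (j, k) is
#' \eqn{w_{jk} = (\mu^+_j - \mu^-_j)(\mu^+_k - \mu^-_k) /
#' (\sigma^-_j \sigma^-_k)}. When the case-subgroup means \eqn{\mu^+} are
#' unknown, passing the whole-cohort means instead yields the approximate
#' weights \eqn{\hat w_{jk}}, uniformly rescaled by \eqn{\pi^2}; the score
#' is invariant to that rescaling.
#'
#' @param mu Per-predictor case-subgroup means (exact weights) or
#'   whole-cohort means (approximate weights).
#' @param mu_ref Reference (control-subgroup) means.
#' @param sd_ref Reference standard deviations (> 0).
#' @return The symmetric matrix of pairwise weights.
#' @export
continuous_weights <- function(mu, mu_ref, sd_ref) {
  if (any(sd_ref <= 0)) stop("reference sds must be positive", call. = FALSE)
  d <- (mu - mu_ref) / sd_ref
  outer(d, d)
}

#' Expected gene-gene correlations under liability ascertainment
#'
#' Closed-form correlation matrices of jointly Gaussian predictors
#' conditioned on the liability \eqn{Y^* = Z^T\alpha + \epsilon} falling in
#' the case (upper) or control (lower) tail of the threshold. Writing
#' \eqn{c = Cov(Z, Y^*)} and the truncated-liability variance deficit
#' \eqn{\delta = \lambda(\lambda - T)} (Mills-ratio mean \eqn{\lambda} of
#' the truncated standard normal), the conditional covariance is
#' \eqn{\Sigma - \delta\, c c^T}. With `side = "population"` the prior
#' (unascertained) correlations from shared SNP effects are returned.
#'
#' @param spec An [expression_model()].
#' @param side `"case"`, `"control"`, or `"population"`.
#' @return An L x L correlation matrix.
#' @export
expected_expression_correlation <- function(spec,
                                            side = c("case", "control",
                                                     "population")) {
  stopifnot(inherits(spec, "expression_model"))
  side <- match.arg(side)
  stats::cov2cor(.trunc_gene_cov(spec, side))
}

# Truncated-liability mean multiplier (lambda) and variance deficit (delta).
.trunc_liab_moments <- function(threshold, side) {
  V <- stats::pnorm(threshold, lower.tail = FALSE)
  lambda <- switch(side,
                   case = stats::dnorm(threshold) / V,
                   control = -stats::dnorm(threshold) / (1 - V),
                   population = 0)
  list(lambda = lambda, delta = lambda * (lambda - threshold))
}

.trunc_gene_cov <- function(spec, side) {
  tm <- .trunc_liab_moments(spec$threshold, side)
  spec$sigma_z - tm$delta * tcrossprod(spec$liab_cov)
}

# Conditional gene means under ascertainment (prior means are 0).
.trunc_gene_mean <- function(spec, side) {
  .trunc_liab_moments(spec$threshold, side)$lambda * spec$liab_cov
}

#' Expected CLiP-X score of a homogeneous expression cohort
#'
#' Assembles the analytic case-minus-control expected correlations and the
#' analytic pairwise weights (case/control subgroup moments from the
#' truncated-Gaussian conditioning) into the score normalisation, giving
#' the deterministic null value for a homogeneous cohort of the stated
#' sizes.
#'
#' @param spec An [expression_model()].
#' @param n_cases,n_controls Cohort sizes entering the normalisation.
#' @return Expected null score (scalar).
#' @export
expected_clipx_score <- function(spec, n_cases, n_controls) {
  stopifnot(inherits(spec, "expression_model"))
  mu_case <- .trunc_gene_mean(spec, "case")
  mu_ctrl <- .trunc_gene_mean(spec, "control")
  sd_ctrl <- sqrt(diag(.trunc_gene_cov(spec, "control")))
  W <- continuous_weights(mu_case, mu_ctrl, sd_ctrl)
  dR <- expected_expression_correlation(spec, "case") -
    expected_expression_correlation(spec, "control")
  den <- sqrt((n_cases + n_controls) / (n_cases * n_controls) *
                upper_sum(W^2))
  upper_sum(W * dR) / den
}

#' CLiP-X heterogeneity score for continuous predictors
#'
#' The continuous-predictor analogue of [clip_score()]: predictors are
#' standardised by control moments, pairwise weights are the approximate
#' mixture-derived weights \eqn{\hat w_{jk}} built from whole-case-cohort
#' means against control moments, and the weighted upper-triangle sum of
#' case-minus-control correlation differences is normalised by
#' \eqn{\sqrt{(N + N^0)/(N N^0)\,\sum_{j<k} \hat w_{jk}^2}}. The null is
#' `"analytic"` (truncated-Gaussian expected correlations, requires
#' `spec`), `"mc"` (mean score of `n_null_reps` simulated homogeneous
#' cohorts, requires `spec`), or `"zero"`.
#'
#' @param cases,controls Numeric predictor matrices (individuals x
#'   predictors), matched columns.
#' @param null `"analytic"`, `"zero"`, or `"mc"`.
#' @param spec An [expression_model()] for the analytic or MC null.
#' @param n_null_reps Homogeneous replicate cohorts for the MC null.
#' @param seed Optional seed for the MC null.
#' @return A `clip_het` object.
#' @export
clipx_score <- function(cases, controls, null = c("analytic", "zero", "mc"),
                        spec = NULL, n_null_reps = 400, seed = NULL) {
  null <- match.arg(null)
  stopifnot(is.matrix(cases), is.matrix(controls),
            ncol(cases) == ncol(controls))
  if (ncol(cases) < 2) stop("at least two predictors are required",
                            call. = FALSE)
  if (null != "zero" && is.null(spec))
    stop("`spec` is required for the ", null, " null", call. = FALSE)
  N <- nrow(cases); N0 <- nrow(controls)
  mu0 <- colMeans(controls); sd0 <- apply(controls, 2L, stats::sd)
  if (any(sd0 == 0)) stop("a predictor has zero variance in controls",
                          call. = FALSE)
  mu_case_std <- (colMeans(cases) - mu0) / sd0
  W <- outer(mu_case_std, mu_case_std)
  R <- stats::cor(cases); R0 <- stats::cor(controls)
  den <- sqrt((N + N0) / (N * N0) * upper_sum(W^2))
  score <- upper_sum(W * (R - R0)) / den
  if (null == "analytic") {
    dR <- expected_expression_correlation(spec, "case") -
      expected_expression_correlation(spec, "control")
    expected_null <- upper_sum(W * dR) / den
    null_se <- NULL
  } else if (null == "mc") {
    reps <- with_seed_if(seed, vapply(seq_len(n_null_reps), function(i) {
      hom <- simulate_expression_cohort(spec, N, N0)
      clipx_score(hom$cases, hom$controls, null = "zero")$score
    }, numeric(1)))
    expected_null <- mean(reps)
    null_se <- stats::sd(reps) / sqrt(n_null_reps)
  } else {
    expected_null <- 0
    null_se <- NULL
  }
  new_clip_het(score, expected_null,
               method = paste0("CLiP-X (", null, " null)"),
               weights = W, case_corr = R, control_corr = R0,
               n_cases = N, n_controls = N0, m = ncol(cases),
               null_se = null_se)
}
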