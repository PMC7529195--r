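# CLiP-Y: heterogeneity detection for quantitative phenotypes through
# phenotype-weighted SNP correlations, a library of weight functions over
# phenotype percentiles, and a local-search learner for polynomial weights.

#' Generative model for a quantitative polygenic trait
#'
#' SNPs are binomial(2, p); for PRS-dependent ("homogeneous") individuals
#' the phenotype is \eqn{Y = (x - E[X])^T\beta + N(0, 1 - h^2)} with the
#' constant effect sized so the PRS explains `h2` of the unit phenotype
#' variance. A `mixture_fraction` of individuals instead receive
#' \eqn{Y \sim N(0, 1)} independent of genotype — the heterogeneous
#' contamination the test is designed to detect.
#'
#' @param n_snps Number of SNPs M.
#' @param h2 PRS variance explained of the trait, in (0, 1).
#' @param allele_freqs Allele frequencies (scalar or length M), default 0.5.
#' @param mixture_fraction Fraction of PRS-independent individuals, in
#'   [0, 1]; 0 is the homogeneous null.
#' @return An object of class `quant_model`.
#' @export
quant_model <- function(n_snps, h2, allele_freqs = 0.5,
                        mixture_fraction = 0) {
  check_probability(h2, "h2")
  stopifnot(mixture_fraction >= 0, mixture_fraction <= 1)
  p <- check_probability(rep_len(allele_freqs, n_snps), "allele_freqs")
  structure(list(n_snps = n_snps, h2 = h2, allele_freqs = p,
                 effects = rep(beta_for_ve(h2, p), n_snps),
                 mixture_fraction = mixture_fraction),
            class = "quant_model")
}

#' Simulate a quantitative-phenotype cohort
#'
#' @param spec A [quant_model()].
#' @param n_individuals Cohort size.
#' @param seed Optional integer seed.
#' @return A `quant_cohort`: list with `genotypes` (N x M), `phenotype`
#'   (length N), logical `truth$prs_dependent`, and `spec`.
#' @export
simulate_quantitative_cohort <- function(spec, n_individuals, seed = NULL) {
  stopifnot(inherits(spec, "quant_model"), n_individuals > 0)
  with_seed_if(seed, {
    x <- sim_genotypes(n_individuals, spec$allele_freqs)
    n_mix <- round(spec$mixture_fraction * n_individuals)
    prs_dep <- rep(c(FALSE, TRUE), c(n_mix, n_individuals - n_mix))
    y <- numeric(n_individuals)
    y[!prs_dep] <- stats::rnorm(n_mix)
    if (any(prs_dep)) {
      prs <- drop(sweep(x[prs_dep, , drop = FALSE], 2L,
                        2 * spec$allele_freqs) %*% spec$effects)
      y[prs_dep] <- prs + stats::rnorm(sum(prs_dep),
                                       sd = sqrt(1 - spec$h2))
    }
    structure(list(genotypes = x, phenotype = y,
                   truth = data.frame(prs_dependent = prs_dep),
                   spec = spec, seed = seed),
              class = "quant_cohort")
  })
}

#' Empirical mid-rank percentiles of a phenotype vector
#'
#' Maps phenotypes to \eqn{(rank - 0.5)/N} with ties sharing their
#' mid-rank, so the result is invariant under monotone transforms of the
#' phenotype and confined to (0, 1).
#'
#' @param y Numeric phenotype vector (finite values).
#' @return Percentiles in (0, 1).
#' @export
phenotype_to_percentiles <- function(y) {
  if (any(!is.finite(y))) stop("phenotypes must be finite", call. = FALSE)
  (rank(y, ties.method = "average") - 0.5) / length(y)
}

#' Weight functions over phenotype percentiles
#'
#' Constructs one of the individual-weight functions F evaluated on
#' phenotype percentiles in [0, 1]: `"uniform"` (F = 1), `"step"`
#' (indicator above `threshold`, the pseudo-case/control split),
#' `"sigmoid"` (logistic ramp of steepness `scale` centred at
#' `threshold`), `"linear"` (F = x), `"neglog1m"` (F = -log(1 - x)), or
#' `"polynomial"` with the given coefficients (constant term first).
#' Negative function values are floored at 0 when the weights are
#' normalised.
#'
#' @param kind Weight-function family.
#' @param threshold Percentile threshold/centre for step and sigmoid.
#' @param coefficients Polynomial coefficients, constant term first.
#' @param scale Sigmoid steepness on the percentile scale.
#' @return An object of class `clip_weight_fn`.
#' @seealso [clipy_default_polynomial()] for the shipped learned weights.
#' @export
weight_function <- function(kind = c("uniform", "step", "sigmoid", "linear",
                                     "neglog1m", "polynomial"),
                            threshold = 0.5, coefficients = NULL,
                            scale = 10) {
  kind <- match.arg(kind)
  if (kind == "polynomial") {
    if (is.null(coefficients) || length(coefficients) < 2)
      stop("polynomial weights need a coefficient vector", call. = FALSE)
    coefficients <- as.numeric(coefficients)
  }
  structure(list(kind = kind, threshold = threshold,
                 coefficients = coefficients, scale = scale),
            class = "clip_weight_fn")
}

#' @export
print.clip_weight_fn <- function(x, ...) {
  cat("Weight function:", x$kind)
  if (x$kind %in% c("step", "sigmoid")) cat(" (threshold", x$threshold, ")")
  if (x$kind == "polynomial")
    cat(" degree", length(x$coefficients) - 1L)
  cat("\n")
  invisible(x)
}

# Evaluate F on percentiles (no flooring/normalisation here).
wf_eval <- function(wf, x) {
  stopifnot(inherits(wf, "clip_weight_fn"))
  switch(wf$kind,
         uniform = rep(1, length(x)),
         step = as.numeric(x >= wf$threshold),
         sigmoid = stats::plogis((x - wf$threshold) * wf$scale),
         linear = x,
         neglog1m = -log1p(-pmin(x, 1 - 1e-12)),
         polynomial = drop(outer(x, seq_along(wf$coefficients) - 1L, `^`) %*%
                             wf$coefficients))
}

#' Normalised individual weights from a phenotype and a weight function
#'
#' Converts phenotypes to mid-rank percentiles, evaluates the weight
#' function, floors negative values at 0, and normalises to
#' \eqn{\sum_i \phi_i = 1}.
#'
#' @param y Phenotype vector.
#' @param wf A [weight_function()].
#' @return The weight vector \eqn{\phi} (non-negative, summing to 1).
#' @export
normalized_weights <- function(y, wf) {
  f <- pmax(wf_eval(wf, phenotype_to_percentiles(y)), 0)
  s <- sum(f)
  if (s <= 0) stop("all weight-function values are zero", call. = FALSE)
  f / s
}

#' Phenotype-weighted SNP correlation matrix
#'
#' Weighted moments \eqn{E[u_j] = \sum_i \phi_i x_{ij}} and covariance
#' \eqn{\sum_i \phi_i (x_{ij} - E[u_j])(x_{ik} - E[u_k])} define the
#' weighted correlation matrix \eqn{R^\phi}; uniform \eqn{\phi} recovers the
#' ordinary Pearson matrix, and a dichotomous \eqn{\phi} recovers the
#' Pearson matrix of the selected subset.
#'
#' @param x Genotype matrix (individuals x SNPs).
#' @param phi Normalised weight vector (length `nrow(x)`).
#' @return List with `corr` (\eqn{R^\phi}), `means`, `vars` (weighted
#'   moments) and `scale` \eqn{s = \sum_i \phi_i^2 - 1/N}.
#' @export
weighted_correlation <- function(x, phi) {
  stopifnot(is.matrix(x), length(phi) == nrow(x),
            abs(sum(phi) - 1) < 1e-8, all(phi >= 0))
  u <- drop(crossprod(x, phi))
  xc <- sweep(x, 2L, u)
  cov <- crossprod(xc, phi * xc)
  v <- diag(cov)
  if (any(v <= 0))
    stop("SNP(s) with zero weighted variance: ",
         paste(which(v <= 0), collapse = ", "), call. = FALSE)
  list(corr = cov / sqrt(outer(v, v)), means = u, vars = v,
       scale = sum(phi^2) - 1 / nrow(x))
}

#' Per-SNP weights for the quantitative-phenotype score
#'
#' The weighted allele frequency \eqn{p^\phi_j = E[u^\phi_j]/2} and the
#' uniform frequency \eqn{p^0_j} define a weighted generalisation of an
#' odds ratio
#' \eqn{\gamma^\phi_j = \frac{p^\phi_j(1 - p^\phi_j)}{p^0_j(1 - p^0_j)}},
#' from which the SNP weight follows the case/control form
#' \eqn{w^\phi_j = p^0_j(1 - p^0_j)(\gamma^\phi_j - 1) /
#' ((\gamma^\phi_j - 1) p^0_j + 1)}. A dichotomous \eqn{\phi} reproduces
#' the case/control weights computed from pseudo-case and whole-cohort
#' allele frequencies.
#'
#' @inheritParams weighted_correlation
#' @return Per-SNP weight vector \eqn{w^\phi}.
#' @export
clipy_snp_weights <- function(x, phi) {
  p_phi <- drop(crossprod(x, phi)) / 2
  p0 <- colMeans(x) / 2
  bad <- p_phi <= 0 | p_phi >= 1 | p0 <= 0 | p0 >= 1
  if (any(bad))
    stop("allele frequency at the boundary for SNP(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  gamma <- (p_phi * (1 - p_phi)) / (p0 * (1 - p0))
  p0 * (1 - p0) * (gamma - 1) / ((gamma - 1) * p0 + 1)
}

#' CLiP-Y heterogeneity score for a quantitative phenotype
#'
#' Contrasts the phenotype-weighted SNP correlations against the uniform
#' correlations over the same individuals:
#' \deqn{S = \frac{\sum_{j<k} w^\phi_j w^\phi_k (R^\phi_{jk} - R^0_{jk})}
#'   {\sqrt{(\sum_i \phi_i^2 - 1/N)\,\sum_{j<k} (w^\phi_j)^2
#'    (w^\phi_k)^2}},}
#' approximately standard normal for genotype-independent phenotypes. The
#' supplied `null` (an expected homogeneous score, e.g. from
#' [estimate_clipy_null()]) is subtracted to form the one-sided z-test.
#'
#' @param x Genotype matrix (individuals x SNPs).
#' @param y Phenotype vector.
#' @param wf A [weight_function()]; must not be uniform (the scale factor
#'   degenerates).
#' @param null Expected homogeneous score (scalar, default 0).
#' @return A `clip_het` object.
#' @export
clipy_score <- function(x, y, wf, null = 0) {
  stopifnot(is.matrix(x), length(y) == nrow(x), is.numeric(null),
            length(null) == 1)
  phi <- normalized_weights(y, wf)
  wc <- weighted_correlation(x, phi)
  if (wc$scale <= 0)
    stop("the weight function is uniform over the cohort; ",
         "the CLiP-Y scale factor is undefined", call. = FALSE)
  r0 <- weighted_correlation(x, rep(1 / nrow(x), nrow(x)))
  w <- clipy_snp_weights(x, phi)
  WW <- outer(w, w)
  den <- sqrt(wc$scale * upper_sum(outer(w^2, w^2)))
  score <- upper_sum(WW * (wc$corr - r0$corr)) / den
  new_clip_het(score, null, method = paste0("CLiP-Y (", wf$kind, " weights)"),
               weights = w, case_corr = wc$corr, control_corr = r0$corr,
               n_cases = nrow(x), n_controls = NA, m = ncol(x))
}

#' Simulation-based expected CLiP-Y score for homogeneous cohorts
#'
#' Estimates the null score of a homogeneous (PRS-dependent, no mixture)
#' cohort by averaging CLiP-Y scores over `n_reps` simulated cohorts of the
#' stated size, the practical default when the analytic pairwise
#' expectation is too costly.
#'
#' @param spec A [quant_model()]; its `mixture_fraction` is ignored and
#'   treated as 0.
#' @param n_individuals Cohort size matching the data to be tested.
#' @param wf A [weight_function()].
#' @param n_reps Number of replicate cohorts (default 400).
#' @param seed Optional integer seed.
#' @return List with `expected` (mean score), `se` (Monte-Carlo standard
#'   error), and the replicate `scores`.
#' @export
estimate_clipy_null <- function(spec, n_individuals, wf, n_reps = 400,
                                seed = NULL) {
  stopifnot(inherits(spec, "quant_model"))
  hom <- quant_model(spec$n_snps, spec$h2, spec$allele_freqs,
                     mixture_fraction = 0)
  scores <- with_seed_if(seed, vapply(seq_len(n_reps), function(i) {
    coh <- simulate_quantitative_cohort(hom, n_individuals)
    clipy_score(coh$genotypes, coh$phenotype, wf)$score
  }, numeric(1)))
  list(expected = mean(scores), se = stats::sd(scores) / sqrt(n_reps),
       scores = scores)
}

# Precomputed per-cohort structures for repeated CLiP-Y scoring of the same
# cohort under many weight functions: percentiles, the uniform correlation
# matrix and uniform allele frequencies are phi-independent.
.clipy_precompute <- function(x, y) {
  n <- nrow(x)
  r0 <- weighted_correlation(x, rep(1 / n, n))
  list(x = x, pct = phenotype_to_percentiles(y), r0 = r0$corr,
       p0 = r0$means / 2, n = n)
}

.clipy_score_fast <- function(pre, wf) {
  f <- pmax(wf_eval(wf, pre$pct), 0)
  s <- sum(f)
  if (s <= 0) return(NA_real_)
  phi <- f / s
  scale <- sum(phi^2) - 1 / pre$n
  if (scale <= 0) return(NA_real_)
  u <- drop(crossprod(pre$x, phi))
  xc <- sweep(pre$x, 2L, u)
  cov <- crossprod(sqrt(phi) * xc)
  v <- diag(cov)
  if (any(v <= 0)) return(NA_real_)
  rphi <- cov / sqrt(outer(v, v))
  p_phi <- u / 2
  if (any(p_phi <= 0 | p_phi >= 1 | pre$p0 <= 0 | pre$p0 >= 1))
    return(NA_real_)
  gamma <- (p_phi * (1 - p_phi)) / (pre$p0 * (1 - pre$p0))
  w <- pre$p0 * (1 - pre$p0) * (gamma - 1) / ((gamma - 1) * pre$p0 + 1)
  upper_sum(outer(w, w) * (rphi - pre$r0)) /
    sqrt(scale * upper_sum(outer(w^2, w^2)))
}

#' Learn a polynomial weight function by local search
#'
#' Hill-climbing over polynomial coefficients: starting from the given (or
#' a flat) polynomial, one randomly chosen coefficient is perturbed by a
#' normal increment at each iteration and the change is kept when the
#' separation between heterogeneous and homogeneous cohort scores on fixed
#' training cohorts increases. Candidates whose training gap reaches the
#' running best are re-scored on a larger fixed validation set and the
#' validation winner is returned.
#'
#' @param spec A [quant_model()] describing the homogeneous trait;
#'   heterogeneous training cohorts use an even PRS-independent mixture.
#' @param n_individuals Cohort size for training/validation cohorts.
#' @param degree Polynomial degree, an even number (2, 4 or 6).
#' @param n_train,n_val Number of homogeneous and heterogeneous cohorts in
#'   the training and validation sets.
#' @param iterations Local-search iterations.
#' @param step_scale Standard deviation of coefficient increments.
#' @param init Optional starting coefficient vector (constant first).
#' @param seed Optional integer seed.
#' @return The selected polynomial [weight_function()], with attributes
#'   `train_gap`, `val_gap` and the accepted-gap `trajectory`.
#' @export
learn_polynomial_weights <- function(spec, n_individuals, degree = 6,
                                     n_train = 20, n_val = 100,
                                     iterations = 2000, step_scale = 0.05,
                                     init = NULL, seed = NULL) {
  stopifnot(inherits(spec, "quant_model"), degree >= 2, degree %% 2 == 0)
  het_spec <- quant_model(spec$n_snps, spec$h2, spec$allele_freqs,
                          mixture_fraction = 0.5)
  hom_spec <- quant_model(spec$n_snps, spec$h2, spec$allele_freqs,
                          mixture_fraction = 0)
  with_seed_if(seed, {
    make_set <- function(n_each)
      list(hom = lapply(seq_len(n_each), function(i) {
             coh <- simulate_quantitative_cohort(hom_spec, n_individuals)
             .clipy_precompute(coh$genotypes, coh$phenotype)
           }),
           het = lapply(seq_len(n_each), function(i) {
             coh <- simulate_quantitative_cohort(het_spec, n_individuals)
             .clipy_precompute(coh$genotypes, coh$phenotype)
           }))
    gap_on <- function(coefs, set) {
      wf <- weight_function("polynomial", coefficients = coefs)
      sc <- function(pre) .clipy_score_fast(pre, wf)
      g <- mean(vapply(set$het, sc, numeric(1))) -
        mean(vapply(set$hom, sc, numeric(1)))
      if (is.na(g)) -Inf else g
    }
    train <- make_set(n_train)
    # Random start as in the method description. An all-negative start
    # polynomial has no valid weights and scores -Inf, from which small
    # single-coefficient moves cannot escape, so degenerate starts are
    # redrawn.
    coefs <- if (is.null(init)) stats::rnorm(degree + 1L, sd = 0.5) else
      rep_len(as.numeric(init), degree + 1L)
    best_gap <- gap_on(coefs, train)
    if (is.null(init)) {
      tries <- 0L
      while (!is.finite(best_gap) && tries < 100L) {
        coefs <- stats::rnorm(degree + 1L, sd = 0.5)
        best_gap <- gap_on(coefs, train)
        tries <- tries + 1L
      }
    }
    if (!is.finite(best_gap))
      stop("no valid starting polynomial found", call. = FALSE)
    trajectory <- best_gap
    candidates <- list(coefs)
    if (step_scale > 0) {
      for (it in seq_len(iterations)) {
        prop <- coefs
        idx <- sample.int(degree + 1L, 1L)
        prop[idx] <- prop[idx] + stats::rnorm(1, sd = step_scale)
        g <- gap_on(prop, train)
        if (g > best_gap) {
          coefs <- prop; best_gap <- g
          trajectory <- c(trajectory, g)
          candidates[[length(candidates) + 1L]] <- prop
        }
      }
    }
    if (length(trajectory) == 1L && step_scale > 0)
      warning("local search accepted no improvement; ",
              "returning the initial polynomial", call. = FALSE)
    # Validate the best recent candidates on a larger fixed set.
    top <- candidates[max(1L, length(candidates) - 4L):length(candidates)]
    val <- make_set(max(1L, ceiling(n_val / 2)))
    val_gaps <- vapply(top, gap_on, numeric(1), set = val)
    pick <- top[[which.max(val_gaps)]]
    out <- weight_function("polynomial", coefficients = pick)
    attr(out, "train_gap") <- best_gap
    attr(out, "val_gap") <- max(val_gaps)
    attr(out, "trajectory") <- trajectory
    out
  })
}
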