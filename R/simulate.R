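# Cohort simulators: homogeneous, misclassified, subtype and stratified
# case/control genotype cohorts under the generative disease models.

new_cohort <- function(cases, controls, truth = NULL, spec = list()) {
  stopifnot(ncol(cases) == ncol(controls))
  structure(list(cases = cases, controls = controls, truth = truth,
                 spec = spec),
            class = "clip_cohort")
}

#' @export
print.clip_cohort <- function(x, ...) {
  cat("Case/control cohort:", nrow(x$cases), "cases,", nrow(x$controls),
      "controls,", ncol(x$cases), "SNPs\n")
  if (!is.null(x$truth))
    cat("  truth labels retained (", class(x$truth)[1L], ")\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Case sampling machinery.
#
# Under all three disease models with a constant effect size, the acceptance
# probability of a genotype vector depends on it only through per-block
# risk-allele counts (blocks = groups of SNPs sharing an allele frequency).
# For one or two blocks we exploit this: sample the block counts from their
# exact case-conditional distribution by enumeration, then scatter alleles
# within each block uniformly (hypergeometric allocation over the 2 slots
# per SNP), which is the exact conditional law of exchangeable binomial
# genotypes given their sum. Otherwise we fall back to batched rejection
# sampling on the full genotype vectors.
# ---------------------------------------------------------------------------

# Acceptance probability as a function of the total risk-allele count, for
# models whose per-SNP effects are constant. `mean_count` is E[sum X].
.accept_by_count <- function(model, k, mean_count) {
  switch(model$kind,
    liability = stats::pnorm(
      (model$liability_effects[1L] * (k - mean_count) - model$threshold) /
        model$resid_sd),
    logistic = stats::plogis(model$intercept +
                               model$log_or[1L] * (k - mean_count)),
    risch = pmin(1, model$risch_norm * model$odds_ratios[1L]^k)
  )
}

# Can cases be sampled by count-conditioning? Requires a constant effect and
# at most two distinct allele frequencies.
.count_sampler_blocks <- function(model) {
  eff <- switch(model$kind,
                liability = model$liability_effects,
                logistic = model$log_or,
                risch = log(model$odds_ratios))
  if (length(unique(eff)) != 1L) return(NULL)
  p_unique <- unique(model$allele_freqs)
  if (length(p_unique) > 2L) return(NULL)
  lapply(p_unique, function(pu)
    list(p = pu, idx = which(model$allele_freqs == pu)))
}

# Uniform allocation of per-individual allele counts `k` over `m` SNPs with
# two slots each (multivariate hypergeometric).
.allocate_counts <- function(k, m) {
  n <- length(k)
  out <- matrix(0L, nrow = n, ncol = m)
  rem <- k
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      xj <- stats::rhyper(n, 2L, 2L * (m - j), rem)
      out[, j] <- xj
      rem <- rem - xj
    }
  }
  out[, m] <- rem
  out
}

.sample_cases_counts <- function(model, n, blocks) {
  m_total <- model$n_snps
  mean_count <- sum(2 * model$allele_freqs)
  if (length(blocks) == 1L) {
    k_grid <- 0:(2L * m_total)
    wt <- stats::dbinom(k_grid, 2L * m_total, blocks[[1L]]$p) *
      .accept_by_count(model, k_grid, mean_count)
    k <- sample(k_grid, n, replace = TRUE, prob = wt)
    return(.allocate_counts(k, m_total))
  }
  m1 <- length(blocks[[1L]]$idx); m2 <- length(blocks[[2L]]$idx)
  k1 <- 0:(2L * m1); k2 <- 0:(2L * m2)
  grid <- expand.grid(k1 = k1, k2 = k2)
  wt <- stats::dbinom(grid$k1, 2L * m1, blocks[[1L]]$p) *
    stats::dbinom(grid$k2, 2L * m2, blocks[[2L]]$p) *
    .accept_by_count(model, grid$k1 + grid$k2, mean_count)
  cell <- sample.int(nrow(grid), n, replace = TRUE, prob = wt)
  x <- matrix(0L, nrow = n, ncol = m_total)
  x[, blocks[[1L]]$idx] <- .allocate_counts(grid$k1[cell], m1)
  x[, blocks[[2L]]$idx] <- .allocate_counts(grid$k2[cell], m2)
  x
}

.sample_cases_rejection <- function(model, n, batch_cap = 2e6,
                                    max_draws = 5e8) {
  batch <- min(batch_cap, max(1e4, ceiling(10 * n / model$prevalence)))
  got <- 0L; drawn <- 0; pieces <- list()
  while (got < n) {
    if (drawn >= max_draws)
      stop("rejection sampling drew ", format(drawn, big.mark = ","),
           " individuals but accumulated only ", got, " of ", n,
           " cases; prevalence ", model$prevalence,
           " is too small for the configured cap", call. = FALSE)
    x <- sim_genotypes(batch, model$allele_freqs)
    drawn <- drawn + batch
    keep <- stats::runif(batch) < disease_risk(x, model)
    if (any(keep)) {
      pieces[[length(pieces) + 1L]] <- x[keep, , drop = FALSE]
      got <- got + sum(keep)
    }
  }
  do.call(rbind, pieces)[seq_len(n), , drop = FALSE]
}

.sample_cases <- function(model, n, method = c("auto", "rejection", "counts")) {
  method <- match.arg(method)
  blocks <- if (method != "rejection") .count_sampler_blocks(model) else NULL
  if (method == "counts" && is.null(blocks))
    stop("count-conditioned sampling requires a constant effect size and ",
         "at most two distinct allele frequencies", call. = FALSE)
  if (!is.null(blocks)) .sample_cases_counts(model, n, blocks)
  else .sample_cases_rejection(model, n)
}

# ---------------------------------------------------------------------------

#' Simulate a homogeneous case/control genotype cohort
#'
#' Controls are sampled as independent binomial(2, \eqn{p_j}) genotypes from
#' the population allele frequencies. Cases are ascertained on disease
#' status under the generative model: an individual is retained as a case
#' with probability [disease_risk()], which for the liability model equals
#' thresholding the PRS plus its normal residual at
#' \eqn{T = \Phi^{-1}(1 - V)}.
#'
#' Two exact samplers are available. `"rejection"` draws population batches
#' and keeps case-labelled individuals until `n_cases` accumulate.
#' `"counts"` (used automatically when the model has a constant effect size
#' and at most two distinct allele frequencies) samples each case's
#' risk-allele counts from their enumerated case-conditional distribution
#' and scatters alleles uniformly across SNPs; this draws from the identical
#' distribution at a fraction of the cost and is validated against the
#' rejection sampler in the package tests.
#'
#' @param model A [disease_model()].
#' @param n_cases,n_controls Cohort sizes (positive integers).
#' @param seed Optional integer seed for reproducible sampling.
#' @param method `"auto"` (default), `"rejection"`, or `"counts"`.
#' @return A `clip_cohort`: list with integer matrices `cases`
#'   (`n_cases` x M) and `controls`, optional `truth` labels, and a `spec`
#'   provenance record.
#' @export
sample_case_control <- function(model, n_cases, n_controls, seed = NULL,
                                method = c("auto", "rejection", "counts")) {
  stopifnot(inherits(model, "disease_model"), n_cases > 0, n_controls > 0)
  method <- match.arg(method)
  with_seed_if(seed, {
    cases <- .sample_cases(model, n_cases, method)
    controls <- sim_genotypes(n_controls, model$allele_freqs)
    new_cohort(cases, controls,
               spec = list(model = model, seed = seed, mixture = "none"))
  })
}

#' Simulate a heterogeneous cohort by case/control misclassification
#'
#' The labelled "case" matrix concatenates `ceiling(fraction * n_cases)`
#' true ascertained cases with controls masquerading as cases; the control
#' matrix is sampled independently. Truth labels record which rows are true
#' cases.
#'
#' @inheritParams sample_case_control
#' @param true_case_fraction Fraction of the labelled cases that are true
#'   cases, in [0, 1]; `0.5` is the maximally heterogeneous even mixture.
#' @return A `clip_cohort` with logical `truth$is_true_case`.
#' @export
make_misclassified_cohort <- function(model, n_cases, n_controls,
                                      true_case_fraction, seed = NULL,
                                      method = c("auto", "rejection", "counts")) {
  stopifnot(inherits(model, "disease_model"),
            true_case_fraction >= 0, true_case_fraction <= 1)
  method <- match.arg(method)
  n_true <- as.integer(ceiling(true_case_fraction * n_cases))
  with_seed_if(seed, {
    true_cases <- if (n_true > 0) .sample_cases(model, n_true, method)
                  else matrix(0L, 0L, model$n_snps)
    fake_cases <- sim_genotypes(n_cases - n_true, model$allele_freqs)
    controls <- sim_genotypes(n_controls, model$allele_freqs)
    new_cohort(rbind(true_cases, fake_cases), controls,
               truth = data.frame(is_true_case = rep(c(TRUE, FALSE),
                                                     c(n_true,
                                                       n_cases - n_true))),
               spec = list(model = model, seed = seed,
                           mixture = "misclassify",
                           true_case_fraction = true_case_fraction))
  })
}

#' Per-subtype liability effect matrix for subtype-mixture designs
#'
#' Builds an S x M matrix of liability effects in which a `shared_fraction`
#' of SNPs carries an identical effect across all subtypes and the remaining
#' SNPs are split into disjoint consecutive blocks, one per subtype. The
#' base effect is sized so the first subtype's block explains `block_ve` of
#' liability variance; other subtypes' effects are scaled by
#' `effect_ratios`.
#'
#' @param n_snps Number of SNPs M.
#' @param n_subtypes Number of subtypes S (>= 1).
#' @param block_ve Liability variance explained by the first subtype's SNP
#'   block.
#' @param allele_freqs Effect-allele frequencies (scalar or length M).
#' @param shared_fraction Fraction of SNPs shared by all subtypes, in
#'   [0, 1].
#' @param effect_ratios Length-S multipliers of the base effect
#'   (`effect_ratios[1]` is usually 1); ratio 0 gives an unascertained
#'   subtype, the misclassification limit.
#' @return An S x M matrix of liability effects.
#' @export
subtype_effects <- function(n_snps, n_subtypes, block_ve, allele_freqs = 0.5,
                            shared_fraction = 0,
                            effect_ratios = rep(1, n_subtypes)) {
  stopifnot(n_subtypes >= 1, shared_fraction >= 0, shared_fraction <= 1,
            length(effect_ratios) == n_subtypes)
  p <- rep_len(allele_freqs, n_snps)
  n_shared <- floor(shared_fraction * n_snps)
  own <- n_snps - n_shared
  per <- floor(own / n_subtypes)
  beta1 <- beta_for_ve(block_ve, p[seq_len(max(per, 1L))])
  effects <- matrix(0, n_subtypes, n_snps)
  for (s in seq_len(n_subtypes)) {
    idx <- if (per > 0) (n_shared + (s - 1L) * per) + seq_len(per)
           else integer(0)
    effects[s, idx] <- beta1 * effect_ratios[s]
    if (n_shared > 0) effects[s, seq_len(n_shared)] <- beta1
  }
  effects
}

#' Simulate a cohort heterogeneous by distinct disease subtypes
#'
#' Each subtype s has its own liability
#' \eqn{Y^*_s = (x - E[X])^T \beta_s + \epsilon_s} with an independent
#' residual filling the variance to 1, and its own threshold at the shared
#' prevalence. An individual is a case when any sub-liability crosses its
#' threshold; sampling is stratified so realised subtype-of-origin
#' proportions match `case_proportions`. Truth labels record the assigned
#' stratum and the full set of sub-liabilities that fired.
#'
#' @param effects S x M matrix of per-subtype liability effects (see
#'   [subtype_effects()]).
#' @param base A liability [disease_model()] supplying prevalence and allele
#'   frequencies (its own effects are ignored).
#' @param case_proportions Length-S vector summing to 1 (default equal).
#' @inheritParams sample_case_control
#' @return A `clip_cohort`; `truth` holds `subtype` and a logical `fired`
#'   matrix.
#' @export
sample_subtype_cohort <- function(effects, base, n_cases, n_controls,
                                  case_proportions = NULL, seed = NULL) {
  stopifnot(inherits(base, "disease_model"), is.matrix(effects),
            ncol(effects) == base$n_snps)
  S <- nrow(effects)
  if (is.null(case_proportions)) case_proportions <- rep(1 / S, S)
  stopifnot(length(case_proportions) == S,
            abs(sum(case_proportions) - 1) < 1e-8)
  p <- base$allele_freqs
  V <- base$prevalence
  thr <- stats::qnorm(1 - V)
  sub_var <- rowSums(sweep(effects^2, 2L, 2 * p * (1 - p), `*`))
  if (any(sub_var >= 0.99))
    stop("a subtype PRS explains >= 0.99 of liability variance", call. = FALSE)
  resid_sd <- sqrt(1 - sub_var)
  n_s <- diff(round(cumsum(c(0, case_proportions)) * n_cases))

  with_seed_if(seed, {
    case_rows <- vector("list", S)
    fired_rows <- vector("list", S)
    for (s in which(n_s > 0)) {
      got <- 0L; acc <- list(); accf <- list()
      # Rejection on the s-th sub-liability; all sub-liabilities recorded.
      batch <- max(1e4, ceiling(5 * n_s[s] / V))
      while (got < n_s[s]) {
        x <- sim_genotypes(batch, p)
        prs <- sweep(x, 2L, 2 * p) %*% t(effects)
        liab <- prs + matrix(stats::rnorm(batch * S, sd = rep(resid_sd,
                                                              each = batch)),
                             batch, S)
        keep <- liab[, s] > thr
        if (any(keep)) {
          acc[[length(acc) + 1L]] <- x[keep, , drop = FALSE]
          accf[[length(accf) + 1L]] <- liab[keep, , drop = FALSE] > thr
          got <- got + sum(keep)
        }
      }
      case_rows[[s]] <- do.call(rbind, acc)[seq_len(n_s[s]), , drop = FALSE]
      fired_rows[[s]] <- do.call(rbind, accf)[seq_len(n_s[s]), ,
                                              drop = FALSE]
    }
    controls <- sim_genotypes(n_controls, p)
    new_cohort(do.call(rbind, case_rows), controls,
               truth = list(subtype = rep(seq_len(S), n_s),
                            fired = do.call(rbind, fired_rows)),
               spec = list(base = base, effects = effects,
                           case_proportions = case_proportions,
                           seed = seed, mixture = "subtype"))
  })
}

#' Simulate a cohort drawn from two diverged subpopulations
#'
#' Models confounding population structure: controls are drawn from two
#' equally sized subpopulations whose allele frequencies at alternating
#' halves of the SNPs are \eqn{0.5 + p'} and \eqn{0.5 - p'} (mirrored
#' between subpopulations), with \eqn{p' = \sqrt{F_{st}}/2} so the
#' control-level fixation index between the two groups equals `f_st` under
#' the two-population Wright/Hudson convention
#' \eqn{F_{st} = p'^2 / (\bar p (1 - \bar p))} at \eqn{\bar p = 0.5}.
#' Cases are obtained by liability-thresholding draws from the mixed
#' population, so subgroup balance is *not* enforced among cases.
#'
#' @param f_st Target control-level fixation index, in [0, 0.5).
#' @param base A liability [disease_model()] with a constant effect size; its
#'   prevalence and effect size are reused, its allele frequencies replaced
#'   by the stratified pattern (M must be even).
#' @inheritParams sample_case_control
#' @return A `clip_cohort`; `truth` holds the control subgroup labels.
#' @export
sample_stratified_cohort <- function(f_st, base, n_cases, n_controls,
                                     seed = NULL) {
  stopifnot(inherits(base, "disease_model"), base$kind == "liability")
  if (f_st < 0 || f_st >= 0.5)
    stop("`f_st` must lie in [0, 0.5)", call. = FALSE)
  m <- base$n_snps
  if (m %% 2L != 0L) stop("the SNP count must be even", call. = FALSE)
  beta <- unique(base$liability_effects)
  if (length(beta) != 1L)
    stop("stratified sampling requires a constant effect size", call. = FALSE)
  p_off <- sqrt(f_st) / 2
  if (0.5 + p_off >= 1) stop("`f_st` implies an allele frequency >= 1",
                             call. = FALSE)
  half1 <- seq_len(m / 2L); half2 <- setdiff(seq_len(m), half1)
  freq_group <- rbind(c(0.5 + p_off, 0.5 - p_off),   # group 1: half1, half2
                      c(0.5 - p_off, 0.5 + p_off))   # group 2 mirrored

  # Mixture-population per-SNP variance: within-group binomial variance plus
  # the between-group spread of the mean dosage (+-2p' around 1).
  snp_var <- 2 * (0.5 + p_off) * (0.5 - p_off) + 4 * p_off^2
  prs_var <- beta^2 * m * snp_var
  if (prs_var >= 0.99) stop("stratified PRS variance reaches 0.99",
                            call. = FALSE)
  resid_sd <- sqrt(1 - prs_var)
  thr <- stats::qnorm(1 - base$prevalence)

  group_geno <- function(n, g) {
    x <- matrix(0L, n, m)
    x[, half1] <- sim_genotypes(n, rep(freq_group[g, 1L], m / 2L))
    x[, half2] <- sim_genotypes(n, rep(freq_group[g, 2L], m / 2L))
    x
  }
  # Count-conditioned case sampler within a subgroup: acceptance depends on
  # the total risk-allele count only (constant beta, mixture mean m).
  group_cases <- function(n, g) {
    m2 <- m / 2L
    grid <- expand.grid(k1 = 0:(2L * m2), k2 = 0:(2L * m2))
    wt <- stats::dbinom(grid$k1, 2L * m2, freq_group[g, 1L]) *
      stats::dbinom(grid$k2, 2L * m2, freq_group[g, 2L]) *
      stats::pnorm((beta * (grid$k1 + grid$k2 - m) - thr) / resid_sd)
    cell <- sample.int(nrow(grid), n, replace = TRUE, prob = wt)
    x <- matrix(0L, n, m)
    x[, half1] <- .allocate_counts(grid$k1[cell], m2)
    x[, half2] <- .allocate_counts(grid$k2[cell], m2)
    x
  }

  with_seed_if(seed, {
    # P(case | group) is equal for the two mirrored groups, so the
    # case-conditional group label stays Bernoulli(1/2).
    g_case <- sample(1:2, n_cases, replace = TRUE)
    cases <- matrix(0L, n_cases, m)
    for (g in 1:2) if (any(g_case == g))
      cases[g_case == g, ] <- group_cases(sum(g_case == g), g)
    n1 <- floor(n_controls / 2)
    controls <- rbind(group_geno(n1, 1L), group_geno(n_controls - n1, 2L))
    new_cohort(cases, controls,
               truth = list(case_group = g_case,
                            control_group = rep(1:2,
                                                c(n1, n_controls - n1))),
               spec = list(base = base, f_st = f_st, p_offset = p_off,
                           seed = seed, mixture = "stratified"))
  })
}
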