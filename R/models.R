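#' Construct a generative disease-risk model
#'
#' Defines one of three generative models mapping a genotype vector to a
#' probability of disease: a multiplicative (Risch) relative-risk model, a
#' logistic regression model, or a liability threshold model in which a
#' hidden standard-normal liability is thresholded at
#' \eqn{T = \Phi^{-1}(1 - V)} for prevalence \eqn{V}.
#'
#' For the Risch and logistic models effects are supplied as odds ratios; for
#' the liability model effects may be supplied either directly on the
#' liability scale (`liability_effects`) or as odds ratios, which are
#' converted with [or_to_liability()]. The logistic intercept is
#' \eqn{\beta_0 = -\log(1/V - 1)} with genotypes mean-centred, and the Risch
#' normalising constant is \eqn{A = V / E[\prod_m OR_m^{x_m}]}, with the
#' expectation evaluated in closed form over independent binomial genotypes:
#' \eqn{E[OR^x] = ((1-p) + p\,OR)^2} per SNP.
#'
#' @param kind One of `"liability"`, `"logistic"`, `"risch"`.
#' @param prevalence Population disease prevalence \eqn{V}, in (0, 1).
#' @param allele_freqs Vector of effect-allele frequencies in (0, 1).
#' @param odds_ratios Per-SNP odds ratios (> 0); required for
#'   `"logistic"`/`"risch"`, optional for `"liability"`.
#' @param liability_effects Per-SNP effects on the standard-normal liability
#'   scale; `"liability"` only. Exactly one of `odds_ratios` /
#'   `liability_effects` must be given for the liability model.
#'
#' @return An object of class `disease_model`: a list with the resolved
#'   per-SNP parameters, the derived intercept/threshold/normalising
#'   constant, and (liability model) the PRS variance explained and residual
#'   standard deviation.
#'
#' @examples
#' m <- disease_model("liability", prevalence = 0.01,
#'                    allele_freqs = rep(0.2, 100),
#'                    liability_effects = rep(beta_for_ve(0.034, rep(0.2, 100)), 100))
#' m$prs_var
#' @seealso [disease_risk()], [sample_case_control()], [beta_for_ve()]
#' @export
disease_model <- function(kind = c("liability", "logistic", "risch"),
                          prevalence, allele_freqs,
                          odds_ratios = NULL, liability_effects = NULL) {
  kind <- match.arg(kind)
  V <- check_probability(prevalence, "prevalence")
  p <- check_probability(allele_freqs, "allele_freqs")
  m <- length(p)

  if (kind %in% c("logistic", "risch")) {
    if (is.null(odds_ratios))
      stop("`odds_ratios` are required for the ", kind, " model", call. = FALSE)
    if (any(odds_ratios <= 0)) stop("odds ratios must be positive", call. = FALSE)
    gamma <- rep_len(odds_ratios, m)
    beta <- NULL
  } else {
    if (is.null(liability_effects) == is.null(odds_ratios))
      stop("supply exactly one of `liability_effects` or `odds_ratios`",
           call. = FALSE)
    if (!is.null(odds_ratios)) {
      gamma <- rep_len(odds_ratios, m)
      beta <- or_to_liability(gamma, V)
    } else {
      beta <- rep_len(liability_effects, m)
      gamma <- liability_to_or(beta, V)
    }
  }

  out <- list(kind = kind, prevalence = V, allele_freqs = p,
              odds_ratios = gamma, n_snps = m)

  if (kind == "liability") {
    prs_var <- sum(beta^2 * 2 * p * (1 - p))
    if (prs_var >= 0.99)
      stop("PRS variance explained (", signif(prs_var, 4),
           ") must stay below 0.99 for the liability model to be ",
           "well-conditioned", call. = FALSE)
    out$liability_effects <- beta
    out$prs_var <- prs_var
    out$resid_sd <- sqrt(1 - prs_var)
    out$threshold <- stats::qnorm(1 - V)
  } else if (kind == "logistic") {
    out$intercept <- -log(1 / V - 1)
    out$log_or <- log(gamma)
  } else {
    # E[prod OR^x] is exact for independent binomial(2, p) genotypes.
    out$risch_norm <- V / prod(((1 - p) + p * gamma)^2)
  }
  class(out) <- "disease_model"
  out
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Disease model:", x$kind, "\n")
  cat("  SNPs:", x$n_snps, " prevalence:", x$prevalence, "\n")
  if (x$kind == "liability")
    cat("  PRS variance explained:", signif(x$prs_var, 4),
        " threshold T:", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Constant liability effect for a target PRS variance explained
#'
#' Returns the single effect size \eqn{\beta} such that SNPs at the given
#' allele frequencies jointly explain `ve` of the unit liability variance:
#' \eqn{\sum_j \beta^2 \cdot 2 p_j (1 - p_j) = ve}.
#'
#' @param ve Target variance explained, in (0, 1).
#' @param allele_freqs Effect-allele frequencies.
#' @return A scalar effect size.
#' @export
beta_for_ve <- function(ve, allele_freqs) {
  check_probability(ve, "ve")
  p <- check_probability(allele_freqs, "allele_freqs")
  sqrt(ve / sum(2 * p * (1 - p)))
}

#' Disease risk for genotype vectors under a generative model
#'
#' Evaluates \eqn{P(y = 1 \mid x)} under the model:
#' Risch, \eqn{A \prod_m OR_m^{x_m}} (clamped at 1 with a warning if the
#' normalised risk exceeds 1); logistic,
#' \eqn{\sigma(\beta_0 + \sum_m \beta_m (x_m - E[X_m]))}; liability,
#' \eqn{\Phi\!\big(((x - E[X])^T\beta - T) / \sqrt{1 - Var(x^T\beta)}\big)}.
#'
#' @param genotypes A length-M dosage vector or an N x M dosage matrix with
#'   entries in \{0, 1, 2\}.
#' @param model A [disease_model()].
#' @return A vector of case probabilities, one per individual.
#' @export
disease_risk <- function(genotypes, model) {
  stopifnot(inherits(model, "disease_model"))
  x <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, nrow = 1L)
  check_genotypes(x)
  if (ncol(x) != model$n_snps)
    stop("genotype vector length does not match the model's SNP count",
         call. = FALSE)
  centred <- sweep(x, 2L, 2 * model$allele_freqs)
  switch(model$kind,
    risch = {
      risk <- model$risch_norm * exp(x %*% log(model$odds_ratios))[, 1L]
      if (any(risk > 1)) {
        warning("Risch risk exceeded 1 for ", sum(risk > 1),
                " individual(s); clamped", call. = FALSE)
        risk <- pmin(risk, 1)
      }
      risk
    },
    logistic = stats::plogis(model$intercept +
                               (centred %*% model$log_or)[, 1L]),
    liability = stats::pnorm(((centred %*% model$liability_effects)[, 1L] -
                                model$threshold) / model$resid_sd)
  )
}

#' Convert an odds ratio to a liability-scale effect
#'
#' Applies the approximate conversion
#' \deqn{\beta \approx \Phi^{-1}\!\big(F_{logistic}(\log\tfrac{V}{1-V} +
#'   \log OR)\big) - \Phi^{-1}(V)}
#' mapping a logistic-regression odds ratio to an effect on the
#' standard-normal liability scale at prevalence \eqn{V}. The map is monotone
#' in the odds ratio but not antisymmetric: in general
#' \eqn{\beta(1/OR) \neq -\beta(OR)}.
#'
#' @param or Odds ratio(s), positive.
#' @param prevalence Disease prevalence \eqn{V} in (0, 1).
#' @return Liability-scale effect(s).
#' @seealso [liability_to_or()] for the numerical inverse.
#' @export
or_to_liability <- function(or, prevalence) {
  V <- check_probability(prevalence, "prevalence")
  if (any(!is.finite(or)) || any(or <= 0))
    stop("odds ratios must be finite and positive", call. = FALSE)
  stats::qnorm(stats::plogis(stats::qlogis(V) + log(or))) - stats::qnorm(V)
}

#' Convert a liability-scale effect to an odds ratio
#'
#' Exact inverse of [or_to_liability()]:
#' \eqn{OR = \exp\big(logit(\Phi(\beta + \Phi^{-1}(V))) - logit(V)\big)}.
#'
#' @param beta Liability-scale effect(s).
#' @param prevalence Disease prevalence \eqn{V} in (0, 1).
#' @return Odds ratio(s).
#' @export
liability_to_or <- function(beta, prevalence) {
  V <- check_probability(prevalence, "prevalence")
  if (any(!is.finite(beta))) stop("effects must be finite", call. = FALSE)
  exp(stats::qlogis(stats::pnorm(beta + stats::qnorm(V))) - stats::qlogis(V))
}
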