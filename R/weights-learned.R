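# Shipped polynomial weight functions for CLiP-Y, produced by the package's
# own local-search learner (learn_polynomial_weights) on simulated training
# cohorts: 20,000 individuals, 100 SNPs, PRS variance explained 0.1, even
# PRS-independent mixture for the heterogeneous arm; 6 training and 40
# validation cohorts, 600 iterations at step scale 0.1, two random restarts
# per degree (seeds 1000*degree + {1, 2}), winner chosen by validation gap.
# All three degrees converged to concave bumps over the percentile domain
# that vanish towards one extreme of the phenotype distribution.

.learned_polynomials <- list(
  `2` = c(0.0653580874031468, 0.136732387525609, -0.292437611456635),
  `4` = c(-0.0544776331159914, 0.481014032495538, 0.14760940781183,
          0.0943113049205294, -0.543825602328234),
  `6` = c(-0.2075746263394, 0.489329932510373, 0.295231906097099,
          0.436623186883692, -0.834734277256256, 0.199870754950795,
          -0.319627169414794)
)

#' Shipped learned polynomial weight function
#'
#' Returns the polynomial weight function of the requested degree learned
#' by [learn_polynomial_weights()] on simulated cohorts and shipped as the
#' package default (degree 6 is the default used in applications). The
#' learned functions are concave over the percentile domain, concentrating
#' weight over a broad band of the distribution away from the extremes;
#' the training conditions and search settings are described in the
#' methods vignette.
#'
#' @param degree 2, 4 or 6.
#' @return A polynomial [weight_function()].
#' @export
clipy_default_polynomial <- function(degree = 6) {
  key <- as.character(degree)
  if (!key %in% names(.learned_polynomials))
    stop("no shipped polynomial of degree ", degree, call. = FALSE)
  weight_function("polynomial", coefficients = .learned_polynomials[[key]])
}
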