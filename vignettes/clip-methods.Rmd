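---
title: "Detecting heterogeneity in polygenic risk score cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heterogeneity in polygenic risk score cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliphet)
```

## The problem

A GWAS case cohort is rarely guaranteed to be homogeneous. Cases may mix
true cases with misdiagnosed controls, or mix several disease subtypes each
driven by its own polygenic risk score (PRS). Such structure weakens PRS
transferability and confounds downstream analyses, yet with genome-wide
significant effects explaining only a few percent of liability variance it
is invisible to per-individual classification. `cliphet` detects it at the
cohort level: when risk alleles are enriched in only a *subset* of the
labelled cases, the associated SNPs become positively correlated across the
case matrix, and a weighted sum of pairwise correlation differences between
cases and controls aggregates that faint signal over all
\(\binom{M}{2}\) SNP pairs.

## Why the null is not zero

The crucial subtlety is the null hypothesis. Under a liability threshold
model, case status means that a hidden liability
\(Y^* = (x - E[X])^T\beta + \epsilon\) (unit variance,
\(\epsilon \sim N(0, 1 - \mathrm{Var}(x^T\beta))\)) exceeded
\(T = \Phi^{-1}(1 - V)\) at prevalence \(V\). Conditioning on
\(Y^* > T\) makes otherwise independent risk alleles *compete*: given that
the threshold was passed, carrying many copies of one risk allele makes
carrying many of another less necessary, so positively oriented SNP pairs
are negatively correlated among perfectly homogeneous cases. A test that
assumes zero correlation under the null (the behaviour of the earlier
BUHMBOX statistic, available here as `null = "zero"`) is conservative:
genuine heterogeneity must first cancel the negative ascertainment bias
before it looks positive. Under a purely multiplicative (Risch) risk model
the competition disappears and the zero null is exact; under a logistic
model the bias exists but only becomes material at odds ratios larger than
typical GWAS effects. All three generative models are implemented in
`disease_model()` so the contrast can be simulated directly.

## The statistic

For case and control dosage matrices with correlation matrices \(R\) and
\(R^0\),

\[
S \;=\; \frac{\sum_{j<k} w_j w_k \,(R_{jk} - R^0_{jk})}
  {\sqrt{\frac{N + N^0}{N N^0} \sum_{j<k} w_j^2 w_k^2}},
\qquad
w_j = \frac{p_j (1-p_j)(\gamma_j - 1)}{(\gamma_j - 1) p_j + 1},
\]

with \(p_j\) the effect-allele frequency and \(\gamma_j\) the odds ratio,
alleles oriented at load time so \(\gamma_j \ge 1\). \(S\) is
asymptotically standard normal when both matrices are drawn identically
and SNPs are uncorrelated, so `clip_score()` reports
\(z = S - E[S_{\mathrm{hom}}]\) and a one-sided upper-tail p-value —
heterogeneity only ever pushes the score upward. Note the weight
denominator \((\gamma - 1)p + 1 = 1 - p(1 - \gamma)\) is strictly positive
for any valid \(\gamma > 0\), so no extra guard is needed beyond input
validation.

The expected homogeneous score is computed exactly, not simulated:
`expected_case_correlation()` enumerates the genotype values
\(\{0,1,2\}\) (singly and pairwise, with the binomial independence prior)
and applies Bayes' theorem with case probabilities from the liability
model. One convention had to be fixed here, because conditioning on one or
two SNPs leaves the remainder of the PRS unobserved: we absorb the
remaining PRS into the residual, i.e.
\(P(Y{=}1 \mid x_j) = \Phi\big(((x_j - 2p_j)\beta_j - T) /
\sqrt{1 - \beta_j^2\, 2 p_j (1 - p_j)}\big)\), and the pairwise analogue
removes both SNPs' variance contributions. Treating the aggregate of many
small independent effects as Gaussian, this is exact, and the package
verifies it against brute-force Monte-Carlo case sampling on an odds-ratio
by allele-frequency lattice (agreement within three Monte-Carlo standard
errors is part of the test suite).

Summary statistics usually report odds ratios; the liability-scale effect
used throughout is obtained from
\(\beta \approx \Phi^{-1}\!\big(F_{\mathrm{logistic}}(\log\frac{V}{1-V} +
\log OR)\big) - \Phi^{-1}(V)\) (`or_to_liability()`), with the exact
numerical inverse available for the reverse direction. The map is monotone
but *not* antisymmetric, so allele flipping is performed on the odds-ratio
scale first and the liability effect re-derived.

## Simulators

All study designs are generated by first-class, seeded simulators.
Controls are independent binomial(2, \(p_j\)) draws; cases are ascertained
on disease status.

* **Homogeneous / misclassified** (`sample_case_control()`,
  `make_misclassified_cohort()`): the heterogeneous design concatenates
  ascertained cases with population controls labelled as cases; an even
  split maximises the signal.
* **Subtypes** (`sample_subtype_cohort()`): each subtype has its own
  liability with its own threshold at the shared prevalence, and a case
  fires when *any* sub-liability crosses. Within-subtype SNP pairs
  correlate positively across the case matrix, cross-subtype pairs
  negatively, which attenuates but does not remove the aggregate signal.
  The overall case prevalence slightly exceeds \(V\) by construction
  (union of events), which we accept as part of the design.
* **Population structure** (`sample_stratified_cohort()`): two
  subpopulations whose allele frequencies at alternating SNP halves are
  \(0.5 \pm p'\), mirrored between groups, with
  \(p' = \sqrt{F_{st}}/2\) under the two-population Wright convention
  \(F_{st} = p'^2/(\bar p(1-\bar p))\) at \(\bar p = 0.5\) (the package
  fixes this convention; a Weir-style estimator on labelled simulated
  controls recovers the target in the tests). Controls are drawn equally
  from the groups; cases are thresholded draws from the mixture, so their
  subgroup balance is free.
* **Expression-mediated risk** (`expression_model()`,
  `simulate_expression_cohort()`): genes are linear in a shared SNP set
  (unit variance, fraction \(V_G^2\) genetic), liability is linear in the
  genes with noise filling the variance to 1; threshold-passers become
  cases, threshold-failers controls.
* **Quantitative traits** (`quant_model()`,
  `simulate_quantitative_cohort()`): \(Y = \mathrm{PRS} + N(0, 1-h^2)\)
  for PRS-dependent individuals, while a configurable fraction receives
  \(Y \sim N(0,1)\) independent of genotype; the phenotype variance is 1
  either way.

### Exact count-conditioned case sampling

Rejection sampling at prevalence 0.01 discards 99% of draws, which is
wasteful at the 30,000-case cohort sizes the power studies use. For every
model in this package whose effect size is constant across SNPs, the
acceptance probability of a genotype vector depends on it only through
per-block risk-allele counts (blocks group SNPs sharing an allele
frequency). `sample_case_control()` therefore enumerates the exact
case-conditional distribution of the block counts, samples counts, and
scatters alleles uniformly within blocks (the exact conditional law of
exchangeable binomial genotypes given their sum, realised by sequential
hypergeometric draws). This draws from the *identical* distribution as
rejection at a small fraction of the cost; the test suite asserts
distributional equality against the rejection sampler with a chi-square
test on the full allele-count distribution. Heterogeneous-frequency or
heterogeneous-effect specs fall back to batched rejection automatically.

## CLiP-X: continuous predictors

For predictors such as imputed expression there is no allele frequency or
odds ratio, so per-SNP weights are replaced by pairwise mixture-derived
weights. Writing \(\mu^\pm, \sigma^\pm\) for case-like/control-like
subgroup moments and \(\pi\) for the control-like proportion, the weight
is the derivative of the expected whole-cohort correlation with respect to
\(\pi\) at the homogeneous point:
\(w_{jk} = (\mu_j^+ - \mu_j^-)(\mu_k^+ - \mu_k^-)/(\sigma_j^-\sigma_k^-)\).
Since subgroup membership is unknown at test time, `clipx_score()` uses
whole-case-cohort means in place of \(\mu^+\) (the \(\hat w\)
approximation). With the mixture convention used here — whole-cohort mean
\(\mu = \pi\mu^- + (1-\pi)\mu^+\) — the approximation rescales every
weight by the constant \((1-\pi)^2\), the squared proportion of the
case-like subgroup, leaving the normalised score unchanged; the tests
assert the constant and the invariance. (At the even mixture
\(\pi = 0.5\) used throughout the simulations the constant is 0.25
regardless of which subgroup the proportion refers to.)

The null accounts for predictor correlations that exist *before*
ascertainment (shared eQTLs): with jointly Gaussian predictors and
liability \(Y^* = Z^T\alpha + \epsilon\), conditioning on the case (upper)
or control (lower) liability tail gives conditional covariance
\(\Sigma - \delta\, cc^T\) with \(c = \mathrm{Cov}(Z, Y^*)\) and
\(\delta = \lambda(\lambda - T)\) the truncated-normal variance deficit
(Mills-ratio mean \(\lambda\)). `expected_expression_correlation()`
implements this closed form; a Monte-Carlo null over simulated homogeneous
cohorts (`null = "mc"`, 400 replicates by default) is available for
specifications with no analytic description. Because the score aggregates
pairwise weights, its denominator uses
\(\sum_{j<k} \hat w_{jk}^2\) — the natural generalisation of
\(\sum_{j<k} w_j^2 w_k^2\) — a choice validated by the standard-normal
calibration of control-versus-control scores in the test suite.

## CLiP-Y: quantitative phenotypes

Without a case/control split, each individual is weighted by a function of
their phenotype percentile. Weights \(\phi_i \ge 0\), \(\sum_i \phi_i = 1\)
define weighted moments
\(E[u_j] = \sum_i \phi_i x_{ij}\), a weighted correlation matrix
\(R^\phi\), weighted allele frequencies \(p^\phi_j = E[u_j]/2\), a
variance-ratio generalisation of the odds ratio
\(\gamma^\phi_j = p^\phi_j(1-p^\phi_j)/(p^0_j(1-p^0_j))\), and the score

\[
S = \frac{\sum_{j<k} w^\phi_j w^\phi_k (R^\phi_{jk} - R^0_{jk})}
 {\sqrt{\big(\textstyle\sum_i \phi_i^2 - \tfrac1N\big)
   \sum_{j<k} (w^\phi_j)^2 (w^\phi_k)^2}},
\]

where \(R^0\) is the uniform-weight correlation over the *same*
individuals — no held-out controls exist. The scale factor corrects the
variance of \(R^\phi - R^0\) for the overlap; for a dichotomous weighting
with \(N^\phi\) pseudo-cases it becomes \(N^\phi N/(N - N^\phi)\) rather
than the \(N^\phi N/(N + N^\phi)\) of disjoint case/control sets, and the
tests assert the exact \(\sqrt{(N + N^\phi)/(N - N^\phi)}\) ratio between
the two statistics on the induced pseudo-cohort. Working on mid-rank
percentiles makes the score invariant under monotone phenotype transforms.
Weight functions with negative values are floored at zero before
normalisation (the scale requires \(\phi_i \ge 0\); the polynomial family
is otherwise unconstrained), and a uniform weighting is rejected because
the scale factor degenerates to zero.

The shipped polynomial weight functions (`clipy_default_polynomial()`)
were produced by the package's own hill-climbing learner
(`learn_polynomial_weights()`): one randomly chosen coefficient is
perturbed per iteration and the move kept when the mean score gap between
heterogeneous and homogeneous training cohorts increases, with final
selection on a held-out validation set. The shipped runs used cohorts of
20,000 individuals, 100 SNPs, PRS variance explained 0.1, an even
PRS-independent mixture for the heterogeneous arm, 6 training and 40
validation cohorts, 600 iterations of step 0.1, and two random restarts
per degree (seeds recorded in the function's documentation source); these
sizes were chosen so the training signal is far above its Monte-Carlo
noise while a full search completes in minutes. Because the expected
homogeneous score is design-dependent, `estimate_clipy_null()` estimates
it by simulation (400 replicate cohorts by default, standard error
reported) — the practical route whenever the pairwise analytic expectation
would require numerical integration over every SNP pair.

## Meta-analysis

Per-cohort results combine three ways (`fisher_combine()`, `meta_z()`,
`sum_scores()`): Fisher's \(-2\sum\log p_i\) on \(2K\) df, the
sample-size-weighted \(Z = \sum Z_i n_i/\sqrt{\sum n_i^2}\), and the
centred sum of unit-variance scores scaled by \(\sqrt K\). All are
one-sided, in keeping with the directional alternative.
`benjamini_hochberg()` reports per-rank critical values \((k/m)q\)
alongside the step-up discovery flags, as study tables print them; the
rate \(q\) is a required argument with no default, since no universal
value is defensible.

## Numerical choices and degenerate inputs

* Liability specifications with \(\mathrm{Var}(x^T\beta) \ge 0.99\) are
  rejected outright — the residual standard deviation would make the
  threshold model ill-conditioned.
* A SNP with zero variance in either cohort is an error naming the SNP;
  silent dropping would change the statistic's value unannounced. The
  dosage reader flags constant columns on load for the same reason.
* Risch risks exceeding 1 after normalisation are clamped with a warning;
  the normalising constant uses the exact closed form
  \(E\big[\prod_m OR_m^{x_m}\big] = \prod_m ((1-p_m) + p_m OR_m)^2\) for
  independent binomial genotypes.
* Underflowing p-values entering Fisher's method are clamped at 1e-300
  with a warning.
* All samplers accept a `seed` and restore the caller's RNG state;
  identical seeds give bit-identical cohorts.

## What the simulations do and do not show

The generators reproduce the designed features of the study conditions —
ascertainment at low prevalence, even mixtures, two-group allele-frequency
divergence, shared-eQTL gene correlations — but deliberately omit linkage
disequilibrium between SNPs, X-chromosome dosage, covariate effects, and
real genotyping artefacts. Passing tests therefore demonstrate the
statistic's behaviour under its stated assumptions, in particular
approximately uncorrelated SNPs among controls; applying the test to real
data still requires LD pruning and the usual cohort-level quality control
upstream. Known limitations: the count-conditioned fast sampler covers
constant-effect architectures only (others use rejection and are slower);
the analytic CLiP-X null assumes jointly Gaussian predictors; and the
expected CLiP-Y score has no closed form here, so its null is simulated.
The experiment drivers (`run_experiment()`) default to the full study
sizes but accept reduced sizes through their `config` argument; the test
suite runs scaled-down versions of every design and the acceptance script
reruns the headline power/specificity/calibration numbers at full size.
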