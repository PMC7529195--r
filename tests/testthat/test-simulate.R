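test_that("fixed seeds give bit-identical cohorts", {
  m <- scz_model(n_snps = 20)
  a <- sample_case_control(m, 200, 200, seed = 7)
  b <- sample_case_control(m, 200, 200, seed = 7)
  expect_identical(a$cases, b$cases)
  expect_identical(a$controls, b$controls)
  c1 <- make_misclassified_cohort(m, 100, 100, 0.5, seed = 3)
  c2 <- make_misclassified_cohort(m, 100, 100, 0.5, seed = 3)
  expect_identical(c1$cases, c2$cases)
  q <- quant_model(10, 0.1, mixture_fraction = 0.3)
  expect_identical(simulate_quantitative_cohort(q, 500, seed = 5),
                   simulate_quantitative_cohort(q, 500, seed = 5))
})

test_that("count-conditioned and rejection case samplers agree in distribution", {
  # Small architecture where rejection is affordable; compare the full
  # per-individual risk-allele-count distributions.
  p <- rep(0.3, 6)
  m <- disease_model("liability", 0.05, p,
                     liability_effects = rep(beta_for_ve(0.2, p), 6))
  n <- 20000
  fast <- sample_case_control(m, n, 10, seed = 1, method = "counts")
  slow <- sample_case_control(m, n, 10, seed = 2, method = "rejection")
  kf <- tabulate(rowSums(fast$cases) + 1L, 13L)
  ks <- tabulate(rowSums(slow$cases) + 1L, 13L)
  keep <- kf + ks > 10
  expect_gt(suppressWarnings(
    chisq.test(rbind(kf[keep], ks[keep]))$p.value), 1e-3)
  # per-SNP case frequencies agree too
  expect_equal(colMeans(fast$cases), colMeans(slow$cases), tolerance = 0.02)
})

test_that("no ascertainment at 50% prevalence with null effects", {
  m <- disease_model("liability", 0.5, rep(0.25, 10),
                     liability_effects = rep(0, 10))
  coh <- sample_case_control(m, 5000, 5000, seed = 2)
  expect_lt(max(abs(colMeans(coh$cases) - colMeans(coh$controls))), 0.05)
})

test_that("liability cases over-carry risk alleles; risch cases stay uncorrelated", {
  ml <- scz_model()
  coh <- sample_case_control(ml, 5000, 5000, seed = 4)
  expect_gt(mean(rowSums(coh$cases)), mean(rowSums(coh$controls)))
  # liability: positive-effect pairs anti-correlated among cases
  Rl <- cor(coh$cases)
  expect_lt(mean(Rl[upper.tri(Rl)]), 0)
  # risch: independence of SNPs among cases is preserved
  mr <- disease_model("risch", 0.01, rep(0.2, 50), odds_ratios = rep(1.2, 50))
  cr <- sample_case_control(mr, 5000, 10, seed = 5)
  Rr <- cor(cr$cases)
  off <- Rr[upper.tri(Rr)]
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)))
})

test_that("misclassified cohorts interpolate between cases and controls", {
  m <- scz_model(n_snps = 40)
  full <- make_misclassified_cohort(m, 2000, 100, 1, seed = 6)
  expect_true(all(full$truth$is_true_case))
  none <- make_misclassified_cohort(m, 2000, 2000, 0, seed = 7)
  expect_false(any(none$truth$is_true_case))
  # fraction 0: the "cases" are controls in distribution
  expect_lt(max(abs(colMeans(none$cases) - 2 * m$allele_freqs)), 0.05)
  half <- make_misclassified_cohort(m, 2000, 100, 0.5, seed = 8)
  expect_equal(sum(half$truth$is_true_case), 1000)
  expect_gt(mean(rowSums(half$cases[half$truth$is_true_case, ])),
            mean(rowSums(half$cases[!half$truth$is_true_case, ])))
})

test_that("subtype cohorts produce the expected correlation structure", {
  # two disjoint equal subtypes: within-subtype SNP pairs positively
  # correlated among cases, cross-subtype pairs negatively correlated
  p <- rep(0.5, 20)
  base <- disease_model("liability", 0.05, p, liability_effects = rep(0, 20))
  eff <- subtype_effects(20, 2, 0.25, 0.5)
  expect_equal(dim(eff), c(2L, 20L))
  expect_true(all(eff[1, 11:20] == 0) && all(eff[2, 1:10] == 0))
  coh <- sample_subtype_cohort(eff, base, 6000, 100, seed = 9)
  expect_equal(table(coh$truth$subtype)[[1]], 3000)
  R <- cor(coh$cases)
  within <- c(R[1:10, 1:10][upper.tri(R[1:10, 1:10])],
              R[11:20, 11:20][upper.tri(R[11:20, 11:20])])
  cross <- as.vector(R[1:10, 11:20])
  expect_gt(mean(within), 0)
  expect_lt(mean(cross), 0)
  expect_gt(mean(within), mean(cross) + 0.01)
})

test_that("one-subtype sampling reduces to homogeneous case sampling", {
  p <- rep(0.2, 15)
  beta <- beta_for_ve(0.1, p)
  base <- disease_model("liability", 0.05, p, liability_effects = rep(0, 15))
  one <- sample_subtype_cohort(matrix(beta, 1, 15), base, 4000, 10, seed = 10)
  hom <- sample_case_control(
    disease_model("liability", 0.05, p, liability_effects = rep(beta, 15)),
    4000, 10, seed = 11)
  expect_equal(colMeans(one$cases), colMeans(hom$cases), tolerance = 0.04)
})

test_that("stratified controls realise the requested fixation index", {
  base <- scz_model(af = 0.5)
  coh <- sample_stratified_cohort(0.05, base, 500, 20000, seed = 12)
  expect_equal(coh$spec$p_offset, sqrt(0.05) / 2, tolerance = 1e-12)
  # Weir-style two-population estimator on the labelled controls
  g <- coh$truth$control_group
  p1 <- colMeans(coh$controls[g == 1, ]) / 2
  p2 <- colMeans(coh$controls[g == 2, ]) / 2
  pbar <- (p1 + p2) / 2
  fst_hat <- mean((p1 - p2)^2 / 4 / (pbar * (1 - pbar)))
  expect_equal(fst_hat, 0.05, tolerance = 0.01)
  # f_st = 0 reduces to unstratified sampling
  flat <- sample_stratified_cohort(0, base, 2000, 2000, seed = 13)
  expect_lt(max(abs(colMeans(flat$controls) - 1)), 0.1)
  expect_gt(mean(rowSums(flat$cases)), mean(rowSums(flat$controls)))
  expect_error(sample_stratified_cohort(0.6, base, 10, 10), "0.5")
})

test_that("expression cohorts match their model moments", {
  em <- expression_model(100, 10, 0.1, 0.5, 0.01)
  # stated identity: Var(eps) = (1 - VE2)/VE2 * Var(Z alpha) with unit Y*
  expect_equal(em$eps_sd^2, 0.5)
  expect_equal(drop(crossprod(em$gene_trait_effects,
                              em$sigma_z %*% em$gene_trait_effects)), 0.5)
  ec <- simulate_expression_cohort(em, 500, 20000, seed = 14)
  v <- apply(ec$controls, 2, var)
  expect_equal(mean(v), 1, tolerance = 0.05)
  # control gene-gene correlation: near the shared-SNP prior VG2 but
  # depressed by the lower-tail liability truncation of controls, matching
  # the analytic truncated-Gaussian value
  R0 <- cor(ec$controls)
  ctrl_expect <- expected_expression_correlation(em, "control")
  expect_lt(abs(mean(R0[upper.tri(R0)]) -
                  mean(ctrl_expect[upper.tri(ctrl_expect)])), 0.01)
  expect_lt(mean(R0[upper.tri(R0)]), 0.1)
  # homogeneous cases: correlations depressed relative to controls
  em2 <- expression_model(100, 10, 0.1, 0.1, 0.01)
  ec2 <- simulate_expression_cohort(em2, 8000, 8000, seed = 15)
  Rc <- cor(ec2$cases); R0c <- cor(ec2$controls)
  expect_lt(mean(Rc[upper.tri(Rc)]), mean(R0c[upper.tri(R0c)]))
})

test_that("quantitative cohorts have unit phenotype variance and valid labels", {
  for (h2 in c(0.05, 0.3)) {
    q <- quant_model(50, h2, mixture_fraction = 0.5)
    coh <- simulate_quantitative_cohort(q, 20000, seed = round(100 * h2))
    expect_equal(var(coh$phenotype), 1, tolerance = 0.05)
    expect_equal(mean(coh$truth$prs_dependent), 0.5)
    # PRS-phenotype correlation only in the PRS-dependent half
    prs <- drop(sweep(coh$genotypes, 2, 1) %*% q$effects)
    dep <- coh$truth$prs_dependent
    expect_equal(cor(prs[dep], coh$phenotype[dep]), sqrt(h2),
                 tolerance = 0.05)
    expect_lt(abs(cor(prs[!dep], coh$phenotype[!dep])), 0.03)
  }
})
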