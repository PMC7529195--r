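test_that("mixture correlation vanishes in single-subgroup limits and matches the two-point oracle", {
  expect_equal(mixture_correlation(0, c(0, 0), c(1, 1), c(1, 1), c(1, 1)), 0)
  expect_equal(mixture_correlation(1, c(0, 0), c(1, 1), c(1, 1), c(1, 1)), 0)
  # even mixture of unit-variance subgroups with means 0 and 1:
  # cov = 0.25, var = 1.25 per predictor
  expect_equal(mixture_correlation(0.5, c(0, 0), c(1, 1), c(1, 1), c(1, 1)),
               0.2)
  # brute-force two-point-mixture moment oracle at an asymmetric pi
  pi <- 0.3; mu_m <- c(-0.2, 0.1); mu_p <- c(0.8, 1.4); sd_m <- c(1, 1.2)
  sd_p <- c(0.9, 1.1)
  exy <- pi * prod(mu_m) + (1 - pi) * prod(mu_p)
  ex <- pi * mu_m + (1 - pi) * mu_p
  vx <- pi * (sd_m^2 + mu_m^2) + (1 - pi) * (sd_p^2 + mu_p^2) - ex^2
  expect_equal(mixture_correlation(pi, mu_m, mu_p, sd_m, sd_p),
               (exy - prod(ex)) / sqrt(prod(vx)))
})

test_that("approximate weights rescale the exact weights by the squared case-subgroup proportion", {
  mu_minus <- c(0.1, -0.3, 0.2)
  mu_plus <- c(0.9, 0.5, 1.1)
  sd_minus <- c(1, 0.8, 1.2)
  w_exact <- continuous_weights(mu_plus, mu_minus, sd_minus)
  expect_equal(continuous_weights(mu_minus, mu_minus, sd_minus),
               matrix(0, 3, 3))
  for (pi in c(0.5, 0.3)) {
    mu_whole <- pi * mu_minus + (1 - pi) * mu_plus
    w_hat <- continuous_weights(mu_whole, mu_minus, sd_minus)
    expect_equal(w_hat / w_exact,
                 matrix((1 - pi)^2, 3, 3), tolerance = 1e-12)
  }
  # the constant rescale leaves the aggregated score unchanged
  set.seed(31)
  dR <- matrix(rnorm(9), 3); dR <- dR + t(dR); diag(dR) <- 0
  agg <- function(W) sum(W[upper.tri(W)] * dR[upper.tri(dR)]) /
    sqrt(sum(W[upper.tri(W)]^2))
  w_hat <- continuous_weights(0.5 * mu_minus + 0.5 * mu_plus, mu_minus,
                              sd_minus)
  expect_equal(agg(w_hat), agg(w_exact))
})

test_that("binary predictors recover the case/control SNP weight structure", {
  # a 0/1 Bernoulli predictor with control frequency p0 and case frequency
  # p1: mean difference p1 - p0, control sd sqrt(p0(1-p0)); the pairwise
  # continuous weight then factorises into per-predictor terms proportional
  # to the odds-ratio weight of the discrete test
  p0 <- c(0.2, 0.4); p1 <- c(0.3, 0.55)
  w_cont <- continuous_weights(p1, p0, sqrt(p0 * (1 - p0)))
  per <- (p1 - p0) / sqrt(p0 * (1 - p0))
  expect_equal(w_cont, outer(per, per))
  # with the classical odds ratio the discrete weight collapses to the
  # frequency difference, so the pairwise weight is the product of the
  # discrete weights scaled by the control sds (checked on a grid)
  for (a in seq(0.1, 0.7, by = 0.2)) for (d in c(0.02, 0.1)) {
    or <- (a + d) * (1 - a) / (a * (1 - a - d))
    expect_equal(snp_weight(a, or), d, tolerance = 1e-12)
  }
  w_disc <- snp_weight(p0, p1 * (1 - p0) / (p0 * (1 - p1)))
  expect_equal(w_cont, outer(w_disc / sqrt(p0 * (1 - p0)),
                             w_disc / sqrt(p0 * (1 - p0))))
})

test_that("truncated-Gaussian case/control correlations match simulation", {
  em <- expression_model(100, 8, 0.15, 0.2, 0.05)
  pred_case <- expected_expression_correlation(em, "case")
  pred_ctrl <- expected_expression_correlation(em, "control")
  pred_pop <- expected_expression_correlation(em, "population")
  # ascertainment depresses case correlations below the shared-SNP prior
  expect_lt(mean(pred_case[upper.tri(pred_case)]),
            mean(pred_pop[upper.tri(pred_pop)]))
  n <- 30000
  ec <- simulate_expression_cohort(em, n, n, seed = 32)
  for (side in c("cases", "controls")) {
    R <- cor(ec[[side]])
    pred <- if (side == "cases") pred_case else pred_ctrl
    dev <- atanh(R[upper.tri(R)]) - atanh(pred[upper.tri(pred)])
    # Fisher-transformed deviations have sd ~ 1/sqrt(n-3) around the
    # analytic values; the mean deviation must be a null draw
    expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(sum(upper.tri(R))))
    expect_equal(sd(dev), 1 / sqrt(n - 3), tolerance = 0.35)
  }
})

test_that("unascertained predictors keep their prior correlations", {
  em <- expression_model(50, 6, 0.1, 0.3, 0.2)
  pop <- expected_expression_correlation(em, "population")
  expect_equal(pop, cov2cor(em$sigma_z))
  tm <- cliphet:::.trunc_liab_moments(em$threshold, "population")
  expect_equal(tm$delta, 0)
})

test_that("CLiP-X scores: calibration, invariance, and detection", {
  em <- expression_model(100, 10, 0.1, 0.1, 0.01)
  set.seed(33)
  # control-vs-control calibration
  s <- replicate(60, {
    a <- simulate_expression_cohort(em, 1, 1500)$controls
    b <- simulate_expression_cohort(em, 1, 1500)$controls
    clipx_score(a, b, null = "zero")$score
  })
  expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(length(s)))
  expect_gt(sd(s), 0.7); expect_lt(sd(s), 1.3)
  # affine rescaling of predictor columns leaves the score unchanged
  ec <- simulate_expression_cohort(em, 1500, 1500, seed = 34)
  base <- clipx_score(ec$cases, ec$controls, null = "analytic", spec = em)
  sc <- runif(10, 0.5, 3); sh <- rnorm(10)
  resc <- clipx_score(sweep(sweep(ec$cases, 2, sc, `*`), 2, sh, `+`),
                      sweep(sweep(ec$controls, 2, sc, `*`), 2, sh, `+`),
                      null = "analytic", spec = em)
  expect_equal(resc$score, base$score, tolerance = 1e-10)
  expect_equal(resc$z, base$z, tolerance = 1e-10)
  # homogeneous cases sit near the analytic null; an even mixture is
  # detected against it
  set.seed(35)
  zs <- replicate(10, {
    e <- simulate_expression_cohort(em, 1500, 3000)
    mix <- rbind(e$cases,
                 simulate_expression_cohort(em, 1, 1500)$controls)
    c(hom = clipx_score(e$cases, e$controls,
                        null = "analytic", spec = em)$z,
      het = clipx_score(mix, e$controls, null = "analytic", spec = em)$z)
  })
  expect_gt(mean(zs["het", ]), 2)
  expect_error(clipx_score(matrix(rnorm(10), 10), matrix(rnorm(10), 10),
                           null = "zero"),
               "two predictors")
})

test_that("Monte-Carlo null agrees with the analytic null", {
  em <- expression_model(60, 6, 0.1, 0.15, 0.02)
  ec <- simulate_expression_cohort(em, 800, 800, seed = 36)
  mc <- clipx_score(ec$cases, ec$controls, null = "mc", spec = em,
                    n_null_reps = 40, seed = 37)
  an <- clipx_score(ec$cases, ec$controls, null = "analytic", spec = em)
  expect_lt(abs(mc$expected_null - an$expected_null),
            4 * mc$null_se + 0.2)
})
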