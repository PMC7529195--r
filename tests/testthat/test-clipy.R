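test_that("mid-rank percentiles follow the convention and survive monotone maps", {
  expect_equal(phenotype_to_percentiles(c(3, 8, 10, 21, 40)),
               c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(phenotype_to_percentiles(rep(2, 4)), rep(0.5, 4))
  y <- rnorm(50)
  expect_equal(phenotype_to_percentiles(y),
               phenotype_to_percentiles(exp(3 * y) - 1))
  expect_error(phenotype_to_percentiles(c(1, NA)), "finite")
})

test_that("normalised weights are proper and recover the expected special cases", {
  y <- c(5, 1, 9, 3)
  expect_equal(normalized_weights(y, weight_function("uniform")), rep(0.25, 4))
  # step at the median: upper half gets 1/2 each
  expect_equal(normalized_weights(y, weight_function("step", 0.5)),
               c(0.5, 0, 0.5, 0))
  # polynomial with negative dips is floored then normalised
  wf <- weight_function("polynomial", coefficients = c(-0.25, 1))
  phi <- normalized_weights(seq(0.1, 1, 0.1) + rnorm(10, sd = 1e-8), wf)
  expect_true(all(phi >= 0))
  expect_equal(sum(phi), 1)
  expect_true(any(phi == 0))
  expect_error(normalized_weights(y,
      weight_function("polynomial", coefficients = c(-10, 0, 0))), "zero")
})

test_that("weighted correlations reduce to Pearson under uniform and dichotomous weights", {
  set.seed(41)
  x <- matrix(rbinom(400 * 8, 2, 0.4), ncol = 8)
  n <- nrow(x)
  wc <- weighted_correlation(x, rep(1 / n, n))
  expect_equal(wc$corr, cor(x), tolerance = 1e-10, ignore_attr = TRUE)
  # dichotomous weights: correlation within the selected subset
  sel <- seq_len(150)
  phi <- rep(0, n); phi[sel] <- 1 / length(sel)
  wcd <- weighted_correlation(x, phi)
  expect_equal(wcd$corr, cor(x[sel, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(wcd$scale, 1 / 150 - 1 / n)
  # all weight on one individual: zero weighted variance
  one <- rep(0, n); one[1] <- 1
  expect_error(weighted_correlation(x, one), "zero weighted variance")
})

test_that("phenotype-weighted SNP weights vanish at equal frequencies and match the dichotomous form", {
  set.seed(42)
  x <- matrix(rbinom(600 * 6, 2, 0.3), ncol = 6)
  n <- nrow(x)
  expect_equal(clipy_snp_weights(x, rep(1 / n, n)), rep(0, 6))
  sel <- sample(n, 200)
  phi <- rep(0, n); phi[sel] <- 1 / 200
  p_phi <- colMeans(x[sel, ]) / 2
  p0 <- colMeans(x) / 2
  gamma <- p_phi * (1 - p_phi) / (p0 * (1 - p0))
  expect_equal(clipy_snp_weights(x, phi), snp_weight(p0, gamma))
})

test_that("dichotomous CLiP-Y equals case/control CLiP up to the scale-factor ratio", {
  # Build a cohort where pseudo-cases (upper phenotype half) are enriched
  # for every risk allele, so no allele flips interfere.
  set.seed(43)
  n <- 3000; m <- 12
  q <- quant_model(m, 0.4)
  coh <- simulate_quantitative_cohort(q, n)
  x <- coh$genotypes; y <- coh$phenotype
  wf <- weight_function("step", 0.5)
  res_y <- clipy_score(x, y, wf)
  # the induced pseudo-cohort: cases above the median, "controls" = everyone
  sel <- phenotype_to_percentiles(y) >= 0.5
  n_phi <- sum(sel)
  p0 <- colMeans(x) / 2
  p_phi <- colMeans(x[sel, ]) / 2
  expect_true(all(p_phi > p0))
  st <- summary_stats(paste0("s", 1:m), p0,
                      or = p_phi * (1 - p_phi) / (p0 * (1 - p0)),
                      prevalence = 0.01)
  res_cc <- clip_score(x[sel, ], x, st, null = "zero")
  # scale factors: 1/s = N^phi N / (N - N^phi) for CLiP-Y versus
  # N^phi N / (N + N^phi) in the case/control score
  ratio <- sqrt((n + n_phi) / (n - n_phi))
  expect_equal(res_y$score, res_cc$score * ratio, tolerance = 1e-8)
  # the documented worked example: N = 4, N^phi = 2 gives 1/s = 4
  expect_equal(1 / (sum(rep(c(0, 0.5), each = 2)^2) - 1 / 4), 4)
})

test_that("CLiP-Y is invariant under monotone phenotype transforms", {
  set.seed(44)
  q <- quant_model(20, 0.2, mixture_fraction = 0.5)
  coh <- simulate_quantitative_cohort(q, 4000)
  for (wf in list(weight_function("sigmoid"), clipy_default_polynomial(6))) {
    a <- clipy_score(coh$genotypes, coh$phenotype, wf)
    b <- clipy_score(coh$genotypes, 1 - exp(-coh$phenotype), wf)
    expect_equal(a$score, b$score)
  }
})

test_that("uniform weights make the statistic undefined", {
  set.seed(45)
  x <- matrix(rbinom(200 * 5, 2, 0.5), ncol = 5)
  expect_error(clipy_score(x, rnorm(200), weight_function("uniform")),
               "undefined")
})

test_that("genotype-independent phenotypes give calibrated null scores", {
  set.seed(46)
  wfs <- list(step = weight_function("step"),
              sigmoid = weight_function("sigmoid"),
              poly6 = clipy_default_polynomial(6))
  for (wname in names(wfs)) {
    s <- replicate(60, {
      x <- matrix(rbinom(4000 * 15, 2, 0.5), ncol = 15)
      clipy_score(x, rnorm(4000), wfs[[wname]])$score
    })
    expect_lt(abs(mean(s)), 0.4)
    expect_gt(var(s), 0.6); expect_lt(var(s), 1.7)
  }
})

test_that("simulated null estimate is near zero for a vanishing PRS signal", {
  q <- quant_model(10, 1e-4)
  est <- estimate_clipy_null(q, 1000, weight_function("step"), n_reps = 40,
                             seed = 47)
  expect_lt(abs(est$expected), 4 * est$se + 0.1)
})

test_that("the local search returns its starting point when frozen and improves when run", {
  q <- quant_model(30, 0.15)
  init <- c(0.2, 1, -0.5)
  frozen <- learn_polynomial_weights(q, 1500, degree = 2, n_train = 2,
                                     n_val = 2, iterations = 5,
                                     step_scale = 0, init = init, seed = 48)
  expect_equal(frozen$coefficients, init)
  learned <- learn_polynomial_weights(q, 2000, degree = 2, n_train = 4,
                                      n_val = 8, iterations = 60,
                                      step_scale = 0.2, seed = 49)
  expect_s3_class(learned, "clip_weight_fn")
  traj <- attr(learned, "trajectory")
  expect_true(all(diff(traj) > 0))
  expect_gt(length(traj), 1)
})

test_that("homogeneous quantitative cohorts score below their PRS-independent null", {
  set.seed(50)
  q <- quant_model(50, 0.2)
  wf <- weight_function("step")
  s <- replicate(8, {
    coh <- simulate_quantitative_cohort(q, 10000)
    clipy_score(coh$genotypes, coh$phenotype, wf)$score
  })
  expect_lt(mean(s), -2)
})
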