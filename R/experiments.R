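# Experiment drivers reproducing the package's simulation designs as tidy
# per-trial tables.

# Score one case/control cohort under both nulls; returns a one-row frame.
.score_cohort_row <- function(coh, stats, prevalence, expected_null) {
  res <- clip_score(coh$cases, coh$controls, stats, null = "zero")
  z_li <- res$score - expected_null
  data.frame(score = res$score, expected_null = expected_null,
             z_liability = z_li,
             p_liability = stats::pnorm(z_li, lower.tail = FALSE),
             z_zero = res$score,
             p_zero = stats::pnorm(res$score, lower.tail = FALSE))
}

.exp_defaults <- list(
  power_vs_size = list(n_trials = 20, n_cases = 10000, n_controls = 10000,
                    n_snps = 100, af = 0.2, ve = 0.034, prevalence = 0.01,
                    fraction = 0.5,
                    cohorts = c("control", "homogeneous", "heterogeneous")),
  fraction_sweep = list(n_trials = 10, n_cases = 10000, n_controls = 10000,
                        n_snps = 100, af = 0.2, ve = 0.05,
                        prevalence = 0.01,
                        fractions = seq(0, 1, by = 0.1)),
  fst_robustness = list(n_trials = 20, n_cases = 30000, n_controls = 30000,
                        n_snps = 100, ve = 0.034, prevalence = 0.01,
                        fst = c(0, 0.01, 0.02, 0.05),
                        cohorts = c("homogeneous", "heterogeneous")),
  subtype_spectrum = list(n_trials = 10, n_cases = 30000, n_controls = 30000,
                       n_snps = 100, af = 0.2, block_ve = 0.034,
                       prevalence = 0.01,
                       effect_ratios = seq(0, 1, by = 0.25)),
  weight_comparison = list(n_trials = 10, n_individuals = 200000, n_snps = 100,
                      h2 = c(0.05, 0.1), n_null_reps = 20,
                      weight_fns = NULL),
  expression_power = list(n_trials = 20, n_cases = c(1000, 5000, 10000),
                    n_snps = 100, n_genes = 10, vg2 = 0.1, ve2 = 0.1,
                    prevalence = 0.01,
                    cohorts = c("control", "homogeneous", "heterogeneous"))
)

#' Run a named simulation experiment
#'
#' Regenerates the package's simulation designs — CLiP power versus the
#' zero null (`power_vs_size`), the misclassification-fraction sweep
#' (`fraction_sweep`), robustness to two-subpopulation structure
#' (`fst_robustness`), the misclassification-to-subtype spectrum
#' (`subtype_spectrum`), CLiP-Y weight-function comparison (`weight_comparison`),
#' and CLiP-X over continuous predictors (`expression_power`) — as a tidy
#' per-trial results table. Default parameters follow the study designs;
#' any entry can be overridden through `config` (e.g. fewer trials or
#' smaller cohorts for smoke tests).
#'
#' @param name Experiment name.
#' @param config Named list of overrides of the experiment's defaults.
#' @param seed Optional integer seed making the whole run deterministic.
#' @return A `data.frame` with one row per scored cohort: the experiment's
#'   varied parameter, trial index, cohort type, both scores/nulls/z/p where
#'   applicable.
#' @seealso [summarize_experiment()]
#' @export
run_experiment <- function(name = names(.exp_defaults), config = list(),
                           seed = NULL) {
  name <- match.arg(name)
  cfg <- utils::modifyList(.exp_defaults[[name]], config)
  with_seed_if(seed, switch(name,
    power_vs_size = .exp_power_vs_size(cfg),
    fraction_sweep = .exp_fraction(cfg),
    fst_robustness = .exp_fst(cfg),
    subtype_spectrum = .exp_subtype_spectrum(cfg),
    weight_comparison = .exp_weight_comparison(cfg),
    expression_power = .exp_expression_power(cfg)))
}

#' Summarise an experiment table
#'
#' Per parameter/cohort-type group: mean and standard deviation of the
#' score, and the fraction of trials declared heterogeneous at the
#' one-sided 95% threshold under each null (the sensitivity for
#' heterogeneous cohorts; one minus the specificity for homogeneous or
#' control cohorts).
#'
#' @param trials A table from [run_experiment()].
#' @return A summary `data.frame`, one row per group.
#' @export
summarize_experiment <- function(trials) {
  stopifnot(is.data.frame(trials))
  keys <- intersect(c("experiment", "cohort_type", "param_name",
                      "param_value", "n_cases", "weight_fn"),
                    colnames(trials))
  agg <- function(f, col) stats::aggregate(trials[[col]],
                                           trials[keys], f)
  out <- agg(mean, "score")
  names(out)[ncol(out)] <- "mean_score"
  out$sd_score <- agg(stats::sd, "score")$x
  if ("p_liability" %in% colnames(trials)) {
    out$positive_rate_liability <- agg(function(p) mean(p < 0.05),
                                       "p_liability")$x
    out$positive_rate_zero <- agg(function(p) mean(p < 0.05), "p_zero")$x
  }
  out
}

.liability_model <- function(cfg) {
  p <- rep(cfg$af, cfg$n_snps)
  disease_model("liability", cfg$prevalence, p,
                liability_effects = rep(beta_for_ve(cfg$ve, p), cfg$n_snps))
}

.model_stats <- function(model) {
  summary_stats(paste0("snp", seq_len(model$n_snps)), model$allele_freqs,
                beta = model$liability_effects,
                prevalence = model$prevalence)
}

.exp_power_vs_size <- function(cfg) {
  model <- .liability_model(cfg)
  stats_df <- .model_stats(model)
  rows <- list()
  for (n_ca in cfg$n_cases) {
    e_null <- expected_homogeneous_score(stats_df, n_ca, cfg$n_controls)
    for (trial in seq_len(cfg$n_trials)) for (type in cfg$cohorts) {
      coh <- switch(type,
        control = new_cohort(sim_genotypes(n_ca, model$allele_freqs),
                             sim_genotypes(cfg$n_controls,
                                           model$allele_freqs)),
        homogeneous = sample_case_control(model, n_ca, cfg$n_controls),
        heterogeneous = make_misclassified_cohort(model, n_ca,
                                                  cfg$n_controls,
                                                  cfg$fraction))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(experiment = "power_vs_size", trial = trial,
                   cohort_type = type, param_name = "n_cases",
                   param_value = n_ca, n_cases = n_ca,
                   n_controls = cfg$n_controls),
        .score_cohort_row(coh, stats_df, cfg$prevalence, e_null))
    }
  }
  do.call(rbind, rows)
}

.exp_fraction <- function(cfg) {
  model <- .liability_model(cfg)
  stats_df <- .model_stats(model)
  e_null <- expected_homogeneous_score(stats_df, cfg$n_cases,
                                       cfg$n_controls)
  rows <- list()
  for (f in cfg$fractions) for (trial in seq_len(cfg$n_trials)) {
    coh <- make_misclassified_cohort(model, cfg$n_cases, cfg$n_controls, f)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(experiment = "fraction_sweep", trial = trial,
                 cohort_type = "mixture", param_name = "true_case_fraction",
                 param_value = f, n_cases = cfg$n_cases,
                 n_controls = cfg$n_controls),
      .score_cohort_row(coh, stats_df, cfg$prevalence, e_null))
  }
  do.call(rbind, rows)
}

.exp_fst <- function(cfg) {
  p <- rep(0.5, cfg$n_snps)     # nominal frequencies for stats and weights
  model <- disease_model("liability", cfg$prevalence, p,
                         liability_effects = rep(beta_for_ve(cfg$ve, p),
                                                 cfg$n_snps))
  stats_df <- .model_stats(model)
  e_null <- expected_homogeneous_score(stats_df, cfg$n_cases,
                                       cfg$n_controls)
  rows <- list()
  for (fst in cfg$fst) for (trial in seq_len(cfg$n_trials)) {
    hom <- sample_stratified_cohort(fst, model, cfg$n_cases,
                                    cfg$n_controls)
    sets <- list(homogeneous = hom)
    if ("heterogeneous" %in% cfg$cohorts) {
      n_true <- ceiling(cfg$n_cases / 2)
      het_cases <- rbind(hom$cases[seq_len(n_true), , drop = FALSE],
                         sample_stratified_cohort(fst, model,
                                                  2L,
                                                  cfg$n_cases - n_true)$controls)
      sets$heterogeneous <- new_cohort(het_cases, hom$controls)
    }
    for (type in intersect(cfg$cohorts, names(sets))) {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(experiment = "fst_robustness", trial = trial,
                   cohort_type = type, param_name = "f_st",
                   param_value = fst, n_cases = cfg$n_cases,
                   n_controls = cfg$n_controls),
        .score_cohort_row(sets[[type]], stats_df, cfg$prevalence, e_null))
    }
  }
  do.call(rbind, rows)
}

.exp_subtype_spectrum <- function(cfg) {
  p <- rep(cfg$af, cfg$n_snps)
  base <- disease_model("liability", cfg$prevalence, p,
                        liability_effects = rep(0, cfg$n_snps))
  rows <- list()
  for (r in cfg$effect_ratios) for (trial in seq_len(cfg$n_trials)) {
    eff <- subtype_effects(cfg$n_snps, 2L, cfg$block_ve, cfg$af,
                           effect_ratios = c(1, r))
    coh <- sample_subtype_cohort(eff, base, cfg$n_cases, cfg$n_controls)
    marginal <- colMeans(eff)                  # GWAS-style marginal effects
    keep <- marginal > 0
    stats_df <- summary_stats(paste0("snp", which(keep)), p[keep],
                              beta = marginal[keep],
                              prevalence = cfg$prevalence)
    e_null <- expected_homogeneous_score(stats_df, cfg$n_cases,
                                         cfg$n_controls)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(experiment = "subtype_spectrum", trial = trial,
                 cohort_type = "subtype", param_name = "effect_ratio",
                 param_value = r, n_cases = cfg$n_cases,
                 n_controls = cfg$n_controls),
      .score_cohort_row(list(cases = coh$cases[, keep, drop = FALSE],
                             controls = coh$controls[, keep, drop = FALSE]),
                        stats_df, cfg$prevalence, e_null))
  }
  do.call(rbind, rows)
}

.exp_weight_comparison <- function(cfg) {
  wfs <- cfg$weight_fns
  if (is.null(wfs))
    wfs <- list(step = weight_function("step"),
                sigmoid = weight_function("sigmoid"),
                linear = weight_function("linear"),
                neglog1m = weight_function("neglog1m"),
                poly6 = clipy_default_polynomial(6))
  rows <- list()
  for (h2 in cfg$h2) {
    het <- quant_model(cfg$n_snps, h2, mixture_fraction = 0.5)
    for (wname in names(wfs)) {
      null_est <- estimate_clipy_null(het, cfg$n_individuals, wfs[[wname]],
                                      n_reps = cfg$n_null_reps)
      for (trial in seq_len(cfg$n_trials)) {
        coh <- simulate_quantitative_cohort(het, cfg$n_individuals)
        res <- clipy_score(coh$genotypes, coh$phenotype, wfs[[wname]],
                           null = null_est$expected)
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = "weight_comparison", trial = trial,
          cohort_type = "heterogeneous", weight_fn = wname,
          param_name = "h2", param_value = h2,
          n_cases = cfg$n_individuals, n_controls = NA,
          score = res$score, expected_null = res$expected_null,
          z_liability = res$z, p_liability = res$p_value,
          z_zero = res$score,
          p_zero = stats::pnorm(res$score, lower.tail = FALSE))
      }
    }
  }
  do.call(rbind, rows)
}

.exp_expression_power <- function(cfg) {
  spec <- expression_model(cfg$n_snps, cfg$n_genes, cfg$vg2, cfg$ve2,
                           cfg$prevalence)
  rows <- list()
  for (n_ca in cfg$n_cases) {
    e_null <- expected_clipx_score(spec, n_ca, n_ca)
    for (trial in seq_len(cfg$n_trials)) for (type in cfg$cohorts) {
      base <- simulate_expression_cohort(spec, n_ca, n_ca)
      zmat <- switch(type,
        control = base$controls[seq_len(n_ca), , drop = FALSE],
        homogeneous = base$cases,
        heterogeneous = {
          n_true <- ceiling(n_ca / 2)
          extra <- simulate_expression_cohort(spec, 1L, n_ca - n_true)
          rbind(base$cases[seq_len(n_true), , drop = FALSE],
                extra$controls)
        })
      ctrl <- if (type == "control")
        simulate_expression_cohort(spec, 1L, n_ca)$controls
      else base$controls
      res <- clipx_score(zmat, ctrl, null = "zero")
      z_li <- res$score - e_null
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = "expression_power", trial = trial, cohort_type = type,
        param_name = "n_cases", param_value = n_ca, n_cases = n_ca,
        n_controls = n_ca, score = res$score, expected_null = e_null,
        z_liability = z_li,
        p_liability = stats::pnorm(z_li, lower.tail = FALSE),
        z_zero = res$score,
        p_zero = stats::pnorm(res$score, lower.tail = FALSE))
    }
  }
  do.call(rbind, rows)
}
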