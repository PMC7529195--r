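# Shared fixtures built in code for the test suite.

# Schizophrenia-scale liability architecture: 100 SNPs at frequency 0.2
# jointly explaining 3.4% of liability variance, prevalence 1%.
scz_model <- function(n_snps = 100, af = 0.2, ve = 0.034, prevalence = 0.01) {
  p <- rep(af, n_snps)
  disease_model("liability", prevalence, p,
                liability_effects = rep(beta_for_ve(ve, p), n_snps))
}

model_stats <- function(model) {
  summary_stats(paste0("snp", seq_len(model$n_snps)), model$allele_freqs,
                beta = model$liability_effects,
                prevalence = model$prevalence)
}

# Independent control-vs-control "cohort": both matrices drawn from the
# population, the exact null of the case/control score.
null_cohort <- function(n, n0, allele_freqs) {
  list(cases = cliphet:::sim_genotypes(n, allele_freqs),
       controls = cliphet:::sim_genotypes(n0, allele_freqs))
}
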