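# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG state untouched; with seed = NULL the global stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a deterministic 32-bit sub-seed from a parent seed and a stream name,
# so independent sampling stages (genotypes, noise, labels) are reproducible
# in isolation.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% 2147483587L
}

# Binomial(2, p_j) genotype matrix, individuals in rows.
sim_genotypes <- function(n, allele_freqs) {
  m <- length(allele_freqs)
  matrix(stats::rbinom(n * m, 2L, rep(allele_freqs, each = n)), nrow = n, ncol = m)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop(sprintf("`%s` must lie strictly in (0, 1)", name), call. = FALSE)
  x
}

check_genotypes <- function(x, name = "genotypes") {
  if (!all(x %in% c(0, 1, 2)))
    stop(sprintf("`%s` must contain dosages in {0, 1, 2}", name), call. = FALSE)
  x
}

# Upper-triangle (j < k) sum of a square matrix.
upper_sum <- function(mat) {
  sum(mat[upper.tri(mat)])
}
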