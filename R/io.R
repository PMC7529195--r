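# Readers and writers for the package's delimited interchange formats:
# dosage matrices, summary-statistic tables, phenotype vectors and
# predictor matrices, plus optional VCF dosage ingestion.

#' Read a tab-delimited dosage matrix
#'
#' Expects a header line `id <snp ids...>` and one row per individual with
#' integer dosages in \{0, 1, 2\}. Gzipped files are handled
#' transparently. Constant (zero-variance) columns are retained but
#' reported through the `constant_snps` attribute so callers can exclude
#' them explicitly.
#'
#' @param path File path (optionally `.gz`).
#' @return Integer matrix (individuals x SNPs) with row names from the id
#'   column, column names from the header, and attribute `constant_snps`.
#' @export
read_dosage_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (colnames(df)[1L] != "id")
    stop("first column of a dosage file must be `id`", call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate individual ids", call. = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(x) <- "integer")
  if (anyNA(x)) stop("non-numeric dosage entries", call. = FALSE)
  check_genotypes(x, "dosage matrix")
  rownames(x) <- ids
  const <- colnames(x)[apply(x, 2L, function(v) length(unique(v)) == 1L)]
  if (length(const))
    message("constant dosage column(s): ", paste(const, collapse = ", "))
  attr(x, "constant_snps") <- const
  x
}

#' Write a dosage matrix with an optional JSON sidecar
#'
#' @param x Integer dosage matrix; row names become the id column
#'   (generated when absent).
#' @param path Output path; a `.gz` suffix enables gzip compression.
#' @param sidecar Optional list (seed, model parameters, truth labels)
#'   written as JSON next to the matrix at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(x, path, sidecar = NULL) {
  stopifnot(is.matrix(x))
  check_genotypes(x, "dosage matrix")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(x)))
  snps <- colnames(x)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(x)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", snps), collapse = "\t"), con)
  utils::write.table(data.frame(ids, x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

#' Read per-SNP summary statistics
#'
#' Reads a tab-delimited table with header columns among `snp_id`,
#' `effect_allele`, `af`, `or`, `beta` and returns a [summary_stats()]
#' table with both the odds ratio and the liability effect populated (the
#' missing one is derived at the given prevalence) and alleles oriented so
#' every odds ratio is >= 1.
#'
#' @param path File path.
#' @param prevalence Disease prevalence for the scale conversion.
#' @return A [summary_stats()] table (plus any `effect_allele` column,
#'   carried through).
#' @export
read_summary_stats <- function(path, prevalence) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("snp_id", "af") %in% colnames(df)))
    stop("summary statistics need `snp_id` and `af` columns", call. = FALSE)
  if (!any(c("or", "beta") %in% colnames(df)))
    stop("summary statistics need an `or` or `beta` column", call. = FALSE)
  out <- summary_stats(df$snp_id, df$af,
                       or = if ("or" %in% colnames(df)) df$or,
                       beta = if ("beta" %in% colnames(df)) df$beta,
                       prevalence = prevalence)
  if ("effect_allele" %in% colnames(df))
    out$effect_allele <- df$effect_allele
  out
}

#' Write a summary-statistics table
#'
#' @param stats A [summary_stats()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  utils::write.table(as.data.frame(stats)[, c("snp_id", "af", "or", "beta")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column id/value phenotype table
#'
#' @param path Tab-delimited file with header `id value` (names free; the
#'   first column is the id, the second the phenotype).
#' @return Named numeric vector of phenotypes.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("phenotype files have two columns", call. = FALSE)
  y <- as.numeric(df[[2L]])
  if (anyNA(y)) stop("non-numeric phenotype values", call. = FALSE)
  names(y) <- as.character(df[[1L]])
  y
}

#' Read a tab-delimited continuous predictor matrix
#'
#' Same layout as [read_dosage_matrix()] (id column plus named predictor
#' columns) but with real-valued entries.
#'
#' @param path File path.
#' @return Numeric matrix (individuals x predictors).
#' @export
read_predictor_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (colnames(df)[1L] != "id")
    stop("first column of a predictor file must be `id`", call. = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("non-numeric predictor entries", call. = FALSE)
  rownames(x) <- as.character(df[[1L]])
  x
}

#' Extract a dosage matrix from a VCF file
#'
#' Import-only convenience for diploid autosomal genotypes: GT fields are
#' mapped to effect-allele counts (0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2);
#' missing or non-diploid genotypes are an error.
#'
#' @param path VCF path (optionally gzipped).
#' @return Integer dosage matrix (individuals x variants).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the `vcfR` package is required for VCF ingestion", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (length(alleles) != 2L || !all(alleles %in% c("0", "1")))
      return(NA_integer_)
    sum(alleles == "1")
  })
  if (anyNA(counts))
    stop("missing or non-diploid-biallelic genotypes in VCF", call. = FALSE)
  t(counts)
}
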