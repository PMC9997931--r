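#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM scale factors: for each sample the weighted mean
#' of gene-wise log2 ratios (M-values) to a reference sample, after trimming
#' `trim_m` of the most extreme M-values and `trim_a` of the most extreme
#' average intensities, with inverse delta-method binomial variances as
#' weights. Factors are rescaled to geometric mean 1. The reference defaults
#' to the sample whose 75th count percentile is closest to the mean across
#' samples. Computation is delegated to the reference implementation in
#' \pkg{edgeR} (`calcNormFactors`), which this wrapper validates against the
#' stated contract.
#'
#' @param dataset a [count_dataset()].
#' @param trim_m fraction of M-values trimmed on each side (default 0.30).
#' @param trim_a fraction of A-values trimmed on each side (default 0.05).
#' @param reference optional reference sample index.
#' @return an object of class `norm_factors`: list with `factors`,
#'   `lib_sizes` and `effective` (their product).
#' @export
tmm_factors <- function(dataset, trim_m = 0.30, trim_a = 0.05,
                        reference = NULL) {
  stopifnot(inherits(dataset, "count_dataset"))
  if (ncol(dataset$counts) < 2L) stop_msg("need at least 2 samples for TMM")
  if (any(dataset$library_sizes <= 0))
    stop_msg("every sample must have a positive library size")
  f <- edgeR::calcNormFactors(dataset$counts, method = "TMM",
                              refColumn = reference,
                              logratioTrim = trim_m, sumTrim = trim_a)
  f <- as.numeric(f)
  f <- f / exp(mean(log(f)))
  structure(list(factors = f,
                 lib_sizes = as.numeric(dataset$library_sizes),
                 effective = f * as.numeric(dataset$library_sizes),
                 sample_ids = dataset$sample_ids),
            class = "norm_factors")
}

#' Counts per million on effective library sizes
#'
#' @param dataset a [count_dataset()].
#' @param factors a [tmm_factors()] object.
#' @return a numeric matrix of CPM values.
#' @export
cpm_matrix <- function(dataset, factors) {
  stopifnot(inherits(dataset, "count_dataset"), inherits(factors, "norm_factors"))
  eff <- factors$effective
  if (any(eff <= 0)) stop_msg("effective library sizes must be positive")
  sweep(dataset$counts, 2, eff, "/") * 1e6
}

#' Filter lowly expressed genes by mean CPM
#'
#' Keeps genes whose mean CPM across all samples (conditions pooled) is at
#' least `threshold`; gene order is preserved.
#'
#' @param dataset a [count_dataset()].
#' @param factors a [tmm_factors()] object.
#' @param threshold CPM threshold (default 1).
#' @return `list(dataset =, kept =)` where `kept` is the integer index of
#'   retained genes in the input.
#' @export
filter_low_expression <- function(dataset, factors, threshold = 1) {
  if (threshold <= 0) stop_msg("'threshold' must be > 0")
  cpm <- cpm_matrix(dataset, factors)
  kept <- unname(which(rowMeans(cpm) >= threshold))
  if (length(kept) == 0L)
    stop_msg("no gene passes the CPM >= %g filter", threshold)
  out <- count_dataset(dataset$counts[kept, , drop = FALSE],
                       condition = dataset$condition,
                       gene_ids = dataset$gene_ids[kept],
                       sample_ids = dataset$sample_ids,
                       batch = dataset$batch)
  list(dataset = out, kept = kept)
}

#' Normalized counts and their log2 transform
#'
#' Normalized counts divide each column by its relative effective library
#' size (effective size over the mean effective size), i.e. depth- and
#' composition-corrected counts on the original count scale.
#' `log_transform()` returns `log2(normalized + pseudocount)`.
#'
#' @param dataset a [count_dataset()].
#' @param factors a [tmm_factors()] object.
#' @param pseudocount positive constant added before taking logs (default 1).
#' @return a numeric matrix.
#' @export
normalized_counts <- function(dataset, factors) {
  stopifnot(inherits(dataset, "count_dataset"), inherits(factors, "norm_factors"))
  rel <- factors$effective / mean(factors$effective)
  sweep(dataset$counts, 2, rel, "/")
}

#' @rdname normalized_counts
#' @export
log_transform <- function(dataset, factors, pseudocount = 1) {
  if (pseudocount <= 0) stop_msg("'pseudocount' must be > 0")
  log2(normalized_counts(dataset, factors) + pseudocount)
}
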