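#' Two-group design with optional batch covariates and offsets
#'
#' Builds the model-matrix pieces shared by the count-based detectors: a
#' condition indicator (second level vs first), one-hot batch covariates
#' (first batch as baseline), and per-sample offsets equal to the log of the
#' relative effective library size (TMM factor times library size, divided
#' by the mean so intercepts stay on the count scale).
#'
#' @param dataset a [count_dataset()].
#' @param factors a [tmm_factors()] object (`NULL` for unit offsets).
#' @param use_batch include the dataset's batch labels as covariates.
#' @return an object of class `group_design`: list with `condition` (0/1),
#'   `X` (mean design), `Z` (dispersion design), `offset`.
#' @export
group_design <- function(dataset, factors = NULL, use_batch = TRUE) {
  stopifnot(inherits(dataset, "count_dataset"))
  cond <- as.integer(dataset$condition == levels(dataset$condition)[2])
  n <- length(cond)
  if (length(unique(cond)) != 2L) stop_msg("need samples in both conditions")
  X <- cbind(intercept = rep(1, n), condition = cond)
  if (use_batch && !is.null(dataset$batch) && nlevels(dataset$batch) > 1L) {
    B <- stats::model.matrix(~ dataset$batch)[, -1, drop = FALSE]
    colnames(B) <- paste0("batch", seq_len(ncol(B)))
    X <- cbind(X, B)
  }
  if (qr(X)$rank < ncol(X)) stop_msg("design matrix is not full rank")
  offset <- if (is.null(factors)) rep(0, n) else
    log(factors$effective / mean(factors$effective))
  structure(list(condition = cond, X = X, Z = X, offset = offset,
                 n = n), class = "group_design")
}

# standard per-gene result table shared by all detectors
detector_result <- function(gene_ids, log2_mean_fc, log2_disp_fc,
                            stat_mean, stat_disp, p_mean, p_disp,
                            converged, method, boundary = FALSE) {
  data.frame(gene_id = gene_ids,
             log2_mean_fc = log2_mean_fc,
             log2_disp_fc = log2_disp_fc,
             stat_mean = stat_mean,
             stat_disp = stat_disp,
             p_mean = pmin(pmax(p_mean, 0), 1),
             p_disp = pmin(pmax(p_disp, 0), 1),
             q_mean = NA_real_,
             q_disp = NA_real_,
             converged = converged,
             boundary = boundary,
             method = method,
             stringsAsFactors = FALSE)
}
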