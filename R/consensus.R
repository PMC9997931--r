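#' Partition genes into DE+, DE- and non-DE by the covariate-capable test
#'
#' @param mdseq_result an adjusted result from
#'   [mdseq_mean_dispersion_test()] (the detector whose GLM accepts batch
#'   covariates).
#' @param alpha significance level on `q_mean`.
#' @return list of character vectors `de_up`, `de_down`, `non_de` that
#'   partition the analyzed genes.
#' @export
call_de_genes <- function(mdseq_result, alpha = 0.05) {
  de <- !is.na(mdseq_result$q_mean) & mdseq_result$q_mean < alpha
  up <- de & mdseq_result$log2_mean_fc > 0
  list(de_up = mdseq_result$gene_id[up],
       de_down = mdseq_result$gene_id[de & !up],
       non_de = mdseq_result$gene_id[!de])
}

#' Per-method DD+/DD- calls restricted to non-DE genes
#'
#' @param results named list of adjusted detector results.
#' @param non_de character vector of non-DE gene ids.
#' @param alpha significance level on `q_disp`.
#' @return named list; per method a list `dd_up`, `dd_down`.
#' @export
call_dd_among_non_de <- function(results, non_de, alpha = 0.05) {
  lapply(results, function(res) {
    keep <- res$gene_id %in% non_de
    dd <- keep & !is.na(res$q_disp) & res$q_disp < alpha &
      !is.na(res$log2_disp_fc)
    list(dd_up = res$gene_id[dd & res$log2_disp_fc > 0],
         dd_down = res$gene_id[dd & res$log2_disp_fc < 0])
  })
}

#' Sign-validate a sensitive detector's DD calls against the robust one
#'
#' Keeps a call iff the robust detector's dispersion fold-change estimate
#' has the same sign. Calls whose robust estimate is exactly zero, missing
#' or non-converged are dropped (conservative).
#'
#' @param dd_calls character vector of called gene ids.
#' @param sensitive_result adjusted result of the detector being validated.
#' @param robust_result adjusted result of [robust_dispersion_test()].
#' @return the validated subset of `dd_calls`.
#' @export
validate_signs <- function(dd_calls, sensitive_result, robust_result) {
  if (length(dd_calls) == 0L) return(character())
  si <- match(dd_calls, sensitive_result$gene_id)
  ri <- match(dd_calls, robust_result$gene_id)
  missing <- is.na(ri) | is.na(si)
  if (any(missing))
    warning(sprintf("%d call(s) absent from the robust result were dropped",
                    sum(missing)))
  s_sign <- sign(sensitive_result$log2_disp_fc[si])
  r_sign <- sign(robust_result$log2_disp_fc[ri])
  ok <- !missing & robust_result$converged[ri] &
    !is.na(r_sign) & r_sign != 0 & s_sign == r_sign
  dd_calls[ok]
}

#' Union of validated DD+ sets with per-gene provenance
#'
#' @param dd_up_sets named list of character vectors (per-method validated
#'   DD+ calls).
#' @return data.frame `gene_id`, `n_methods`, `methods` (comma-joined),
#'   ordered by decreasing support then gene id.
#' @export
union_dd_plus <- function(dd_up_sets) {
  stopifnot(is.list(dd_up_sets), !is.null(names(dd_up_sets)))
  genes <- sort(unique(unlist(dd_up_sets)))
  if (length(genes) == 0L)
    return(data.frame(gene_id = character(), n_methods = integer(),
                      methods = character()))
  sup <- vapply(genes, function(g)
    paste(names(dd_up_sets)[vapply(dd_up_sets, function(s) g %in% s,
                                   logical(1))], collapse = ","),
    character(1))
  n <- lengths(strsplit(sup, ","))
  out <- data.frame(gene_id = genes, n_methods = n, methods = sup,
                    stringsAsFactors = FALSE)
  out[order(-out$n_methods, out$gene_id), , drop = FALSE]
}
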