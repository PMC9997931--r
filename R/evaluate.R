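#' Threshold adjusted dispersion p-values into calls
#'
#' A gene is called differentially dispersed iff its adjusted dispersion
#' p-value is strictly below `alpha`.
#'
#' @param result a detector result with `q_disp` filled in.
#' @param alpha significance level (default 0.05).
#' @return named logical vector over genes.
#' @export
classify_calls <- function(result, alpha = 0.05) {
  stats::setNames(!is.na(result$q_disp) & result$q_disp < alpha,
                  result$gene_id)
}

#' Confusion rates of dispersion calls against simulation truth
#'
#' @param calls named logical call vector (from [classify_calls()]).
#' @param truth a `sim_truth` table covering the called genes.
#' @return one-row data.frame: `n_calls`, `tp`, `fp`, `fn`, `fdr`
#'   (`fp / max(tp + fp, 1)`, 0 when nothing is called), `tpr`.
#' @export
confusion_rates <- function(calls, truth) {
  idx <- match(names(calls), truth$gene_id)
  if (any(is.na(idx)))
    stop_msg("calls contain gene ids absent from truth (e.g. %s)",
             names(calls)[which(is.na(idx))[1]])
  pos <- truth$is_dd[idx]
  tp <- sum(calls & pos); fp <- sum(calls & !pos); fn <- sum(!calls & pos)
  data.frame(n_calls = sum(calls), tp = tp, fp = fp, fn = fn,
             fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
             tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Area under the ROC curve of a p-value ranking
#'
#' Computed by the rank (Mann-Whitney) identity with average ranks for
#' ties; smaller p-values rank as stronger evidence. Genes flagged
#' non-converged can be forced to the worst rank via `worst`.
#'
#' @param p raw p-values (the ranking statistic).
#' @param labels logical truth labels (TRUE = positive).
#' @param worst logical: entries forced to the bottom of the ranking.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(p, labels, worst = NULL) {
  labels <- as.logical(labels)
  if (length(p) != length(labels)) stop_msg("'p' and 'labels' lengths differ")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_msg("AUC needs at least one positive and one negative label")
  score <- -p
  if (!is.null(worst)) score[worst] <- -Inf
  r <- rank(score, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Exclusive (UpSet-style) intersection sizes of call sets
#'
#' @param call_sets named list of character vectors (e.g. per-method true
#'   positive gene sets).
#' @return data.frame with one row per non-empty region of the Venn
#'   partition: `members` (method names joined by `+`), `size`.
#' @export
intersect_calls <- function(call_sets) {
  stopifnot(is.list(call_sets), length(call_sets) >= 1,
            !is.null(names(call_sets)))
  universe <- unique(unlist(call_sets))
  if (length(universe) == 0L)
    return(data.frame(members = character(), size = integer()))
  membership <- vapply(call_sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(call_sets)))
  key <- apply(membership, 1, function(m)
    paste(names(call_sets)[m], collapse = "+"))
  tab <- table(key)
  out <- data.frame(members = names(tab), size = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$size, out$members), , drop = FALSE]
}

#' Sign-correctness of dispersion fold-change estimates among true positives
#'
#' Counts true-positive calls whose estimated `log2_disp_fc` sign disagrees
#' with the true dispersion fold-change sign, stratified by true dispersion
#' direction and by true mean-change direction. Non-converged genes are
#' excluded.
#'
#' @param result an adjusted detector result.
#' @param truth the matching `sim_truth`.
#' @param alpha call threshold on `q_disp`.
#' @return list with `n_tp`, `n_sign_errors`, and a stratified data.frame
#'   `by_stratum` (`true_disp_dir`, `true_mean_dir`, `n_tp`, `n_errors`).
#' @export
sign_error_analysis <- function(result, truth, alpha = 0.05) {
  idx <- match(result$gene_id, truth$gene_id)
  if (any(is.na(idx))) stop_msg("result contains gene ids absent from truth")
  tr <- truth[idx, ]
  tp <- !is.na(result$q_disp) & result$q_disp < alpha & tr$is_dd &
    result$converged & !is.na(result$log2_disp_fc)
  est_sign <- sign(result$log2_disp_fc)
  true_sign <- sign(log2(tr$disp_fc))
  err <- tp & est_sign != true_sign
  strat <- data.frame(
    true_disp_dir = ifelse(true_sign > 0, "increase", "decrease"),
    true_mean_dir = ifelse(tr$mean_fc >= 1, "up", "down"))
  agg <- stats::aggregate(cbind(n_tp = tp, n_errors = err),
                          by = strat, FUN = sum)
  list(n_tp = sum(tp), n_sign_errors = sum(err), by_stratum = agg)
}

#' Score one adjusted detector result against truth
#'
#' Convenience wrapper producing one tidy `EvalSummary` row: FDR and TPR of
#' calls at `alpha`, AUC of the raw dispersion p-value ranking (adjustment
#' is monotone, so AUC is unchanged; non-converged genes are ranked worst),
#' and the sign-error count among true positives.
#'
#' @param result adjusted detector result.
#' @param truth matching `sim_truth` (subset to analyzed genes happens here).
#' @param alpha call threshold.
#' @return one-row data.frame.
#' @export
evaluate_result <- function(result, truth, alpha = 0.05) {
  tr <- truth[match(result$gene_id, truth$gene_id), ]
  calls <- classify_calls(result, alpha)
  cr <- confusion_rates(calls, tr)
  auc <- roc_auc(result$p_disp, tr$is_dd, worst = !result$converged)
  se <- sign_error_analysis(result, tr, alpha)
  data.frame(method = result$method[1], n_genes = nrow(result),
             n_calls = cr$n_calls, fdr = cr$fdr, tpr = cr$tpr, auc = auc,
             n_sign_errors = se$n_sign_errors,
             stringsAsFactors = FALSE)
}
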