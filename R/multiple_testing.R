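#' Benjamini-Hochberg / Benjamini-Yekutieli step-up adjustment
#'
#' Step-up FDR adjustment of a raw p-value vector: BH computes
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}; BY multiplies by the
#' harmonic sum \eqn{\sum_{k=1}^n 1/k}, both capped at 1. Delegates to
#' [stats::p.adjust()], which implements exactly these rules. BY is never
#' smaller than BH, which is why the conservative detector pairing below
#' uses it.
#'
#' @param p raw p-values in [0, 1] (NAs not allowed).
#' @param method `"bh"` or `"by"`.
#' @return adjusted p-values, same order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "by")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_msg("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = toupper(method))
}

#' Default adjustment pairing per detector
#'
#' The conservative Benjamini-Yekutieli procedure for the MDSeq-style Wald
#' test, Benjamini-Hochberg for all other detectors, as each method's
#' authors recommend. `pairing = "bh"` forces BH everywhere (the
#' supplementary-style experiment).
#'
#' @param result a detector result data.frame.
#' @param pairing `"default"` or `"bh"`.
#' @return the result with `q_mean` and `q_disp` filled in.
#' @export
adjust_detector_result <- function(result, pairing = c("default", "bh")) {
  pairing <- match.arg(pairing)
  method <- if (pairing == "bh") "bh" else
    if (result$method[1] == "mdseq") "by" else "bh"
  if (!all(is.na(result$p_mean)))
    result$q_mean <- adjust_pvalues(result$p_mean, method)
  result$q_disp <- adjust_pvalues(result$p_disp, method)
  result
}
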