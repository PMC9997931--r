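#' Levene's test for differential variance of log counts
#'
#' Applies the classic mean-centered Levene statistic gene by gene to the
#' log2-transformed normalized counts: with absolute deviations
#' \eqn{z_{gj} = |x_{gj} - \bar x_g|} per group,
#' \deqn{W = \frac{N-k}{k-1}\cdot
#'   \frac{\sum_g n_g (\bar z_g - \bar z)^2}{\sum_g\sum_j (z_{gj}-\bar z_g)^2}}
#' referred to \eqn{F(k-1, N-k)} (here k = 2 groups). The reported
#' dispersion effect is the log2 ratio of group variances of the log counts;
#' no mean test is performed (mean columns are NA).
#'
#' @param log_matrix genes-by-samples matrix of log2 normalized counts
#'   (from [log_transform()]).
#' @param design a [group_design()] (batch covariates are ignored; Levene's
#'   test is covariate-free).
#' @param gene_ids optional gene identifiers (default rownames).
#' @return a detector result data.frame (`method = "levene"`).
#' @export
levene_dispersion_test <- function(log_matrix, design,
                                   gene_ids = rownames(log_matrix)) {
  stopifnot(inherits(design, "group_design"))
  x <- as.matrix(log_matrix)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(x)))
  g1 <- design$condition == 0
  g2 <- design$condition == 1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop_msg("need at least 2 samples per group")
  N <- n1 + n2
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  z1 <- abs(x1 - m1); z2 <- abs(x2 - m2)
  zb1 <- rowMeans(z1); zb2 <- rowMeans(z2)
  zb <- (n1 * zb1 + n2 * zb2) / N
  num <- n1 * (zb1 - zb)^2 + n2 * (zb2 - zb)^2
  den <- rowSums((z1 - zb1)^2) + rowSums((z2 - zb2)^2)
  W <- ifelse(den > 0, (N - 2) * num / den, 0)
  p <- ifelse(den > 0, stats::pf(W, 1, N - 2, lower.tail = FALSE), 1)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  l2dfc <- ifelse(v1 > 0 & v2 > 0, log2(v2 / v1), 0)
  detector_result(gene_ids, NA_real_, l2dfc, NA_real_, W, NA_real_, p,
                  rep(TRUE, nrow(x)), "levene")
}
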