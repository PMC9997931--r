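make_result <- function(ids, p_disp, l2dfc = 0, converged = TRUE,
                        method = "toy", q_disp = NULL) {
  n <- length(ids)
  data.frame(gene_id = ids, log2_mean_fc = 0, log2_disp_fc = rep_len(l2dfc, n),
             stat_mean = 0, stat_disp = 0, p_mean = 1,
             p_disp = p_disp, q_mean = 1,
             q_disp = if (is.null(q_disp)) p_disp else q_disp,
             converged = rep_len(converged, n), method = method)
}

make_truth <- function(ids, is_dd, disp_fc = ifelse(is_dd, 2, 1),
                       mean_fc = 1) {
  structure(data.frame(gene_id = ids, is_dd = is_dd,
                       disp_fc = disp_fc, mean_fc = mean_fc),
            class = c("sim_truth", "data.frame"))
}

test_that("calls use strict inequality at alpha", {
  res <- make_result(paste0("g", 1:3), p_disp = c(0.049, 0.05, 1))
  calls <- classify_calls(res, alpha = 0.05)
  expect_equal(unname(calls), c(TRUE, FALSE, FALSE))
  expect_length(classify_calls(res[0, ], 0.05), 0)
})

test_that("confusion rates match a hand-counted table", {
  ids <- paste0("g", 1:10)
  truth <- make_truth(ids, is_dd = rep(c(TRUE, FALSE), each = 5))
  calls <- setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE,
                      TRUE, TRUE, FALSE, FALSE, FALSE), ids)
  cr <- confusion_rates(calls, truth)
  expect_equal(cr$tp, 3); expect_equal(cr$fp, 2); expect_equal(cr$fn, 2)
  expect_equal(cr$fdr, 2 / 5); expect_equal(cr$tpr, 3 / 5)
  # calls == truth and calls == complement
  cr1 <- confusion_rates(setNames(truth$is_dd, ids), truth)
  expect_equal(c(cr1$fdr, cr1$tpr), c(0, 1))
  cr0 <- confusion_rates(setNames(!truth$is_dd, ids), truth)
  expect_equal(cr0$tpr, 0)
  # no calls at all: FDR defined as 0
  expect_equal(confusion_rates(setNames(rep(FALSE, 10), ids), truth)$fdr, 0)
  expect_error(confusion_rates(setNames(TRUE, "nope"), truth), "absent")
})

test_that("AUC equals the all-pairs ordering proportion", {
  p <- c(0.01, 0.2, 0.03, 0.6, 0.5, 0.2)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # brute-force oracle: proportion of correctly ordered (pos, neg) pairs,
  # ties counted 1/2
  num <- 0
  for (i in which(lab)) for (j in which(!lab))
    num <- num + (p[i] < p[j]) + 0.5 * (p[i] == p[j])
  expect_equal(roc_auc(p, lab), num / (sum(lab) * sum(!lab)))
  expect_equal(roc_auc(c(0.01, 0.02, 0.9, 0.99), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(0.9, 0.99, 0.01, 0.02), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_error(roc_auc(p, rep(TRUE, 6)), "positive and")
  # invariance under strictly monotone transforms; worst-rank handling
  expect_equal(roc_auc(sqrt(p), lab), roc_auc(p, lab))
  expect_lt(roc_auc(p, lab, worst = c(TRUE, rep(FALSE, 5))), roc_auc(p, lab))
})

test_that("exclusive intersections match inclusion-exclusion enumeration", {
  a <- c("g1", "g2", "g3"); b <- c("g2", "g3", "g4"); c3 <- c("g3", "g5")
  tab <- intersect_calls(list(A = a, B = b, C = c3))
  get <- function(m) { s <- tab$size[tab$members == m]; if (length(s)) s else 0 }
  expect_equal(get("A"), 1)       # g1
  expect_equal(get("A+B"), 1)     # g2
  expect_equal(get("A+B+C"), 1)   # g3
  expect_equal(get("B"), 1)       # g4
  expect_equal(get("C"), 1)       # g5
  expect_equal(sum(tab$size), length(union(union(a, b), c3)))
  # identical and disjoint sets
  same <- intersect_calls(list(X = a, Y = a))
  expect_equal(same$size, 3)
  expect_equal(same$members, "X+Y")
  disj <- intersect_calls(list(X = c("g1"), Y = c("g2")))
  expect_equal(sort(disj$members), c("X", "Y"))
})

test_that("sign errors are counted and stratified correctly", {
  ids <- paste0("g", 1:6)
  truth <- make_truth(ids, is_dd = rep(TRUE, 6),
                      disp_fc = c(2, 2, 0.5, 0.5, 2, 0.5),
                      mean_fc = c(2, 0.5, 2, 0.5, 2, 0.5))
  est <- c(1, 1, -1, -1, 1, -1) # all correct signs
  res <- make_result(ids, p_disp = rep(0.001, 6), l2dfc = est)
  expect_equal(sign_error_analysis(res, truth)$n_sign_errors, 0)
  res2 <- make_result(ids, p_disp = rep(0.001, 6), l2dfc = -est)
  se2 <- sign_error_analysis(res2, truth)
  expect_equal(se2$n_sign_errors, 6)
  # mixed case stratification matches enumeration
  res3 <- make_result(ids, p_disp = rep(0.001, 6),
                      l2dfc = c(1, -1, -1, 1, 1, -1)) # errors at g2, g4
  se3 <- sign_error_analysis(res3, truth)
  expect_equal(se3$n_sign_errors, 2)
  bs <- se3$by_stratum
  expect_equal(bs$n_errors[bs$true_disp_dir == "increase" &
                             bs$true_mean_dir == "down"], 1) # g2
  expect_equal(bs$n_errors[bs$true_disp_dir == "decrease" &
                             bs$true_mean_dir == "down"], 1) # g4
  # non-converged true positives are excluded
  res4 <- make_result(ids, p_disp = rep(0.001, 6), l2dfc = -est,
                      converged = FALSE)
  expect_equal(sign_error_analysis(res4, truth)$n_tp, 0)
})
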