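toy_result <- function(ids, q_mean = 1, q_disp = 1, l2m = 0, l2d = 0,
                       converged = TRUE, method = "toy") {
  n <- length(ids)
  data.frame(gene_id = ids,
             log2_mean_fc = rep_len(l2m, n), log2_disp_fc = rep_len(l2d, n),
             stat_mean = 0, stat_disp = 0, p_mean = 0.5, p_disp = 0.5,
             q_mean = rep_len(q_mean, n), q_disp = rep_len(q_disp, n),
             converged = rep_len(converged, n), method = method)
}

test_that("DE partition matches enumeration", {
  ids <- paste0("g", 1:5)
  res <- toy_result(ids, q_mean = c(0.01, 0.2, 0.01, 1, 0.04),
                    l2m = c(1, 1, -2, 0, 0.5))
  de <- call_de_genes(res, alpha = 0.05)
  expect_setequal(de$de_up, c("g1", "g5"))
  expect_equal(de$de_down, "g3")
  expect_setequal(de$non_de, c("g2", "g4"))
  expect_setequal(c(de$de_up, de$de_down, de$non_de), ids)
  # all q = 1: everything non-DE
  de1 <- call_de_genes(toy_result(ids), alpha = 0.05)
  expect_setequal(de1$non_de, ids)
  expect_length(de1$de_up, 0)
})

test_that("DD calls are confined to non-DE genes with direction by sign", {
  ids <- paste0("g", 1:6)
  res <- list(
    m1 = toy_result(ids, q_disp = c(0.01, 0.01, 0.01, 1, 0.01, 1),
                    l2d = c(1, -1, 1, 1, -2, 0)),
    m2 = toy_result(ids, q_disp = 1))
  non_de <- c("g1", "g2", "g4", "g5")
  dd <- call_dd_among_non_de(res, non_de, alpha = 0.05)
  expect_equal(dd$m1$dd_up, "g1")      # g3 excluded: not non-DE
  expect_setequal(dd$m1$dd_down, c("g2", "g5"))
  expect_length(dd$m2$dd_up, 0)
  dd0 <- call_dd_among_non_de(res, character(), alpha = 0.05)
  expect_length(dd0$m1$dd_up, 0)
})

test_that("sign validation keeps agreeing calls and is idempotent", {
  ids <- paste0("g", 1:4)
  sens <- toy_result(ids, l2d = c(1, 1, -1, 1))
  rob <- toy_result(ids, l2d = c(2, -0.5, -3, 0))
  kept <- validate_signs(ids, sens, rob)
  expect_equal(kept, c("g1", "g3")) # g2 disagrees, g4 has robust estimate 0
  expect_equal(validate_signs(kept, sens, rob), kept)
  # non-converged robust estimates drop the call
  rob2 <- rob; rob2$converged[1] <- FALSE
  expect_equal(validate_signs(ids, sens, rob2), "g3")
  # genes absent from the robust result are dropped with a warning
  expect_warning(out <- validate_signs(c("g1", "zzz"), sens, rob), "dropped")
  expect_equal(out, "g1")
  expect_length(validate_signs(character(), sens, rob), 0)
})

test_that("DD+ union records per-gene provenance", {
  u <- union_dd_plus(list(a = c("g1", "g2"), b = c("g2", "g3"),
                          c = character()))
  expect_equal(u$gene_id[u$n_methods == 2], "g2")
  expect_equal(u$methods[u$gene_id == "g2"], "a,b")
  expect_setequal(u$gene_id, c("g1", "g2", "g3"))
  # identical sets collapse, disjoint sets add up
  expect_equal(nrow(union_dd_plus(list(a = c("x", "y"), b = c("x", "y")))), 2)
  expect_equal(nrow(union_dd_plus(list(a = "x", b = "y"))), 2)
  expect_equal(nrow(union_dd_plus(list(a = character()))), 0)
})

test_that("validated union keeps FDR at or below the worst single method", {
  # scenario-2 simulation scored among non-DE genes (checked property)
  cfg <- sim_config(n_genes = 400, n_per_condition = 30,
                    scenario = "moderated", fc_mean_max = 1.5, seed = 1)
  sim <- simulate_dataset(cfg)
  prep <- preprocess_dataset(sim$dataset)
  res <- run_detectors(prep)
  de <- call_de_genes(res$mdseq, alpha = 0.05)
  dd <- call_dd_among_non_de(res, de$non_de, alpha = 0.05)
  val <- validate_signs(dd$gamlss$dd_up, res$gamlss, res$robust)
  union <- union_dd_plus(list(levene = dd$levene$dd_up,
                              mdseq = dd$mdseq$dd_up,
                              robust = dd$robust$dd_up,
                              gamlss = val))
  truth_up <- sim$truth$gene_id[sim$truth$is_dd & sim$truth$disp_fc > 1]
  fdr_of <- function(set) if (length(set) == 0) 0 else
    mean(!set %in% truth_up)
  per_method <- c(fdr_of(dd$levene$dd_up), fdr_of(dd$mdseq$dd_up),
                  fdr_of(dd$robust$dd_up), fdr_of(dd$gamlss$dd_up))
  expect_true(nrow(union) > 0)
  expect_lte(fdr_of(union$gene_id), max(per_method))
  expect_true(all(union$gene_id %in% de$non_de))
})
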