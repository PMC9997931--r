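test_that("parameter pair tables: surrogate, file round-trip, validation", {
  pairs <- load_parameter_pairs("surrogate", n = 10000, seed = 3)
  expect_true(all(pairs$mean > 0))
  expect_true(all(pairs$dispersion > 0))
  # mean-dispersion trend is decreasing: rank-correlation oracle on the draw
  expect_lt(cor(pairs$mean, pairs$dispersion, method = "spearman"), 0)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("100\t0.2", "50\t0.4"), tsv)
  tab <- load_parameter_pairs(tsv)
  expect_equal(tab$mean, c(100, 50))
  expect_equal(tab$dispersion, c(0.2, 0.4))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("100\t0.2", "50\t-0.4"), bad)
  expect_error(load_parameter_pairs(bad), "row 2")
  expect_error(load_parameter_pairs("/no/such/file.tsv"), "not found")
})

test_that("truth assignment composition and exact stratum balance", {
  cfg <- sim_config(seed = 5)
  pairs <- load_parameter_pairs("surrogate", n = 2000, seed = 5)
  truth <- assign_truth(cfg, pairs)
  expect_equal(nrow(truth), 10000)
  expect_equal(sum(truth$is_dd), 5000)
  expect_equal(sum(truth$is_highly_de), 5000)
  # exact balance: identical DD counts in every DE stratum, and identical
  # DD+ counts across DE+/DE- among highly DE genes
  tab <- table(truth$is_dd, truth$is_highly_de)
  expect_true(all(tab == 2500))
  up <- table(truth$disp_direction[truth$is_dd & truth$is_highly_de],
              truth$mean_direction[truth$is_dd & truth$is_highly_de])
  expect_true(all(up == up[1, 1]))
  # every DD gene moves dispersion by at least the configured minimum
  ratio <- truth$condition2_dispersion / truth$baseline_dispersion
  expect_true(all(pmax(ratio, 1 / ratio)[truth$is_dd] >= cfg$fc_disp_min))
  # non-DD genes keep their dispersion exactly
  expect_identical(truth$condition2_dispersion[!truth$is_dd],
                   truth$baseline_dispersion[!truth$is_dd])
})

test_that("frac_dd = 0 leaves all dispersions unchanged", {
  cfg <- sim_config(n_genes = 500, frac_dd = 0, seed = 2)
  truth <- assign_truth(cfg, load_parameter_pairs(n = 500, seed = 2))
  expect_identical(truth$condition2_dispersion, truth$baseline_dispersion)
  expect_false(any(truth$is_dd))
})

test_that("NB sampling matches the stated mean-variance relationship", {
  # one gene, 5e4 samples per condition with identical parameters:
  # 1e5 draws at mu = 100, phi = 0.5
  cfg <- sim_config(n_genes = 1, n_per_condition = 50000, frac_dd = 0,
                    frac_highly_de = 0, outlier_fraction = 0, seed = 9)
  truth <- assign_truth(cfg, load_parameter_pairs(n = 5, seed = 9))
  truth$baseline_mean <- truth$condition2_mean <- 100
  truth$baseline_dispersion <- truth$condition2_dispersion <- 0.5
  y <- as.numeric(simulate_counts(truth, cfg)$counts)
  se_mean <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 100), 4 * se_mean)
  v <- var(y)
  se_var <- sd((y - mean(y))^2) / sqrt(length(y))
  expect_lt(abs(v - 5100), 4 * se_var)

  # Poisson limit: phi -> 0 makes variance collapse to the mean
  truth$baseline_dispersion <- truth$condition2_dispersion <- 1e-8
  yp <- as.numeric(simulate_counts(truth, cfg)$counts)
  expect_lt(abs(var(yp) / mean(yp) - 1), 0.05)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 200, n_per_condition = 5, seed = 42)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("outlier injection touches exactly the recorded cells", {
  cfg <- sim_config(n_genes = 1000, n_per_condition = 10, seed = 8)
  pairs <- load_parameter_pairs(n = 1000, seed = 8)
  truth <- assign_truth(cfg, pairs)
  ds <- simulate_counts(truth, cfg)
  out <- inject_outliers(ds, truth, cfg)
  hit <- which(!is.na(out$truth$outlier_sample))
  expect_length(hit, 100) # 10% of 1000 genes
  cells <- cbind(hit, out$truth$outlier_sample[hit])
  orig <- ds$counts[cells]
  mod <- out$dataset$counts[cells]
  expect_true(all(mod[orig > 0] >= 5 * orig[orig > 0]))
  # conservation off the recorded positions
  untouched <- out$dataset$counts
  untouched[cells] <- ds$counts[cells]
  expect_identical(untouched, ds$counts)

  cfg0 <- sim_config(n_genes = 1000, n_per_condition = 10,
                     outlier_fraction = 0, seed = 8)
  out0 <- inject_outliers(ds, truth, cfg0)
  expect_identical(out0$dataset$counts, ds$counts)
})

test_that("count dataset TSV round-trip preserves everything", {
  ds <- make_nb_dataset(n_genes = 20, n_per = 4, seed = 3)
  cp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_count_dataset(ds, cp, sp)
  back <- read_count_dataset(cp, sp)
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_equal(as.character(back$condition), as.character(ds$condition))
  expect_equal(back$gene_ids, ds$gene_ids)
})
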