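#' Preprocess a count dataset (TMM + CPM filter)
#'
#' Computes TMM factors on the full matrix, removes genes below the mean
#' CPM threshold, and returns the filtered dataset together with the
#' factors every downstream detector consumes.
#'
#' @param dataset a [count_dataset()].
#' @param cpm_threshold mean-CPM filter threshold (default 1).
#' @return list `dataset`, `factors`, `kept`.
#' @export
preprocess_dataset <- function(dataset, cpm_threshold = 1) {
  factors <- tmm_factors(dataset)
  flt <- filter_low_expression(dataset, factors, cpm_threshold)
  list(dataset = flt$dataset, factors = factors, kept = flt$kept)
}

#' Run a set of differential-dispersion detectors on one dataset
#'
#' Levene's test consumes the log2 normalized matrix; the count-based
#' detectors consume raw counts with log effective library sizes as
#' offsets. Batch covariates (when present) enter the MDSeq-style and
#' double-NB GLMs; the robust detector is covariate-free by design.
#' Adjusted p-values follow the default pairing (BY for the MDSeq-style
#' test, BH elsewhere) unless `pairing = "bh"`.
#'
#' @param prep a [preprocess_dataset()] result.
#' @param detectors subset of `c("levene", "mdseq", "robust", "gamlss")`.
#' @param pairing `"default"` or `"bh"` (see [adjust_detector_result()]).
#' @param fc_threshold Wald fold-change threshold for the MDSeq-style test.
#' @return named list of adjusted detector results.
#' @export
run_detectors <- function(prep,
                          detectors = c("levene", "mdseq", "robust", "gamlss"),
                          pairing = "default", fc_threshold = 1) {
  detectors <- match.arg(detectors, several.ok = TRUE)
  ds <- prep$dataset
  design <- group_design(ds, prep$factors, use_batch = TRUE)
  out <- list()
  if ("levene" %in% detectors) {
    lm2 <- log_transform(ds, prep$factors)
    out$levene <- levene_dispersion_test(lm2, design, ds$gene_ids)
  }
  if ("mdseq" %in% detectors)
    out$mdseq <- mdseq_mean_dispersion_test(ds, design,
                                            fc_threshold_mean = fc_threshold,
                                            fc_threshold_disp = fc_threshold)
  if ("robust" %in% detectors) {
    design_plain <- group_design(ds, prep$factors, use_batch = FALSE)
    out$robust <- robust_dispersion_test(ds, design_plain)
  }
  if ("gamlss" %in% detectors)
    out$gamlss <- gamlss_dispersion_lrt(ds, design)
  lapply(out, adjust_detector_result, pairing = pairing)
}

#' Grid configuration for the simulation study
#'
#' @param sample_sizes samples per condition to sweep.
#' @param scenarios subset of `c("unconstrained", "moderated")`.
#' @param fc_mean_max_grid mean fold-change caps swept in the moderated
#'   scenario.
#' @param n_genes genes per simulated dataset.
#' @param n_replicates replicates per grid cell (default 10).
#' @param detectors detectors to run.
#' @param alpha call threshold.
#' @param pairing p-value adjustment pairing.
#' @param seed master seed.
#' @return class `study_config` list.
#' @export
study_config <- function(sample_sizes = c(20, 30, 40, 50, 100),
                         scenarios = c("unconstrained", "moderated"),
                         fc_mean_max_grid = seq(1.1, 1.5, by = 0.1),
                         n_genes = 10000L,
                         n_replicates = 10L,
                         detectors = c("levene", "mdseq", "robust", "gamlss"),
                         alpha = 0.05,
                         pairing = "default",
                         seed = 1L) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (n_replicates < 1) stop_msg("'n_replicates' must be >= 1")
  structure(list(sample_sizes = as.integer(sample_sizes),
                 scenarios = scenarios,
                 fc_mean_max_grid = fc_mean_max_grid,
                 n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 detectors = detectors, alpha = alpha, pairing = pairing,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full simulation study grid
#'
#' For every (scenario, sample size, fold-change cap) cell and replicate:
#' simulate, preprocess, run the detectors, adjust, and score against
#' truth. Per-replicate seeds derive deterministically from the master
#' seed, so reruns are identical. Stage failures are recorded in the
#' `error` column and the study continues.
#'
#' @param config a [study_config()].
#' @return tidy data.frame: one row per cell x replicate x detector.
#' @export
run_simulation_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cells <- list(); ci <- 0L
  for (sc in config$scenarios) {
    fcs <- if (sc == "moderated") config$fc_mean_max_grid else NA_real_
    for (fc in fcs) for (n in config$sample_sizes) {
      ci <- ci + 1L
      cells[[ci]] <- list(scenario = sc, fc_max = fc, n = n, index = ci)
    }
  }
  rows <- list()
  for (cell in cells) {
    for (rep in seq_len(config$n_replicates)) {
      seed <- derive_seed(config$seed, stage = 100L + cell$index, index = rep)
      row <- tryCatch({
        sim_cfg <- sim_config(
          n_genes = config$n_genes, n_per_condition = cell$n,
          scenario = cell$scenario,
          fc_mean_max = if (is.na(cell$fc_max)) 1.5 else cell$fc_max,
          seed = seed)
        sim <- simulate_dataset(sim_cfg)
        prep <- preprocess_dataset(sim$dataset)
        results <- run_detectors(prep, detectors = config$detectors,
                                 pairing = config$pairing)
        ev <- do.call(rbind, lapply(results, evaluate_result,
                                    truth = sim$truth,
                                    alpha = config$alpha))
        ev$error <- NA_character_
        ev
      }, error = function(e) {
        data.frame(method = NA_character_, n_genes = NA_integer_,
                   n_calls = NA_integer_, fdr = NA_real_, tpr = NA_real_,
                   auc = NA_real_, n_sign_errors = NA_integer_,
                   error = conditionMessage(e))
      })
      row$scenario <- cell$scenario
      row$n_per_condition <- cell$n
      row$fc_max <- cell$fc_max
      row$replicate <- rep
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Applied analysis: DD genes among non-DE genes with sign validation
#'
#' Runs the recommended workflow on a real (or simulated) dataset:
#' preprocess, call DE genes with the covariate-capable MDSeq-style test
#' (batch included when labels exist), call DD genes among non-DE genes
#' with every detector, validate the sensitive double-NB detector's signs
#' against the robust detector, and take the union of DD+ calls with
#' per-gene provenance.
#'
#' @param dataset a [count_dataset()] (or use `counts_path`/`samples_path`).
#' @param counts_path,samples_path TSV inputs, read when `dataset` is NULL.
#' @param alpha significance level (default 0.05).
#' @param fc_threshold Wald fold-change threshold (default 1).
#' @param force analyze datasets with fewer than 30 samples per condition.
#' @param validate_levene also sign-validate Levene calls (default FALSE).
#' @param out_dir optional directory for TSV reports.
#' @return list with `results` (per-detector tables), `de` (DE+/DE-/non-DE
#'   partition), `dd` (per-method DD+/DD- sets), `validated_gamlss_up`,
#'   `union_dd_plus`.
#' @export
run_analysis <- function(dataset = NULL, counts_path = NULL,
                         samples_path = NULL, alpha = 0.05,
                         fc_threshold = 1, force = FALSE,
                         validate_levene = FALSE, out_dir = NULL) {
  if (is.null(dataset))
    dataset <- read_count_dataset(counts_path, samples_path)
  n_per <- tabulate(dataset$condition)
  if (min(n_per) < 30 && !force)
    stop_msg(paste("fewer than 30 samples in a condition (%d);",
                   "dispersion calls are unreliable at this size,",
                   "use force = TRUE to override"), min(n_per))
  prep <- preprocess_dataset(dataset)
  results <- run_detectors(prep, fc_threshold = fc_threshold)
  de <- call_de_genes(results$mdseq, alpha = alpha)
  dd <- call_dd_among_non_de(results, de$non_de, alpha = alpha)
  val_gamlss <- validate_signs(dd$gamlss$dd_up, results$gamlss,
                               results$robust)
  lev_up <- if (validate_levene)
    validate_signs(dd$levene$dd_up, results$levene, results$robust)
  else dd$levene$dd_up
  union <- union_dd_plus(list(levene = lev_up,
                              mdseq = dd$mdseq$dd_up,
                              robust = dd$robust$dd_up,
                              gamlss = val_gamlss))
  out <- list(results = results, de = de, dd = dd,
              validated_gamlss_up = val_gamlss, union_dd_plus = union)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(results))
      utils::write.table(results[[m]],
                         file.path(out_dir, paste0(m, "_result.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(union, file.path(out_dir, "dd_plus_union.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
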