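#' Simulation configuration for two-condition RNA-seq counts
#'
#' Bundles every tunable of the count simulator. Defaults reproduce the
#' stated simulation protocol: 10,000 genes, negative binomial counts with
#' variance \eqn{\mu + \phi \mu^2}, 50% differentially dispersed (DD) genes
#' whose dispersion fold change has magnitude at least `fc_disp_min = 1.5`
#' plus an Exponential(1) extra amount, and one injected outlier count
#' (multiplied by Uniform(5, 10)) in 10% of genes.
#'
#' Two scenarios control the mean fold changes:
#' \describe{
#'   \item{`"unconstrained"`}{50% of genes are highly differentially
#'     expressed with fold-change magnitude `fc_mean_min + Exp(exp_rate)`
#'     in a random direction; the remaining (lowly DE) genes get a fold
#'     change drawn from Uniform(1, `fc_mean_min`).}
#'   \item{`"moderated"`}{every gene gets a mean fold change drawn from
#'     Uniform(1, `fc_mean_max`); no gene is flagged highly DE.}
#' }
#'
#' @param n_genes number of genes.
#' @param n_per_condition samples in each of the two conditions.
#' @param scenario `"unconstrained"` or `"moderated"`.
#' @param fc_disp_min minimum dispersion fold-change magnitude for DD genes.
#' @param fc_mean_min minimum fold change of highly DE genes (scenario
#'   `"unconstrained"`; also the upper bound of the lowly DE uniform draw).
#' @param fc_mean_max upper bound of the uniform mean fold change in
#'   scenario `"moderated"`.
#' @param exp_rate rate of the exponential "extra amount" distribution.
#' @param frac_dd fraction of genes differentially dispersed.
#' @param frac_highly_de fraction of genes highly DE (scenario
#'   `"unconstrained"` only).
#' @param outlier_fraction fraction of genes receiving one outlier count.
#' @param outlier_multiplier_range closed interval the outlier multiplier is
#'   drawn from.
#' @param seed master seed; all stages derive their streams from it via
#'   [derive_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 10000L,
                       n_per_condition = 50L,
                       scenario = c("unconstrained", "moderated"),
                       fc_disp_min = 1.5,
                       fc_mean_min = 1.5,
                       fc_mean_max = 1.5,
                       exp_rate = 1,
                       frac_dd = 0.5,
                       frac_highly_de = 0.5,
                       outlier_fraction = 0.1,
                       outlier_multiplier_range = c(5, 10),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  if (!is.numeric(n_genes) || n_genes < 1) stop_msg("'n_genes' must be >= 1")
  if (!is.numeric(n_per_condition) || n_per_condition < 2)
    stop_msg("'n_per_condition' must be >= 2")
  if (fc_disp_min < 1) stop_msg("'fc_disp_min' must be >= 1")
  if (fc_mean_min < 1) stop_msg("'fc_mean_min' must be >= 1")
  if (fc_mean_max < 1) stop_msg("'fc_mean_max' must be >= 1")
  if (exp_rate <= 0) stop_msg("'exp_rate' must be > 0")
  assert_prob(frac_dd, "frac_dd")
  assert_prob(frac_highly_de, "frac_highly_de")
  assert_prob(outlier_fraction, "outlier_fraction")
  if (length(outlier_multiplier_range) != 2L ||
      outlier_multiplier_range[1] > outlier_multiplier_range[2] ||
      outlier_multiplier_range[1] <= 1)
    stop_msg("'outlier_multiplier_range' must be an interval (a, b), 1 < a <= b")
  structure(list(
    n_genes = as.integer(n_genes),
    n_per_condition = as.integer(n_per_condition),
    scenario = scenario,
    fc_disp_min = fc_disp_min,
    fc_mean_min = fc_mean_min,
    fc_mean_max = fc_mean_max,
    exp_rate = exp_rate,
    frac_dd = frac_dd,
    frac_highly_de = frac_highly_de,
    outlier_fraction = outlier_fraction,
    outlier_multiplier_range = as.numeric(outlier_multiplier_range),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Load or synthesize baseline (mean, dispersion) parameter pairs
#'
#' The simulator draws each gene's condition-1 mean \eqn{\mu_{i1}} and
#' dispersion \eqn{\phi_{i1}} jointly from a table of parameter pairs.
#' `source = "surrogate"` generates a packaged stand-in resembling bulk
#' RNA-seq estimates: means are log-normal and dispersions follow a
#' decreasing mean-dispersion trend \eqn{\phi_0 + a/\mu} with log-normal
#' noise. Any two-column numeric TSV (mean, dispersion) overrides it.
#'
#' @param source `"surrogate"` or a path to a headerless two-column TSV.
#' @param n number of surrogate pairs to draw (ignored for files).
#' @param seed RNG seed for the surrogate draw.
#' @param meanlog,sdlog log-normal parameters of the surrogate means.
#' @param phi0,phi_slope,phi_sdlog surrogate dispersion trend
#'   \eqn{\phi = (\phi_0 + a/\mu)\,e^{N(0,\sigma^2)}} parameters.
#' @return a data.frame of class `parameter_pairs` with columns `mean` and
#'   `dispersion`, all strictly positive.
#' @export
load_parameter_pairs <- function(source = "surrogate", n = 10000L, seed = 1L,
                                 meanlog = 4.8, sdlog = 1.6,
                                 phi0 = 0.05, phi_slope = 8, phi_sdlog = 0.6) {
  if (identical(source, "surrogate")) {
    set.seed(derive_seed(seed, stage = 1L))
    mu <- stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    phi <- (phi0 + phi_slope / mu) * stats::rlnorm(n, 0, phi_sdlog)
    tab <- data.frame(mean = mu, dispersion = phi)
  } else {
    if (!file.exists(source)) stop_msg("parameter pair file not found: %s", source)
    tab <- utils::read.table(source, header = FALSE)
    if (ncol(tab) < 2L)
      stop_msg("parameter pair table needs at least 2 columns, got %d", ncol(tab))
    tab <- data.frame(mean = as.numeric(tab[[1]]), dispersion = as.numeric(tab[[2]]))
  }
  if (nrow(tab) == 0L) stop_msg("parameter pair table is empty")
  bad <- which(!is.finite(tab$mean) | !is.finite(tab$dispersion) |
                 tab$mean <= 0 | tab$dispersion <= 0)
  if (length(bad))
    stop_msg("non-positive or non-finite parameter pair at row %d", bad[1])
  class(tab) <- c("parameter_pairs", "data.frame")
  tab
}

# deterministic split of n into a "+" cell (gets the remainder) and a "-" cell
split_half <- function(n) c(ceiling(n / 2), floor(n / 2))

#' Assign per-gene simulation ground truth
#'
#' Draws baseline (mean, dispersion) pairs for every gene (sampling the pair
#' table with replacement) and assigns mean and dispersion fold changes
#' according to the configured scenario. DD genes receive a dispersion fold
#' change of magnitude `fc_disp_min + Exp(exp_rate)`, applied multiplicatively
#' in the drawn direction (increase: multiply, decrease: divide); non-DD
#' genes keep their dispersion exactly. The DD fraction is balanced exactly
#' across highly/lowly DE strata and the DD+ fraction across DE+/DE- strata;
#' remainders go to the "+" cells.
#'
#' @param config a [sim_config()].
#' @param pairs a [load_parameter_pairs()] table.
#' @return a data.frame of class `sim_truth` with one row per gene:
#'   `gene_id`, `baseline_mean`, `baseline_dispersion`, `is_dd`,
#'   `disp_direction` (+1/-1, NA for non-DD), `disp_extra`, `disp_fc`
#'   (ratio \eqn{\phi_{i2}/\phi_{i1}}), `is_highly_de`, `mean_direction`,
#'   `mean_fc` (ratio \eqn{\mu_{i2}/\mu_{i1}}), `condition2_mean`,
#'   `condition2_dispersion`, `outlier_sample`, `outlier_multiplier`.
#' @export
assign_truth <- function(config, pairs) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(pairs, "parameter_pairs") || nrow(pairs) == 0L)
    stop_msg("'pairs' must be a non-empty parameter_pairs table")
  n <- config$n_genes
  set.seed(derive_seed(config$seed, stage = 2L))

  idx <- sample.int(nrow(pairs), n, replace = TRUE)
  mu1 <- pairs$mean[idx]
  phi1 <- pairs$dispersion[idx]

  is_dd <- logical(n)
  disp_dir <- rep(NA_integer_, n)
  is_hde <- logical(n)
  mean_dir <- integer(n)
  mean_mag <- numeric(n)

  n_dd <- round(config$frac_dd * n)
  perm <- sample.int(n)

  if (config$scenario == "unconstrained") {
    n_h <- round(config$frac_highly_de * n)
    n_l <- n - n_h
    hde_idx <- perm[seq_len(n_h)]
    lde_idx <- perm[n_h + seq_len(n_l)]
    is_hde[hde_idx] <- TRUE
    dd_h <- min(round(config$frac_dd * n_h), n_h)
    dd_l <- min(n_dd - dd_h, n_l)

    # highly DE stratum: fix DE direction counts, then balance DD and DD+
    de_split <- split_half(n_h)
    hp <- hde_idx[seq_len(de_split[1])]              # DE+
    hm <- hde_idx[de_split[1] + seq_len(de_split[2])] # DE-
    mean_dir[hp] <- 1L
    mean_dir[hm] <- -1L
    dd_split <- split_half(dd_h)
    dd_hp <- hp[seq_len(min(dd_split[1], length(hp)))]
    dd_hm <- hm[seq_len(min(dd_split[2], length(hm)))]
    for (cell in list(dd_hp, dd_hm)) {
      is_dd[cell] <- TRUE
      s <- split_half(length(cell))
      disp_dir[cell[seq_len(s[1])]] <- 1L
      if (s[2] > 0) disp_dir[cell[s[1] + seq_len(s[2])]] <- -1L
    }
    mean_mag[hde_idx] <- config$fc_mean_min +
      stats::rexp(n_h, rate = config$exp_rate)

    # lowly DE stratum: Uniform(1, fc_mean_min) magnitude, random direction
    is_dd[lde_idx[seq_len(dd_l)]] <- TRUE
    s <- split_half(dd_l)
    disp_dir[lde_idx[seq_len(s[1])]] <- 1L
    if (s[2] > 0) disp_dir[lde_idx[s[1] + seq_len(s[2])]] <- -1L
    mean_dir[lde_idx] <- sample(c(1L, -1L), n_l, replace = TRUE)
    mean_mag[lde_idx] <- stats::runif(n_l, 1, config$fc_mean_min)
  } else {
    dd_idx <- perm[seq_len(n_dd)]
    is_dd[dd_idx] <- TRUE
    s <- split_half(n_dd)
    disp_dir[dd_idx[seq_len(s[1])]] <- 1L
    if (s[2] > 0) disp_dir[dd_idx[s[1] + seq_len(s[2])]] <- -1L
    mean_dir[] <- sample(c(1L, -1L), n, replace = TRUE)
    mean_mag[] <- stats::runif(n, 1, config$fc_mean_max)
  }

  disp_extra <- ifelse(is_dd, stats::rexp(n, rate = config$exp_rate), 0)
  disp_mag <- config$fc_disp_min + disp_extra
  disp_fc <- rep(1, n)
  disp_fc[is_dd] <- disp_mag[is_dd]^disp_dir[is_dd]
  mean_fc <- mean_mag^mean_dir

  truth <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    baseline_mean = mu1,
    baseline_dispersion = phi1,
    is_dd = is_dd,
    disp_direction = disp_dir,
    disp_extra = disp_extra,
    disp_fc = disp_fc,
    is_highly_de = is_hde,
    mean_direction = mean_dir,
    mean_fc = mean_fc,
    condition2_mean = mu1 * mean_fc,
    condition2_dispersion = phi1 * disp_fc,
    outlier_sample = NA_integer_,
    outlier_multiplier = NA_real_,
    stringsAsFactors = FALSE
  )
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

#' Two-condition count dataset container
#'
#' @param counts non-negative integer matrix, genes in rows.
#' @param condition per-sample condition labels with exactly two levels.
#' @param gene_ids,sample_ids optional dimension names.
#' @param batch optional per-sample batch labels.
#' @return an object of class `count_dataset`.
#' @export
count_dataset <- function(counts, condition, gene_ids = rownames(counts),
                          sample_ids = colnames(counts), batch = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_msg("'counts' must be a non-negative integer matrix")
  if (length(condition) != ncol(counts))
    stop_msg("'condition' length must equal the number of samples")
  condition <- factor(condition)
  if (nlevels(condition) != 2L)
    stop_msg("'condition' must have exactly two levels")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%05d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%03d", seq_len(ncol(counts)))
  if (!is.null(batch) && length(batch) != ncol(counts))
    stop_msg("'batch' length must equal the number of samples")
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(
    counts = counts,
    gene_ids = as.character(gene_ids),
    sample_ids = as.character(sample_ids),
    condition = condition,
    batch = if (is.null(batch)) NULL else factor(batch),
    library_sizes = colSums(counts)
  ), class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", levels(x$condition),
                            tabulate(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Simulate negative binomial counts from assigned truth
#'
#' Each cell is drawn independently from the canonical negative binomial
#' with mean \eqn{\mu_{i\rho(j)}} and dispersion \eqn{\phi_{i\rho(j)}}
#' (variance \eqn{\mu + \phi\mu^2}); the first `n_per_condition` samples
#' form condition 1.
#'
#' @param truth a [assign_truth()] table.
#' @param config the matching [sim_config()].
#' @return a [count_dataset()].
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  n <- nrow(truth)
  if (n != config$n_genes)
    stop_msg("truth has %d genes but config specifies %d", n, config$n_genes)
  bad <- which(!is.finite(truth$condition2_mean) |
                 !is.finite(truth$condition2_dispersion) |
                 truth$condition2_mean <= 0 | truth$condition2_dispersion <= 0)
  if (length(bad))
    stop_msg("non-finite or non-positive NB parameters for gene %s",
             truth$gene_id[bad[1]])
  m <- config$n_per_condition
  set.seed(derive_seed(config$seed, stage = 3L))
  y1 <- matrix(stats::rnbinom(n * m, mu = truth$baseline_mean,
                              size = 1 / truth$baseline_dispersion),
               nrow = n, ncol = m)
  y2 <- matrix(stats::rnbinom(n * m, mu = truth$condition2_mean,
                              size = 1 / truth$condition2_dispersion),
               nrow = n, ncol = m)
  counts <- cbind(y1, y2)
  count_dataset(counts,
                condition = rep(c(1L, 2L), each = m),
                gene_ids = truth$gene_id,
                sample_ids = sprintf("sample_%03d", seq_len(2 * m)))
}

#' Inject one high-count outlier into a fraction of genes
#'
#' Selects `round(outlier_fraction * n_genes)` distinct genes uniformly;
#' for each, one uniformly chosen sample's count is multiplied by a value
#' drawn from Uniform over `outlier_multiplier_range` and rounded to the
#' nearest integer. Positions are recorded in the returned truth.
#'
#' @param dataset a [count_dataset()].
#' @param truth the matching `sim_truth`.
#' @param config the matching [sim_config()].
#' @return `list(dataset =, truth =)` with updated counts and outlier columns.
#' @export
inject_outliers <- function(dataset, truth, config) {
  stopifnot(inherits(dataset, "count_dataset"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  n <- nrow(dataset$counts)
  k <- round(config$outlier_fraction * n)
  if (k == 0L) return(list(dataset = dataset, truth = truth))
  set.seed(derive_seed(config$seed, stage = 4L))
  genes <- sample.int(n, k, replace = FALSE)
  cols <- sample.int(ncol(dataset$counts), k, replace = TRUE)
  mult <- stats::runif(k, config$outlier_multiplier_range[1],
                       config$outlier_multiplier_range[2])
  cells <- cbind(genes, cols)
  dataset$counts[cells] <- round(dataset$counts[cells] * mult)
  dataset$library_sizes <- colSums(dataset$counts)
  truth$outlier_sample[genes] <- cols
  truth$outlier_multiplier[genes] <- mult
  list(dataset = dataset, truth = truth)
}

#' One-call simulation: truth, counts and outliers
#'
#' @param config a [sim_config()].
#' @param pairs optional parameter pair table (surrogate drawn from the
#'   config seed when omitted).
#' @return `list(dataset, truth, config)`.
#' @export
simulate_dataset <- function(config, pairs = NULL) {
  if (is.null(pairs))
    pairs <- load_parameter_pairs("surrogate", n = config$n_genes,
                                  seed = config$seed)
  truth <- assign_truth(config, pairs)
  ds <- simulate_counts(truth, config)
  out <- inject_outliers(ds, truth, config)
  list(dataset = out$dataset, truth = out$truth, config = config)
}

#' Write / read a count dataset as TSV
#'
#' The TSV has gene ids in the first column and one column per sample; the
#' sample sheet holds `sample_id`, `condition` and optional `batch`.
#'
#' @param dataset a [count_dataset()].
#' @param counts_path,samples_path output paths.
#' @return invisibly, the paths.
#' @export
write_count_dataset <- function(dataset, counts_path, samples_path) {
  df <- data.frame(gene_id = dataset$gene_ids, dataset$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample_id = dataset$sample_ids,
                      condition = as.character(dataset$condition))
  if (!is.null(dataset$batch)) sheet$batch <- as.character(dataset$batch)
  utils::write.table(sheet, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' @rdname write_count_dataset
#' @export
read_count_dataset <- function(counts_path, samples_path) {
  df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "double"
  sheet <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                             colClasses = "character")
  if (!all(colnames(counts) %in% sheet$sample_id))
    stop_msg("sample sheet is missing ids present in the count matrix")
  sheet <- sheet[match(colnames(counts), sheet$sample_id), ]
  count_dataset(counts, condition = sheet$condition,
                gene_ids = df[[1]], sample_ids = sheet$sample_id,
                batch = if ("batch" %in% names(sheet)) sheet$batch else NULL)
}
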