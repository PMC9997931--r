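# Shared fixture builders: everything is generated in code at test time.

# small two-condition dataset with NB counts and optional per-gene settings
make_nb_dataset <- function(n_genes = 50, n_per = 10, mu = 100, phi = 0.2,
                            mu2 = mu, phi2 = phi, seed = 1) {
  set.seed(seed)
  mu <- rep_len(mu, n_genes); phi <- rep_len(phi, n_genes)
  mu2 <- rep_len(mu2, n_genes); phi2 <- rep_len(phi2, n_genes)
  y1 <- matrix(rnbinom(n_genes * n_per, mu = mu, size = 1 / phi),
               nrow = n_genes)
  y2 <- matrix(rnbinom(n_genes * n_per, mu = mu2, size = 1 / phi2),
               nrow = n_genes)
  count_dataset(cbind(y1, y2), condition = rep(1:2, each = n_per))
}

unit_factors <- function(dataset) {
  # identity normalization: equal effective sizes => zero offsets
  structure(list(factors = rep(1, ncol(dataset$counts)),
                 lib_sizes = rep(1e6, ncol(dataset$counts)),
                 effective = rep(1e6, ncol(dataset$counts)),
                 sample_ids = dataset$sample_ids),
            class = "norm_factors")
}

# independent straight-line NB log-likelihood (canonical, Var = mu+phi*mu^2)
# used by oracle computations; deliberately separate from the package code
oracle_nb_loglik <- function(y, mu, phi) {
  s <- 1 / phi
  sum(lgamma(y + s) - lgamma(s) - lgamma(y + 1) +
        s * log(s / (s + mu)) + y * log(mu / (s + mu)))
}

# two-stage grid-search ML for an intercept-only NB gene (oracle)
oracle_nb_grid_fit <- function(y, mu_range = NULL, phi_range = c(1e-4, 5)) {
  if (is.null(mu_range)) mu_range <- c(max(mean(y) / 4, 0.1), mean(y) * 4)
  best <- c(NA, NA, -Inf)
  grid_pass <- function(mus, phis, best) {
    for (m in mus) for (p in phis) {
      ll <- oracle_nb_loglik(y, m, p)
      if (ll > best[3]) best <- c(m, p, ll)
    }
    best
  }
  mus <- exp(seq(log(mu_range[1]), log(mu_range[2]), length.out = 60))
  phis <- exp(seq(log(phi_range[1]), log(phi_range[2]), length.out = 60))
  best <- grid_pass(mus, phis, best)
  for (iter in 1:2) {
    mus <- exp(seq(log(best[1]) - 0.1, log(best[1]) + 0.1, length.out = 40))
    phis <- exp(seq(log(best[2]) - 0.2, log(best[2]) + 0.2, length.out = 40))
    best <- grid_pass(mus, phis, best)
  }
  list(mu = best[1], phi = best[2], loglik = best[3])
}

# toy ontology: root -> {A, B}; A -> {A1, A2}; B -> {B1}
make_toy_ontology <- function() {
  build_ontology(
    ids = c("GO:R", "GO:A", "GO:B", "GO:A1", "GO:A2", "GO:B1"),
    names = c("GO:R" = "root", "GO:A" = "process A", "GO:B" = "process B",
              "GO:A1" = "subprocess A1", "GO:A2" = "subprocess A2",
              "GO:B1" = "subprocess B1"),
    parents = list("GO:R" = character(), "GO:A" = "GO:R", "GO:B" = "GO:R",
                   "GO:A1" = "GO:A", "GO:A2" = "GO:A", "GO:B1" = "GO:B"))
}

# annotation corpus over `n` genes: every gene hits the root; 2 genes each
# on A1/A2 (siblings, disjoint), 10 on B1, so sim(A1, A2) lands above 0.8
make_toy_annotation <- function(n = 1000) {
  genes <- sprintf("g%04d", seq_len(n))
  ann <- rbind(
    data.frame(gene = genes, term = "GO:R"),
    data.frame(gene = genes[1:2], term = "GO:A1"),
    data.frame(gene = genes[3:4], term = "GO:A2"),
    data.frame(gene = genes[5:14], term = "GO:B1"))
  list(genes = genes, table = ann)
}
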