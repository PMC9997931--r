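# Gene Ontology support: a minimal OBO (is_a) parser, upward-propagated
# annotation maps with corpus-based information content, Schlicker-style
# relevance semantic similarity, hypergeometric enrichment, and the
# two-level redundancy reduction (within-dataset clustering, cross-dataset
# merging to common generic terms).

#' Parse an OBO ontology file (is_a edges only)
#'
#' Reads `[Term]` stanzas, keeping term ids, names and `is_a` parents;
#' obsolete terms are skipped. The graph must be acyclic and every term
#' must reach a root (a term without parents).
#'
#' @param path path to an OBO file.
#' @return an object of class `ontology`: list with `ids`, `names` (named
#'   by id), `parents` (named list), `roots`, and `ancestors` (named list,
#'   inclusive of the term itself).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop_msg("OBO file not found: %s", path)
  lines <- readLines(path)
  terms <- list(); cur <- NULL; in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && nzchar(cur$id %||% ""))
      terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = "", name = "", parents = character(), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
      else if (startsWith(ln, "is_a:"))
        cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
      else if (startsWith(ln, "is_obsolete:") && grepl("true", ln))
        cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0L) stop_msg("no terms parsed from %s", path)
  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$parents, ids))
  names(parents) <- ids
  build_ontology(ids,
                 stats::setNames(vapply(terms, `[[`, "", "name"), ids),
                 parents)
}

#' Construct an ontology from explicit term/parent lists
#'
#' @param ids character vector of term ids.
#' @param names named character vector of term names.
#' @param parents named list mapping each id to its parent ids.
#' @return an `ontology` object (see [read_obo()]).
#' @export
build_ontology <- function(ids, names, parents) {
  roots <- ids[lengths(parents[ids]) == 0L]
  if (length(roots) == 0L) stop_msg("ontology has no root term")
  anc <- stats::setNames(vector("list", length(ids)), ids)
  state <- stats::setNames(integer(length(ids)), ids) # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return(anc[[id]])
    if (state[[id]] == 1L) stop_msg("ontology contains a cycle through %s", id)
    state[[id]] <<- 1L
    up <- unique(unlist(lapply(parents[[id]], visit)))
    anc[[id]] <<- unique(c(id, up))
    state[[id]] <<- 2L
    anc[[id]]
  }
  for (id in ids) visit(id)
  for (id in ids)
    if (!any(anc[[id]] %in% roots))
      stop_msg("term %s does not reach a root", id)
  structure(list(ids = ids, names = names, parents = parents,
                 roots = roots, ancestors = anc), class = "ontology")
}

#' Upward-propagated annotation map with information content
#'
#' Closes gene-to-term annotations under ancestors, then computes each
#' term's annotation probability p(t) = |genes(t)| / |universe| and
#' information content IC(t) = -log p(t) from the supplied corpus itself
#' (no external GO release), so analyses are self-contained.
#'
#' @param annotations two-column data.frame (gene, term) of direct
#'   annotations; extra columns (GAF-like) are ignored.
#' @param ontology an [read_obo()] / [build_ontology()] object.
#' @param universe optional gene universe; defaults to all annotated genes.
#' @return class `annotation_map`: list with `term_genes` (named list),
#'   `p`, `ic` (named numeric), `universe`.
#' @export
annotation_map <- function(annotations, ontology, universe = NULL) {
  stopifnot(inherits(ontology, "ontology"))
  ann <- data.frame(gene = as.character(annotations[[1]]),
                    term = as.character(annotations[[2]]))
  ann <- ann[ann$term %in% ontology$ids, , drop = FALSE]
  if (nrow(ann) == 0L) stop_msg("no annotation matches the ontology")
  if (is.null(universe)) universe <- unique(ann$gene)
  ann <- ann[ann$gene %in% universe, , drop = FALSE]
  # propagate each (gene, term) pair to all ancestors of the term
  prop <- data.frame(
    gene = rep(ann$gene, lengths(ontology$ancestors[ann$term])),
    term = unlist(ontology$ancestors[ann$term], use.names = FALSE))
  term_genes <- lapply(split(prop$gene, prop$term), unique)
  p <- stats::setNames(lengths(term_genes) / length(universe),
                       names(term_genes))
  structure(list(term_genes = term_genes, p = p, ic = -log(p),
                 universe = universe), class = "annotation_map")
}

#' Upper-tail hypergeometric term enrichment
#'
#' For every propagated term, tests over-representation of `gene_set`
#' within `universe`: \eqn{p = P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}, BH-adjusted; terms with
#' adjusted p below `alpha` are returned.
#'
#' @param gene_set character vector of genes of interest (subset of the
#'   universe).
#' @param ann an [annotation_map()] built on the same universe.
#' @param ontology the matching ontology (for term names).
#' @param alpha adjusted-p threshold (default 0.05); `alpha = 1` returns
#'   every term.
#' @return data.frame `term`, `name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   ordered by p.
#' @export
hypergeometric_enrichment <- function(gene_set, ann, ontology, alpha = 0.05) {
  stopifnot(inherits(ann, "annotation_map"), inherits(ontology, "ontology"))
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0L) stop_msg("empty gene set")
  if (length(ann$universe) == 0L) stop_msg("empty universe")
  if (!all(gene_set %in% ann$universe))
    stop_msg("gene set contains genes outside the universe")
  N <- length(ann$universe); n <- length(gene_set)
  terms <- names(ann$term_genes)
  K <- lengths(ann$term_genes)
  k <- vapply(ann$term_genes, function(g) sum(gene_set %in% g), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- adjust_pvalues(p, "bh")
  out <- data.frame(term = terms, name = unname(ontology$names[terms]),
                    k = k, K = K, n = n, N = N, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$q < alpha | alpha >= 1, , drop = FALSE]
  out[order(out$p, out$term), , drop = FALSE]
}

#' Relevance semantic similarity between two terms
#'
#' Schlicker-style relevance measure: over common ancestors a of the two
#' terms, \eqn{\max_a [2\,IC(a) / (IC(t_1) + IC(t_2))] (1 - p(a))}. The
#' similarity of a term with itself is \eqn{1 - p(t)}; terms whose only
#' common ancestor is the root score 0.
#'
#' @param t1,t2 term ids (must be annotated, p > 0).
#' @param ontology the ontology.
#' @param ann the annotation map.
#' @return similarity in [0, 1).
#' @export
relevance_similarity <- function(t1, t2, ontology, ann) {
  for (t in c(t1, t2))
    if (is.na(ann$p[t]) || ann$p[t] <= 0)
      stop_msg("term %s is not annotated in the corpus", t)
  denom <- ann$ic[[t1]] + ann$ic[[t2]]
  if (denom == 0) return(0)
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  common <- common[common %in% names(ann$p)]
  if (length(common) == 0L) return(0)
  max(2 * ann$ic[common] / denom * (1 - ann$p[common]))
}

relevance_matrix <- function(terms, ontology, ann) {
  n <- length(terms)
  S <- diag(1 - unname(ann$p[terms]), n)
  dimnames(S) <- list(terms, terms)
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      S[i, j] <- S[j, i] <-
        relevance_similarity(terms[i], terms[j], ontology, ann)
  S
}

# average-linkage clustering of terms at a similarity threshold
cluster_terms <- function(terms, ontology, ann, sim_threshold) {
  if (length(terms) == 1L)
    return(stats::setNames(1L, terms))
  S <- relevance_matrix(terms, ontology, ann)
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  stats::cutree(hc, h = 1 - sim_threshold)
}

#' Within-dataset redundancy reduction of enriched terms
#'
#' Clusters enriched terms by average-linkage hierarchical clustering on
#' 1 - relevance similarity, cutting the tree so merged clusters have
#' linkage similarity at least `sim_threshold`; each cluster is represented
#' by its member with the smallest enrichment p-value (ties broken by term
#' id).
#'
#' @param enriched a [hypergeometric_enrichment()] table.
#' @param ontology,ann ontology and annotation map.
#' @param sim_threshold similarity threshold in (0, 1] (default 0.8).
#' @return the enriched table with `cluster` and `representative` columns;
#'   representatives carry the minimum p of their cluster by construction.
#' @export
reduce_within_dataset <- function(enriched, ontology, ann,
                                  sim_threshold = 0.8) {
  if (sim_threshold <= 0 || sim_threshold > 1)
    stop_msg("'sim_threshold' must be in (0, 1]")
  if (nrow(enriched) == 0L) {
    enriched$cluster <- integer(); enriched$representative <- logical()
    return(enriched)
  }
  cl <- cluster_terms(enriched$term, ontology, ann, sim_threshold)
  enriched$cluster <- unname(cl[enriched$term])
  enriched$representative <- FALSE
  for (g in unique(enriched$cluster)) {
    rows <- which(enriched$cluster == g)
    best <- rows[order(enriched$p[rows], enriched$term[rows])][1]
    enriched$representative[best] <- TRUE
  }
  enriched
}

#' Cross-dataset merging of reduced term lists to common generic terms
#'
#' Pools the representative terms of several datasets, clusters them at
#' `sim_threshold` as in [reduce_within_dataset()], and represents each
#' cluster by the common ancestor of all its members with maximal
#' information content (the root, with a message, when nothing deeper is
#' shared). Per dataset the minimum enrichment p among its members of the
#' cluster is recorded. Output is ordered by decreasing number of enriched
#' datasets, then increasing mean p.
#'
#' @param dataset_terms named list; per dataset a data.frame with columns
#'   `term` and `p` (e.g. the `representative` rows of
#'   [reduce_within_dataset()]).
#' @param ontology,ann ontology and annotation map.
#' @param sim_threshold similarity threshold (default 0.8).
#' @return data.frame: `representative`, `rep_name`, `members`,
#'   `n_datasets`, `mean_p`, plus one `p_<dataset>` column per dataset.
#' @export
merge_across_datasets <- function(dataset_terms, ontology, ann,
                                  sim_threshold = 0.8) {
  stopifnot(is.list(dataset_terms), length(dataset_terms) >= 1,
            !is.null(names(dataset_terms)))
  pool <- unique(unlist(lapply(dataset_terms, `[[`, "term")))
  if (length(pool) == 0L) stop_msg("no terms to merge")
  cl <- cluster_terms(pool, ontology, ann, sim_threshold)
  rows <- lapply(unique(cl), function(g) {
    members <- names(cl)[cl == g]
    common <- Reduce(intersect, ontology$ancestors[members])
    common <- common[common %in% names(ann$ic)]
    if (length(common) == 0L || all(common %in% ontology$roots)) {
      rep <- ontology$roots[1]
      message(sprintf("cluster {%s}: no common ancestor below the root",
                      paste(members, collapse = ", ")))
    } else {
      rep <- common[order(-ann$ic[common], common)][1]
    }
    ps <- vapply(dataset_terms, function(df) {
      m <- df$p[df$term %in% members]
      if (length(m)) min(m) else NA_real_
    }, numeric(1))
    c(list(representative = rep, rep_name = unname(ontology$names[rep]),
           members = paste(sort(members), collapse = ","),
           n_datasets = sum(!is.na(ps)),
           mean_p = mean(ps, na.rm = TRUE)),
      stats::setNames(as.list(ps), paste0("p_", names(dataset_terms))))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out[order(-out$n_datasets, out$mean_p, out$representative), , drop = FALSE]
}
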