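ont <- make_toy_ontology()
corp <- make_toy_annotation(1000)
ann <- annotation_map(corp$table, ont)

test_that("OBO parsing builds the expected graph", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:R", "name: root", "",
    "[Term]", "id: GO:A", "name: process A", "is_a: GO:R ! root", "",
    "[Term]", "id: GO:A1", "name: sub A1", "is_a: GO:A", "",
    "[Term]", "id: GO:OLD", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), obo)
  o <- read_obo(obo)
  expect_setequal(o$ids, c("GO:R", "GO:A", "GO:A1"))
  expect_equal(o$roots, "GO:R")
  expect_setequal(o$ancestors[["GO:A1"]], c("GO:A1", "GO:A", "GO:R"))
  expect_equal(o$names[["GO:A"]], "process A")
  # cycles are rejected
  expect_error(build_ontology(c("a", "b"), c(a = "a", b = "b"),
                              list(a = "b", b = "a")), "cycle|root")
})

test_that("annotation propagation is upward closed with sane probabilities", {
  expect_equal(unname(ann$p["GO:R"]), 1)
  expect_equal(unname(ann$ic["GO:R"]), 0)
  # A inherits the A1 and A2 genes: p(A) = 4/1000
  expect_equal(unname(ann$p["GO:A"]), 0.004)
  expect_equal(unname(ann$p["GO:A1"]), 0.002)
  # upward closure: every gene of a term annotates all its ancestors
  for (t in names(ann$term_genes))
    for (a in ont$ancestors[[t]])
      expect_true(all(ann$term_genes[[t]] %in% ann$term_genes[[a]]))
  # p never increases from root to leaf
  for (t in names(ann$term_genes))
    for (a in ont$ancestors[[t]])
      expect_gte(ann$p[[a]], ann$p[[t]])
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  # N = 10, K = 5, n = 3, k = 3 -> p = C(5,3)/C(10,3) = 10/120
  o <- build_ontology(c("r", "t"), c(r = "root", t = "term"),
                      list(r = character(), t = "r"))
  genes <- paste0("g", 1:10)
  tab <- rbind(data.frame(gene = genes, term = "r"),
               data.frame(gene = genes[1:5], term = "t"))
  a <- annotation_map(tab, o)
  enr <- hypergeometric_enrichment(genes[1:3], a, o, alpha = 1)
  expect_equal(enr$p[enr$term == "t"], 10 / 120)
  # the root annotates the whole universe -> p = 1
  expect_equal(enr$p[enr$term == "r"], 1)
  # k = 0 -> upper tail includes everything -> p = 1
  enr0 <- hypergeometric_enrichment(genes[6:8], a, o, alpha = 1)
  expect_equal(enr0$p[enr0$term == "t"], 1)
  expect_error(hypergeometric_enrichment(character(), a, o), "empty")
  expect_error(hypergeometric_enrichment("stranger", a, o), "universe")
})

test_that("relevance similarity matches hand evaluation on the toy DAG", {
  # hand-computed: p(A1) = p(A2) = 0.002, p(A) = 0.004, p(B1) = p(B) = 0.01
  icA1 <- -log(0.002); icA <- -log(0.004)
  expect_equal(relevance_similarity("GO:A1", "GO:A1", ont, ann),
               1 - 0.002)
  expect_equal(relevance_similarity("GO:A1", "GO:A2", ont, ann),
               2 * icA / (2 * icA1) * (1 - 0.004))
  # only shared ancestor is the root -> similarity 0
  expect_equal(relevance_similarity("GO:A1", "GO:B1", ont, ann), 0)
  # ancestor-descendant pair: MICA is the ancestor itself
  expect_equal(relevance_similarity("GO:A1", "GO:A", ont, ann),
               2 * icA / (icA1 + icA) * (1 - 0.004))
  # symmetry and range over all annotated pairs
  terms <- c("GO:A", "GO:A1", "GO:A2", "GO:B", "GO:B1")
  for (i in terms) for (j in terms) {
    s <- relevance_similarity(i, j, ont, ann)
    expect_equal(s, relevance_similarity(j, i, ont, ann))
    expect_gte(s, 0); expect_lt(s, 1)
  }
  expect_equal(relevance_similarity("GO:R", "GO:R", ont, ann), 0)
})

test_that("within-dataset reduction merges only close terms", {
  enr <- data.frame(
    term = c("GO:A1", "GO:A2", "GO:B1"),
    name = c("subprocess A1", "subprocess A2", "subprocess B1"),
    p = c(0.001, 0.0005, 0.002), q = c(0.003, 0.003, 0.004))
  red <- reduce_within_dataset(enr, ont, ann, sim_threshold = 0.8)
  # sim(A1, A2) = 0.885 >= 0.8 merges them; B1 is alone
  expect_equal(length(unique(red$cluster)), 2)
  expect_equal(red$cluster[1], red$cluster[2])
  # representative is the member with the smallest p
  expect_true(red$representative[red$term == "GO:A2"])
  expect_false(red$representative[red$term == "GO:A1"])
  expect_true(red$representative[red$term == "GO:B1"])
  # threshold 1 only merges similarity-1 pairs -> all singletons here
  red1 <- reduce_within_dataset(enr, ont, ann, sim_threshold = 1)
  expect_equal(length(unique(red1$cluster)), 3)
  # representative p is the cluster minimum by construction
  for (g in unique(red$cluster)) {
    rows <- red[red$cluster == g, ]
    expect_equal(rows$p[rows$representative], min(rows$p))
  }
})

test_that("cross-dataset merge picks the deepest common ancestor", {
  d1 <- data.frame(term = "GO:A1", p = 0.001)
  d2 <- data.frame(term = "GO:A2", p = 0.01)
  out <- merge_across_datasets(list(x = d1, y = d2), ont, ann,
                               sim_threshold = 0.8)
  # siblings cluster together; their deepest common ancestor is A
  expect_equal(nrow(out), 1)
  expect_equal(out$representative, "GO:A")
  expect_equal(out$n_datasets, 2)
  expect_equal(out$p_x, 0.001)
  expect_equal(out$p_y, 0.01)
  # a term shared verbatim represents itself (it is its own deepest
  # common ancestor)
  out2 <- merge_across_datasets(list(x = d1, y = d1), ont, ann)
  expect_equal(out2$representative, "GO:A1")
  expect_equal(out2$n_datasets, 2)
  # one dataset, one term
  out3 <- merge_across_datasets(list(x = d2), ont, ann)
  expect_equal(out3$representative, "GO:A2")
  expect_equal(out3$n_datasets, 1)
  # ordering: enriched-dataset count dominates, then mean p
  d3 <- data.frame(term = c("GO:A1", "GO:B1"), p = c(0.02, 0.001))
  out4 <- merge_across_datasets(list(x = d1, y = d2, z = d3), ont, ann)
  expect_equal(out4$representative[1], "GO:A")
  expect_equal(out4$n_datasets, c(3, 1))
})
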