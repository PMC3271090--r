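mining_fixture <- function() {
  g <- mini_ontology(c(
    "GO:0009790" = "embryonic development",
    "DOID:4"     = "disease",
    "GO:0005575" = "cellular component",
    "GO:0007599" = "hemostasis"))
  list(graph = g, dict = build_dictionary(g))
}

test_that("one article about one gene yields candidate annotations", {
  fx <- mining_fixture()
  doc <- gene_document("DAX1", paste(
    "DAX1 controls the activity of certain genes in the cells that form",
    "these tissues during embryonic development."))
  cs <- mine_document(doc, fx$dict, fx$graph,
                      excluded_labels = unlist(default_term_filters()))
  expect_equal(cs$candidates$gene_id, "DAX1")
  expect_equal(cs$candidates$term_id, "GO:0009790")
  expect_equal(cs$candidates$n_mentions, 1L)
})

test_that("uninformative labels are filtered after recognition", {
  fx <- mining_fixture()
  doc <- gene_document("G1", "This disease is a cellular component story.")
  cs <- mine_document(doc, fx$dict, fx$graph,
                      excluded_labels = unlist(default_term_filters()))
  expect_equal(nrow(cs$candidates), 0)
  # without the filter both candidates appear
  cs2 <- mine_document(doc, fx$dict, fx$graph)
  expect_setequal(cs2$candidates$term_id, c("DOID:4", "GO:0005575"))
})

test_that("repeated mentions aggregate into one candidate", {
  fx <- mining_fixture()
  doc <- gene_document("F2", paste(
    "Thrombin acts in hemostasis.",
    "Hemostasis requires it.",
    "Without it hemostasis fails."))
  cs <- mine_document(doc, fx$dict, fx$graph)
  expect_equal(nrow(cs$candidates), 1)
  expect_equal(cs$candidates$n_mentions, 3L)
  expect_equal(nrow(cs$mentions), 3)
  expect_equal(cs$candidates$first_evidence_sentence,
               "Thrombin acts in hemostasis.")
})

test_that("empty documents yield empty results", {
  fx <- mining_fixture()
  doc <- gene_document("G0", "")
  cs <- mine_document(doc, fx$dict, fx$graph)
  expect_equal(nrow(cs$candidates), 0)
})

test_that("mining recovers planted gene-term truth exactly", {
  toy <- make_toy_ontology(25, seed = 40)
  g <- toy_graph(toy)
  d <- build_dictionary(g)
  corp <- make_corpus(toy, n_genes = 20, mentions_per_gene = 5,
                      markup_rate = 0.25, imported_block_rate = 0.2,
                      seed = 41)
  cs <- mine_corpus(corp$docs, d, g, drop_imported = TRUE)
  got <- cs$candidates[order(cs$candidates$gene_id, cs$candidates$term_id), ]
  want <- corpus_truth_pairs(corp, drop_imported = TRUE)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$term_id, want$term_id)
  # keeping imported text enlarges (weakly) the candidate set
  cs_all <- mine_corpus(corp$docs, d, g, drop_imported = FALSE)
  all_pairs <- corpus_truth_pairs(corp, drop_imported = FALSE)
  expect_equal(nrow(cs_all$candidates), nrow(all_pairs))
})

test_that("all-imported corpora mine to nothing when imported text is dropped", {
  toy <- make_toy_ontology(15, seed = 42)
  g <- toy_graph(toy)
  d <- build_dictionary(g)
  corp <- make_corpus(toy, n_genes = 8, mentions_per_gene = 3,
                      imported_block_rate = 1, seed = 43)
  cs <- mine_corpus(corp$docs, d, g, drop_imported = TRUE)
  expect_equal(nrow(cs$candidates), 0)
})

test_that("every candidate keeps recognizer evidence (conservation)", {
  toy <- make_toy_ontology(20, seed = 44)
  g <- toy_graph(toy)
  d <- build_dictionary(g)
  corp <- make_corpus(toy, n_genes = 10, mentions_per_gene = 4, seed = 45)
  cs <- mine_corpus(corp$docs, d, g)
  expect_true(all(cs$candidates$n_mentions >= 1))
  for (i in seq_len(nrow(cs$candidates))) {
    ev <- cs$mentions[cs$mentions$gene_id == cs$candidates$gene_id[i] &
                        cs$mentions$term_id == cs$candidates$term_id[i], ]
    expect_equal(nrow(ev), cs$candidates$n_mentions[i])
    doc <- corp$docs[[cs$candidates$gene_id[i]]]
    for (j in seq_len(nrow(ev))) {
      sent <- doc$blocks$text[doc$blocks$sentence_index ==
                                ev$sentence_index[j]]
      redone <- recognize(sent, d, ev$sentence_index[j])
      expect_true(ev$term_id[j] %in% redone$term_id)
    }
  }
})

test_that("growing the exclusion list never adds candidates", {
  toy <- make_toy_ontology(20, seed = 46)
  g <- toy_graph(toy)
  d <- build_dictionary(g)
  corp <- make_corpus(toy, n_genes = 10, mentions_per_gene = 4, seed = 47)
  n_prev <- Inf
  excl <- character()
  for (k in c(0, 3, 8, 15)) {
    excl <- toy$labels[seq_len(k)]
    n <- nrow(mine_corpus(corp$docs, d, g,
                          excluded_labels = excl)$candidates)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("namespace partition is disjoint and size-preserving", {
  g <- mini_ontology(c(B1 = "budding", B2 = "blooming"),
                     namespace = "biological_process")
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2",
               "[Term]", "id: B1", "name: budding",
               "namespace: biological_process",
               "[Term]", "id: B2", "name: blooming",
               "namespace: biological_process",
               "[Term]", "id: M1", "name: binding",
               "namespace: molecular_function"), path)
  g <- read_obo(path)
  cand <- data.frame(gene_id = c("g1", "g1", "g2"),
                     term_id = c("B1", "M1", "B2"))
  parts <- partition_by_namespace(cand, g)
  expect_setequal(names(parts), c("biological_process",
                                  "molecular_function"))
  expect_equal(nrow(parts$biological_process), 2)
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(cand))
  expect_equal(length(partition_by_namespace(cand[0, ], g)), 0)
})

test_that("candidate tables survive a TSV round trip", {
  toy <- make_toy_ontology(15, seed = 48)
  g <- toy_graph(toy)
  corp <- make_corpus(toy, n_genes = 5, mentions_per_gene = 3, seed = 49)
  cs <- mine_corpus(corp$docs, build_dictionary(g), g)
  path <- tempfile(fileext = ".tsv")
  write_candidates(cs, path)
  back <- read_candidates(path)
  expect_equal(back$gene_id, cs$candidates$gene_id)
  expect_equal(back$term_id, cs$candidates$term_id)
  expect_equal(back$n_mentions, cs$candidates$n_mentions)
})
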