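lineage_fixture <- function() {
  mini_ontology(c(
    "GO:0007599" = "hemostasis",
    "GO:0007596" = "blood coagulation",
    "GO:10"      = "transcription from RNA polymerase II promoter",
    "GO:11"      = "positive regulation of transcription from RNA polymerase II promoter",
    "GO:root"    = "biological process"),
    edge_df("GO:0007596", "is_a", "GO:0007599",
            "GO:0007599", "is_a", "GO:root",
            "GO:10", "is_a", "GO:root",
            "GO:11", "positively_regulates", "GO:10"))
}

test_that("candidates broader than a reference term classify MORE_GENERAL", {
  g <- lineage_fixture()
  expect_equal(classify_candidate("GO:0007599", "GO:0007596", g, go_policy()),
               "MORE_GENERAL")
})

test_that("regulation lineage classifies the regulator as MORE_SPECIFIC", {
  g <- lineage_fixture()
  expect_equal(classify_candidate("GO:11", "GO:10", g, go_policy()),
               "MORE_SPECIFIC")
  # without regulation edges in the policy there is no lineage match
  expect_equal(classify_candidate("GO:11", "GO:10", g, do_policy()), "NONE")
})

test_that("exact matches win over lineage matches", {
  g <- lineage_fixture()
  expect_equal(classify_candidate("GO:0007596", "GO:0007596", g), "EXACT")
  expect_equal(classify_candidate("GO:0007596",
                                  c("GO:0007596", "GO:root"), g), "EXACT")
})

test_that("precedence between simultaneous broader and narrower matches", {
  # chain a -> b -> c; candidate b is narrower than c and broader than a
  g <- mini_ontology(c(A = "low", B = "mid", C = "high"),
                     edge_df("A", "is_a", "B", "B", "is_a", "C"))
  refs <- c("A", "C")
  expect_equal(classify_candidate("B", refs, g), "MORE_SPECIFIC")
  expect_equal(classify_candidate("B", refs, g,
                                  precedence = "general_first"),
               "MORE_GENERAL")
  # order of the reference terms never matters
  expect_equal(classify_candidate("B", rev(refs), g), "MORE_SPECIFIC")
})

test_that("classification agrees with a materialized-closure oracle", {
  toy <- make_toy_ontology(30, relation_mix = c(is_a = 0.7, part_of = 0.3),
                           seed = 50)
  g <- toy_graph(toy)
  pol <- relation_policy(c("is_a", "part_of"))
  R <- oracle_reachability(g, pol)
  withr::with_seed(51, {
    for (rep in 1:60) {
      cand <- sample(g$id, 1)
      refs <- sample(g$id, sample(1:4, 1))
      want <- if (cand %in% refs) "EXACT"
      else if (any(R[cand, refs])) "MORE_SPECIFIC"  # some ref above cand
      else if (any(R[refs, cand])) "MORE_GENERAL"   # some ref below cand
      else "NONE"
      expect_equal(classify_candidate(cand, refs, g, pol), want)
    }
  })
})

test_that("summary counts partition the candidate set", {
  g <- lineage_fixture()
  cand <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    term_id = c("GO:0007599", "GO:11", "GO:10", "GO:0007596"))
  refs <- reference_set(data.frame(
    gene_id = c("g1", "g1", "g2"),
    term_id = c("GO:0007596", "GO:10", "GO:10")))
  cmp <- compare_annotations(cand, refs, g, go_policy())
  s <- cmp$summary
  expect_equal(s$exact + s$more_general + s$child + s$none, s$all)
  expect_equal(s$all, nrow(cand))
  # gene without references contributes NONE
  expect_equal(cmp$table$classification[cmp$table$gene_id == "g3"], "NONE")
  # empty reference set: everything NONE
  s0 <- compare_annotations(cand, reference_set(
    data.frame(gene_id = character(), term_id = character())),
    g, go_policy())$summary
  expect_equal(s0$none, nrow(cand))
  # candidates identical to references: all EXACT
  refs_id <- reference_set(cand)
  s1 <- compare_annotations(cand, refs_id, g, go_policy())$summary
  expect_equal(s1$exact, nrow(cand))
})

test_that("noisy-reference proportions land in their binomial bands", {
  toy <- make_toy_ontology(40, relation_mix = c(is_a = 0.8, part_of = 0.2),
                           seed = 52)
  g <- toy_graph(toy)
  withr::with_seed(53, {
    pairs <- data.frame(gene_id = sprintf("G%04d", 1:800),
                        term_id = sample(toy$ids[-1], 800, replace = TRUE))
  })
  nr <- make_reference(pairs, g, drop_rate = 0.2, generalize_rate = 0.3,
                       seed = 54)
  cmp <- compare_annotations(pairs, nr$refs, g,
                             relation_policy(g$relation_types))
  obs <- c(EXACT = cmp$summary$exact, MORE_SPECIFIC = cmp$summary$child,
           NONE = cmp$summary$none) / cmp$summary$all
  for (i in seq_len(nrow(nr$expected))) {
    cl <- nr$expected$classification[i]
    expect_gte(obs[[cl]], nr$expected$band_lo[i])
    expect_lte(obs[[cl]], nr$expected$band_hi[i])
  }
})

test_that("precision bounds follow the tally arithmetic", {
  s <- comparison_summary(exact = 2, more_general = 1, child = 1, none = 6)
  t <- evaluation_tally(e1a = 3, e1b = 1, e1c = 0, e2a = 1, e2b = 1, e3a = 1)
  pb <- precision_bounds(s, t)
  expect_equal(pb$lower, 0.70, tolerance = 1e-12)
  expect_equal(pb$upper, 0.80, tolerance = 1e-12)

  # a unanimous category-1 sample collapses the novel-pool scaling to 1
  t1 <- evaluation_tally(e1a = 7)
  pb1 <- precision_bounds(s, t1)
  expect_equal(pb1$lower, (2 + 1 + 6 + 1) / 10)
  expect_equal(pb1$upper, pb1$lower)

  # no novel pool: the tally is irrelevant
  s0 <- comparison_summary(exact = 3, more_general = 2, child = 0, none = 0)
  pb0 <- precision_bounds(s0, t)
  expect_equal(pb0$lower, 1)
  expect_equal(pb0$upper, 1)

  # dropping 1C from the valid grouping lowers both bounds
  t2 <- evaluation_tally(e1a = 2, e1b = 1, e1c = 2, e2a = 1, e3b = 1)
  expect_lt(precision_bounds(s, t2, include_1c = FALSE)$lower,
            precision_bounds(s, t2, include_1c = TRUE)$lower)
})

test_that("precision bounds are monotone and stay inside [0, 1]", {
  s <- comparison_summary(exact = 5, more_general = 2, child = 3, none = 10)
  prev <- -1
  for (k in 0:10) {
    t <- evaluation_tally(e1a = k, e3b = 10 - k)
    pb <- precision_bounds(s, t)
    expect_gte(pb$lower, prev)
    expect_lte(pb$lower, pb$upper)
    expect_gte(pb$lower, 0)
    expect_lte(pb$upper, 1)
    prev <- pb$lower
  }
  expect_error(precision_bounds(s, evaluation_tally()), "positive")
  expect_error(evaluation_tally(e1a = -1), "non-negative")
})

test_that("reference readers parse gene2go-style and GAF formats", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("#tax_id\tGeneID\tGO_ID\tEvidence",
               "9606\t123\tGO:0007596\tIEA",
               "9606\t123\tGO:0007599\tEXP",
               "9606\t456\tGO:0007596\tIDA"), p)
  refs <- read_gene2go(p)
  expect_equal(nrow(refs$annotations), 3)
  expect_setequal(ref_terms(refs, "123"), c("GO:0007596", "GO:0007599"))
  non_iea <- filter_evidence(refs)
  expect_equal(nrow(non_iea$annotations), 2)

  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("UniProtKB", "P00734", "F2", "", "GO:0007596", "PMID:1",
                     "IDA", "", "P", "prothrombin", "", "protein", "taxon:9606",
                     "20100101", "GOA", "", "", sep = "\t")), gaf)
  refs2 <- read_gaf(gaf)
  expect_equal(refs2$annotations$gene_id, "P00734")
  expect_equal(refs2$annotations$term_id, "GO:0007596")
  expect_equal(refs2$annotations$evidence, "IDA")
})

test_that("novel-candidate sampling is seeded and drawn from the pool", {
  g <- lineage_fixture()
  cand <- data.frame(gene_id = rep("g1", 4),
                     term_id = c("GO:0007599", "GO:11", "GO:10",
                                 "GO:0007596"))
  refs <- reference_set(data.frame(gene_id = "g1", term_id = "GO:10"))
  cmp <- compare_annotations(cand, refs, g, go_policy())
  s1 <- sample_novel_candidates(cmp, 2, seed = 7)
  s2 <- sample_novel_candidates(cmp, 2, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$classification %in% c("NONE", "MORE_SPECIFIC")))
})
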