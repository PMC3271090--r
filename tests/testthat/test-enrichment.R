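test_that("one-tailed Fisher p behaves at the boundaries", {
  # zero overlap is never evidence of enrichment
  expect_identical(fisher_one_tailed(contingency_table(0, 10, 5, 85)), 1)
  expect_identical(fisher_one_tailed(contingency_table(0, 0, 0, 0)), 1)
  # full enumeration: choose(2,2)*choose(2,0)/choose(4,2) = 1/6
  expect_equal(fisher_one_tailed(contingency_table(2, 0, 0, 2)), 1 / 6,
               tolerance = 1e-12)
  expect_error(contingency_table(-1, 0, 0, 2), "non-negative")
})

test_that("Fisher p matches the log-factorial oracle on random tables", {
  withr::with_seed(60, {
    for (i in 1:1000) {
      cells <- as.integer(sample(0:12, 4, replace = TRUE))
      p <- fisher_one_tailed(contingency_table(cells[1], cells[2],
                                               cells[3], cells[4]))
      q <- oracle_fisher_upper(cells[1], cells[2], cells[3], cells[4])
      expect_equal(p, q, tolerance = 1e-12)
    }
  })
})

test_that("p decreases as overlap grows with fixed margins", {
  # margins: mined = 10, truth = 8, N = 40
  prev <- Inf
  for (a in 0:8) {
    p <- fisher_one_tailed(contingency_table(a, 10 - a, 8 - a,
                                             40 - 10 - 8 + a))
    expect_lte(p, prev + 1e-15)
    prev <- p
  }
})

test_that("odds ratio follows the degenerate-cell conventions", {
  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1)), 1)
  expect_equal(odds_ratio(contingency_table(5, 5, 5, 85)), 17)
  expect_identical(odds_ratio(contingency_table(3, 0, 2, 10)), Inf)
  expect_identical(odds_ratio(contingency_table(0, 0, 2, 10)), NA_real_)
})

test_that("term-gene set inversion is a plain inverse index", {
  cand <- data.frame(gene_id = c("g1", "g2", "g2", "g1"),
                     term_id = c("T1", "T1", "T2", "T1"))
  sets <- build_term_gene_sets(cand)
  expect_equal(sets$T1, c("g1", "g2"))
  expect_equal(sets$T2, "g2")
  expect_length(build_term_gene_sets(cand[0, ]), 0)
})

test_that("identical corpora produce zero gained and lost terms", {
  truth <- reference_set(data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    term_id = c("T1", "T1", "T2", "T2")))
  mined <- data.frame(gene_id = c("g1", "g2"), term_id = c("T1", "T1"))
  bg <- sprintf("g%d", 1:20)
  ex <- run_enrichment_experiment(truth, mined, mined, bg, alpha = 0.05)
  expect_equal(ex$gained, 0)
  expect_equal(ex$lost, 0)
  expect_equal(ex$results$p_base, ex$results$p_aug)
})

test_that("disjoint mined and truth sets are never significant", {
  truth <- reference_set(data.frame(gene_id = sprintf("g%d", 1:5),
                                    term_id = "T1"))
  mined <- data.frame(gene_id = sprintf("g%d", 6:10), term_id = "T1")
  ex <- run_enrichment_experiment(truth, mined, mined,
                                  sprintf("g%d", 1:50), alpha = 0.01)
  expect_equal(ex$significant_baseline, 0)
  expect_equal(ex$results$p_base, 1)
})

test_that("experiment tables conserve the set-size margins", {
  sc <- make_enrichment_scenario(n_genes = 120, n_terms = 10,
                                 planted_term_size = 15, noise_rate = 0.01,
                                 seed = 61)
  dict <- build_dictionary(sc$graph)
  mb <- mine_corpus(sc$baseline_docs, dict, sc$graph)
  ma <- mine_corpus(sc$augmentation_docs, dict, sc$graph)
  aug <- rbind(mb$candidates[, c("gene_id", "term_id")],
               ma$candidates[, c("gene_id", "term_id")])
  ex <- run_enrichment_experiment(sc$truth, mb, aug, sc$background)
  truth_sets <- build_term_gene_sets(sc$truth)
  base_sets <- build_term_gene_sets(mb)
  for (i in seq_len(nrow(ex$results))) {
    r <- ex$results[i, ]
    expect_equal(r$a_base + r$c_base, length(truth_sets[[r$term_id]]))
    mined_n <- length(intersect(base_sets[[r$term_id]], sc$background))
    expect_equal(r$a_base + r$b_base, mined_n)
    expect_equal(r$a_base + r$b_base + r$c_base + r$d_base,
                 length(sc$background))
  }
})

test_that("missing background genes and empty inputs raise errors", {
  truth <- reference_set(data.frame(gene_id = "g1", term_id = "T1"))
  mined <- data.frame(gene_id = "g1", term_id = "T1")
  expect_error(run_enrichment_experiment(truth, mined, mined, character()),
               "empty")
  expect_error(run_enrichment_experiment(truth, mined, mined, "g2"),
               "background")
  expect_error(null_simulation("g1", "g1", sprintf("g%d", 1:10), 5,
                               iterations = 0), "positive")
  expect_error(null_simulation("g1", "g1", sprintf("g%d", 1:10), 50),
               "set_size")
})

test_that("identical mined sets give concordant null simulations", {
  bg <- sprintf("g%03d", 1:100)
  genes <- bg[1:10]
  sim <- null_simulation(genes, genes, bg, set_size = 15, iterations = 50,
                         seed = 62)
  expect_equal(sim$gained, 0)
  expect_equal(sim$lost, 0)
  expect_equal(sim$log$p_base, sim$log$p_aug)
  # seeded reproducibility
  sim2 <- null_simulation(genes, genes, bg, set_size = 15, iterations = 50,
                          seed = 62)
  expect_identical(sim$log, sim2$log)
})

test_that("null p-values are stochastically conservative", {
  bg <- sprintf("g%03d", 1:80)
  mined <- bg[1:12]
  sim <- null_simulation(mined, mined, bg, set_size = 10,
                         iterations = 400, seed = 63)
  # discrete one-sided test: P(p <= t) <= t for every threshold
  for (t in c(0.01, 0.05, 0.1, 0.25)) {
    emp <- mean(sim$log$p_base <= t)
    band <- stats::qbinom(0.999, 400, t) / 400
    expect_lte(emp, band)
  }
})

test_that("significance profiles tabulate multiple alpha levels", {
  truth <- reference_set(data.frame(gene_id = sprintf("g%d", 1:10),
                                    term_id = "T1"))
  mined <- data.frame(gene_id = sprintf("g%d", 1:10), term_id = "T1")
  ex <- run_enrichment_experiment(truth, mined, mined,
                                  sprintf("g%d", 1:200))
  prof <- significance_profile(ex)
  expect_equal(prof$alpha, c(0.05, 0.01, 0.001))
  expect_true(all(prof$significant_baseline == 1))
})
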