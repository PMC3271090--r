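# Seeded generators: toy ontologies, planted-mention corpora, noisy
# reference sets and planted enrichment scenarios. Identical spec +
# seed always reproduces byte-identical output (Mersenne-Twister via
# withr::with_seed; character sorts use radix order).

# Distractor vocabulary: common English words, structurally disjoint
# from generated term labels (labels are built from pseudo-word
# syllables and checked against this list).
.distractor_words <- c(
  "analysis", "apple", "autumn", "basket", "bridge", "bright", "candle",
  "carbon", "castle", "cellar", "circle", "cloudy", "copper", "corner",
  "cotton", "current", "curtain", "dinner", "double", "dragon", "eleven",
  "engine", "evening", "fabric", "factor", "feather", "filter", "finger",
  "flower", "forest", "fortune", "garden", "gentle", "glacier", "golden",
  "hammer", "harbor", "hollow", "honest", "hunter", "island", "jacket",
  "jungle", "kitchen", "ladder", "lantern", "launch", "lecture", "lemon",
  "letter", "little", "lumber", "magnet", "mantle", "marble", "market",
  "meadow", "medal", "mellow", "middle", "mirror", "modern", "morning",
  "mountain", "muffin", "narrow", "needle", "number", "orange", "orbit",
  "outline", "oyster", "paddle", "palace", "paper", "pebble", "pencil",
  "pepper", "picture", "pillow", "planet", "plastic", "pocket", "powder",
  "puzzle", "rabbit", "ladle", "random", "reason", "ribbon", "river",
  "rocket", "saddle", "sailor", "sample", "season", "shadow", "shelter",
  "silver", "simple", "singer", "sister", "slender", "smooth", "socket",
  "spring", "square", "stable", "steady", "stone", "stream", "street",
  "string", "summer", "sunset", "supper", "table", "tailor", "temple",
  "tender", "thunder", "ticket", "timber", "tissue", "tunnel", "turtle",
  "valley", "velvet", "village", "vivid", "wagon", "walnut", "weather",
  "window", "winter", "wonder", "yellow", "zigzag"
)

sort_c <- function(x) sort(x, method = "radix")

# pseudo-word labels: CV(C) syllables, never an English distractor word
make_labels <- function(n, words_per_label = 1:2) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  word <- function() {
    k <- sample(2:3, 1)
    w <- paste0(paste0(sample(cons, k, replace = TRUE),
                       sample(vow, k, replace = TRUE), collapse = ""),
                sample(cons, 1))
    w
  }
  out <- character(0)
  used_words <- character(0)
  while (length(out) < n) {
    nw <- sample(words_per_label, 1)
    ws <- replicate(nw, word())
    if (any(ws %in% .distractor_words)) next
    lab <- paste(ws, collapse = " ")
    if (lab %in% out) next
    out <- c(out, lab)
    used_words <- union(used_words, ws)
  }
  out
}

#' Generate a toy OBO ontology
#'
#' Builds a random DAG of `n_terms` pseudo-labelled terms: term 1 is
#' the root; every later term draws 1-2 parents among earlier terms
#' (respecting `max_children`), each edge labelled by a relation drawn
#' from `relation_mix`. The result is acyclic under every relation
#' subset by construction. A fraction of terms can be marked obsolete.
#' Output is deterministic: the same spec and seed give a byte-identical
#' OBO file.
#'
#' @param n_terms number of terms (>= 1).
#' @param max_children cap on children per term.
#' @param relation_mix named numeric vector of relation proportions,
#'   e.g. `c(is_a = 0.7, part_of = 0.3)`.
#' @param words_per_label label lengths in words.
#' @param obsolete_rate fraction of non-root terms marked obsolete.
#' @param namespace namespace string written on each term.
#' @param id_prefix accession prefix (default "TOY").
#' @param seed integer seed.
#' @return A list of class `toy_ontology`: `obo_lines` (the OBO file as
#'   text), `ids`, `labels`, `obsolete`, and `edges` (truth adjacency:
#'   `child`, `relation`, `parent`).
#' @export
make_toy_ontology <- function(n_terms, max_children = 3L,
                              relation_mix = c(is_a = 1),
                              words_per_label = 1:2,
                              obsolete_rate = 0,
                              namespace = "toy_process",
                              id_prefix = "TOY", seed = 1L) {
  stopifnot(n_terms >= 1)
  withr::with_seed(seed, {
    ids <- sprintf("%s:%07d", id_prefix, seq_len(n_terms))
    labels <- make_labels(n_terms, words_per_label)
    nchild <- integer(n_terms)
    edges <- list()
    for (i in seq_len(n_terms)[-1]) {
      open <- which(nchild[seq_len(i - 1L)] < max_children)
      if (length(open) == 0L) {
        stop("infeasible ontology spec: no term can accept more children")
      }
      np <- min(sample(1:2, 1), length(open))
      parents <- if (length(open) == 1L) open else sample(open, np)
      for (p in parents) {
        rel <- sample(names(relation_mix), 1, prob = relation_mix)
        edges[[length(edges) + 1L]] <- c(ids[i], rel, ids[p])
        nchild[p] <- nchild[p] + 1L
      }
    }
    obsolete <- rep(FALSE, n_terms)
    if (obsolete_rate > 0 && n_terms > 1L) {
      obsolete[-1] <- stats::runif(n_terms - 1L) < obsolete_rate
    }
  })
  edges <- if (length(edges)) {
    data.frame(child = vapply(edges, `[[`, "", 1),
               relation = vapply(edges, `[[`, "", 2),
               parent = vapply(edges, `[[`, "", 3),
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), relation = character(),
               parent = character(), stringsAsFactors = FALSE)
  }
  lines <- c("format-version: 1.2", paste0("ontology: ", tolower(id_prefix)))
  for (i in seq_len(n_terms)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", ids[i]),
               paste0("name: ", labels[i]),
               paste0("namespace: ", namespace))
    ei <- edges[edges$child == ids[i], , drop = FALSE]
    for (j in seq_len(nrow(ei))) {
      lines <- c(lines, if (ei$relation[j] == "is_a") {
        paste0("is_a: ", ei$parent[j])
      } else {
        paste0("relationship: ", ei$relation[j], " ", ei$parent[j])
      })
    }
    if (obsolete[i]) lines <- c(lines, "is_obsolete: true")
  }
  structure(list(obo_lines = lines, ids = ids, labels = labels,
                 obsolete = obsolete, edges = edges,
                 namespace = namespace),
            class = "toy_ontology")
}

#' Write a toy ontology to an OBO file
#'
#' @param toy a [make_toy_ontology()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(toy, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(toy$obo_lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Load a toy ontology without the file round trip
#'
#' @param toy a [make_toy_ontology()] result.
#' @return An `ontology_graph`.
#' @export
toy_graph <- function(toy) {
  path <- tempfile(fileext = ".obo")
  on.exit(unlink(path))
  write_obo(toy, path)
  read_obo(path)
}

#' Generate a gene-article corpus with planted term mentions
#'
#' Each gene gets one article of `rpois(mentions_per_gene)` sentences;
#' every sentence embeds exactly one planted term label between
#' distractor words, so the recognizer's output can be scored against
#' exact ground truth. Wiki markup (bold wrappers, piped links,
#' citation tags) is injected into a fraction `markup_rate` of
#' sentences; cleaning must restore the recorded plain text exactly.
#' A fraction `imported_block_rate` of sentences is attributed to a bot
#' author and flagged as imported.
#'
#' Planted labels are drawn from the non-obsolete, non-root-filtered
#' dictionary-eligible terms of `toy`. The distractor vocabulary must
#' be disjoint from all term labels; a collision is an error.
#'
#' @param toy a [make_toy_ontology()] result.
#' @param n_genes number of genes.
#' @param mentions_per_gene Poisson mean of planted mentions per gene.
#' @param plantable_terms term ids eligible for planting (default: all
#'   non-obsolete terms).
#' @param distractors distractor word vocabulary.
#' @param markup_rate fraction of sentences receiving wiki markup.
#' @param imported_block_rate fraction of sentences flagged imported.
#' @param bot_author author name used for imported sentences.
#' @param seed integer seed.
#' @return A list of class `toy_corpus`: `docs` (named list of
#'   [gene_document()]), `truth` (data.frame `gene_id`, `term_id`,
#'   `sentence_index`, `imported`, `plain_sentence`), and `raw` (named
#'   list of raw wikitext strings).
#' @export
make_corpus <- function(toy, n_genes, mentions_per_gene = 3,
                        plantable_terms = NULL,
                        distractors = .distractor_words,
                        markup_rate = 0.2, imported_block_rate = 0,
                        bot_author = "ProteinBoxBot", seed = 1L) {
  label_tokens <- unique(c(toy$labels,
                           unlist(strsplit(toy$labels, " ", fixed = TRUE))))
  if (any(distractors %in% label_tokens)) {
    stop("distractor vocabulary collides with term labels: ",
         paste(intersect(distractors, label_tokens), collapse = ", "))
  }
  if (is.null(plantable_terms)) plantable_terms <- toy$ids[!toy$obsolete]
  lab_of <- stats::setNames(toy$labels, toy$ids)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  docs <- vector("list", n_genes)
  raws <- vector("list", n_genes)
  truth <- list()
  withr::with_seed(seed, {
    for (gi in seq_len(n_genes)) {
      k <- stats::rpois(1, mentions_per_gene)
      sents <- character(k)
      wiki <- character(k)
      imported <- logical(k)
      terms <- character(k)
      for (si in seq_len(k)) {
        tm <- sample(plantable_terms, 1)
        pre <- sample(distractors, sample(2:4, 1))
        post <- sample(distractors, sample(2:4, 1))
        words <- c(pre, lab_of[[tm]], post)
        plain <- paste0(paste(words, collapse = " "), ".")
        substr(plain, 1, 1) <- toupper(substr(plain, 1, 1))
        w <- plain
        if (stats::runif(1) < markup_rate) {
          # decorate a distractor and add a citation tag; the label
          # itself stays plain so cleaning restores `plain` exactly
          tgt <- post[length(post)]
          w <- sub(paste0(" ", tgt, "\\."),
                   paste0(" [[topic|", tgt, "]]<ref>cite</ref>."), w)
          first <- sub(" .*$", "", w)
          w <- sub(first, paste0("'''", first, "'''"), w, fixed = TRUE)
        }
        sents[si] <- plain
        wiki[si] <- w
        terms[si] <- tm
        imported[si] <- stats::runif(1) < imported_block_rate
      }
      raw <- paste(wiki, collapse = " ")
      prov <- data.frame(sentence_index = seq_len(k) - 1L,
                         author = ifelse(imported, bot_author,
                                         sprintf("editor_%d", gi)),
                         imported_flag = imported,
                         stringsAsFactors = FALSE)
      doc <- gene_document(genes[gi], raw, provenance = prov)
      if (nrow(doc$blocks) != k) {
        stop("internal fixture error: sentence count mismatch for ",
             genes[gi])
      }
      docs[[gi]] <- doc
      raws[[gi]] <- raw
      if (k > 0L) {
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = genes[gi], term_id = terms,
          sentence_index = seq_len(k) - 1L, imported = imported,
          plain_sentence = sents, stringsAsFactors = FALSE)
      }
    }
  })
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
           else data.frame(gene_id = character(), term_id = character(),
                           sentence_index = integer(), imported = logical(),
                           plain_sentence = character(),
                           stringsAsFactors = FALSE)
  structure(list(docs = stats::setNames(docs, genes),
                 raw = stats::setNames(raws, genes),
                 truth = truth, genes = genes),
            class = "toy_corpus")
}

#' Expected candidate truth of a corpus
#'
#' Unique (gene, term) pairs planted in a corpus, optionally ignoring
#' mentions that sit in imported blocks.
#'
#' @param corpus a [make_corpus()] result.
#' @param drop_imported drop pairs supported only by imported blocks.
#' @return data.frame `gene_id`, `term_id`.
#' @export
corpus_truth_pairs <- function(corpus, drop_imported = TRUE) {
  tr <- corpus$truth
  if (drop_imported) tr <- tr[!tr$imported, , drop = FALSE]
  out <- unique(tr[, c("gene_id", "term_id")])
  out <- out[order(out$gene_id, out$term_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive a noisy reference set from planted truth
#'
#' Models the structure of a candidate-vs-reference comparison: each
#' planted (gene, term) annotation is dropped with probability
#' `drop_rate` (the candidate then has no match, NONE) or, surviving,
#' generalized with probability `generalize_rate` by replacing the term
#' with a uniformly chosen proper ancestor (the candidate then matches
#' a narrower... i.e. is narrower than the reference: MORE_SPECIFIC);
#' otherwise it is kept verbatim (EXACT). Generalization applies only
#' to terms with at least one ancestor under `policy`.
#'
#' @param truth_pairs data.frame `gene_id`, `term_id` (planted truth).
#' @param graph the `ontology_graph`.
#' @param drop_rate d in [0, 1].
#' @param generalize_rate g in [0, 1].
#' @param policy relation policy for ancestor sampling.
#' @param seed integer seed.
#' @return A list of class `noisy_reference`: `refs` (a
#'   [reference_set()]), and `expected` (data.frame of expected
#'   classification proportions with 3-sigma binomial bands, computed
#'   from the rates and the fraction of generalizable annotations).
#' @export
make_reference <- function(truth_pairs, graph, drop_rate = 0.2,
                           generalize_rate = 0.3,
                           policy = NULL, seed = 1L) {
  stopifnot(nrow(truth_pairs) > 0L)
  if (is.null(policy)) {
    policy <- relation_policy(
      if (length(graph$relation_types)) graph$relation_types else "is_a")
  }
  n <- nrow(truth_pairs)
  anc_cache <- new.env(parent = emptyenv())
  get_anc <- function(tm) {
    a <- anc_cache[[tm]]
    if (is.null(a)) {
      a <- term_ancestors(graph, tm, policy)
      anc_cache[[tm]] <- a
    }
    a
  }
  rows <- vector("list", n)
  withr::with_seed(seed, {
    u_drop <- stats::runif(n)
    u_gen <- stats::runif(n)
    for (i in seq_len(n)) {
      if (u_drop[i] < drop_rate) next
      tm <- truth_pairs$term_id[i]
      anc <- get_anc(tm)
      if (length(anc) > 0L && u_gen[i] < generalize_rate) {
        tm <- if (length(anc) == 1L) anc else sample(anc, 1)
      }
      rows[[i]] <- data.frame(gene_id = truth_pairs$gene_id[i],
                              term_id = tm, evidence = "EXP",
                              stringsAsFactors = FALSE)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  kept <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
          else NULL
  if (is.null(kept)) {
    kept <- data.frame(gene_id = character(), term_id = character(),
                       evidence = character(), stringsAsFactors = FALSE)
  }
  frac_eligible <- mean(vapply(truth_pairs$term_id,
                               function(tm) length(get_anc(tm)) > 0L,
                               logical(1)))
  d <- drop_rate
  g <- generalize_rate * frac_eligible
  probs <- c(EXACT = (1 - d) * (1 - g), MORE_SPECIFIC = (1 - d) * g,
             NONE = d)
  sigma <- sqrt(probs * (1 - probs) / n)
  expected <- data.frame(classification = names(probs),
                         prob = unname(probs),
                         band_lo = pmax(0, unname(probs - 3 * sigma)),
                         band_hi = pmin(1, unname(probs + 3 * sigma)),
                         stringsAsFactors = FALSE)
  structure(list(refs = reference_set(kept), expected = expected,
                 drop_rate = drop_rate, generalize_rate = generalize_rate),
            class = "noisy_reference")
}

#' Generate a planted enrichment scenario
#'
#' Emulates a controlled augmentation experiment: curated truth sets
#' over `n_terms` toy terms and `n_genes` genes; a baseline corpus in
#' which every (gene, term) pairing occurs independently at a small
#' background rate, plus the planted term's label in a fraction
#' `signal_base` of its truth genes' documents; and an augmentation
#' corpus that raises that fraction to `signal_aug` (other pairings
#' again independent background noise).
#'
#' @param n_genes gene universe size.
#' @param n_terms toy ontology size.
#' @param planted_term_size truth-set size of the planted term.
#' @param signal_base,signal_aug fraction of the planted term's truth
#'   genes whose baseline / augmentation document mentions its label.
#' @param noise_rate per-(gene, term) background mention probability.
#' @param truth_set_range truth-set sizes for non-planted terms.
#' @param seed integer seed.
#' @return A list of class `enrichment_scenario`: `toy`, `graph`,
#'   `truth` (a [reference_set()], evidence "EXP"), `baseline_docs`,
#'   `augmentation_docs` (named lists of [gene_document()]),
#'   `planted_term`, `background` (all gene ids).
#' @export
make_enrichment_scenario <- function(n_genes = 500L, n_terms = 30L,
                                     planted_term_size = 20L,
                                     signal_base = 0, signal_aug = 1,
                                     noise_rate = 0.002,
                                     truth_set_range = c(5L, 15L),
                                     seed = 1L) {
  stopifnot(planted_term_size <= n_genes, n_terms >= 2L)
  toy <- make_toy_ontology(n_terms, max_children = 4L,
                           words_per_label = 1L, seed = seed)
  graph <- toy_graph(toy)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  lab_of <- stats::setNames(toy$labels, toy$ids)
  sentence_for <- function(tm) {
    w <- c(sample(.distractor_words, 3), lab_of[[tm]],
           sample(.distractor_words, 2))
    s <- paste0(paste(w, collapse = " "), ".")
    substr(s, 1, 1) <- toupper(substr(s, 1, 1))
    s
  }
  make_docs <- function(mention_pairs) {
    by_gene <- split(mention_pairs$term_id, mention_pairs$gene_id)
    docs <- lapply(genes, function(g) {
      tms <- by_gene[[g]]
      txt <- if (is.null(tms) || length(tms) == 0L) {
        s <- paste0(paste(sample(.distractor_words, 5), collapse = " "), ".")
        substr(s, 1, 1) <- toupper(substr(s, 1, 1))
        s
      } else {
        paste(vapply(tms, sentence_for, character(1)), collapse = " ")
      }
      gene_document(g, txt)
    })
    stats::setNames(docs, genes)
  }
  withr::with_seed(seed, {
    # curated truth sets
    planted_term <- toy$ids[[2L]]  # non-root term
    truth_rows <- list()
    planted_genes <- sample(genes, planted_term_size)
    truth_rows[[1L]] <- data.frame(gene_id = planted_genes,
                                   term_id = planted_term,
                                   evidence = "EXP",
                                   stringsAsFactors = FALSE)
    for (tm in setdiff(toy$ids, planted_term)) {
      sz <- sample(seq(truth_set_range[1], truth_set_range[2]), 1)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(gene_id = sample(genes, sz), term_id = tm,
                   evidence = "EXP", stringsAsFactors = FALSE)
    }
    truth <- reference_set(do.call(rbind, truth_rows))
    noise_pairs <- function() {
      hits <- which(stats::runif(n_genes * n_terms) < noise_rate)
      data.frame(gene_id = genes[((hits - 1L) %% n_genes) + 1L],
                 term_id = toy$ids[((hits - 1L) %/% n_genes) + 1L],
                 stringsAsFactors = FALSE)
    }
    signal_pairs <- function(frac) {
      if (frac <= 0) {
        return(data.frame(gene_id = character(), term_id = character(),
                          stringsAsFactors = FALSE))
      }
      k <- round(frac * length(planted_genes))
      if (k == 0L) {
        return(data.frame(gene_id = character(), term_id = character(),
                          stringsAsFactors = FALSE))
      }
      data.frame(gene_id = sample(planted_genes, k),
                 term_id = planted_term, stringsAsFactors = FALSE)
    }
    base_pairs <- rbind(noise_pairs(), signal_pairs(signal_base))
    aug_pairs <- rbind(noise_pairs(), signal_pairs(signal_aug))
    baseline_docs <- make_docs(base_pairs)
    augmentation_docs <- make_docs(aug_pairs)
  })
  structure(list(toy = toy, graph = graph, truth = truth,
                 baseline_docs = baseline_docs,
                 augmentation_docs = augmentation_docs,
                 planted_term = planted_term,
                 planted_genes = sort_c(planted_genes),
                 background = genes),
            class = "enrichment_scenario")
}

#' Write a fixture preset to disk
#'
#' Presets bundle the generators into ready-to-run input directories:
#' \describe{
#'   \item{tiny}{a 12-term ontology and a 6-gene corpus with markup and
#'     imported blocks, plus a gene2go-style reference table.}
#'   \item{comparison}{a 60-term ontology, a 40-gene corpus, and a
#'     noisy reference set derived from the planted truth.}
#'   \item{enrichment}{a planted augmentation scenario (200 genes,
#'     15 terms) with baseline and augmentation corpora.}
#' }
#' Files written: `ontology.obo`, `manifest.tsv`, one
#' `<gene>.wiki.txt` + `<gene>.authors.tsv` per gene, `reference.tsv`
#' (gene2go columns), `background.txt`, and for the enrichment preset a
#' second corpus under `augmentation/`.
#'
#' @param preset one of "tiny", "comparison", "enrichment".
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of the written paths.
#' @export
write_fixture_preset <- function(preset = c("tiny", "comparison",
                                            "enrichment"),
                                 seed = 1L, out_dir) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ref_tsv <- function(refs, path) {
    a <- refs$annotations
    a <- a[order(a$gene_id, a$term_id, method = "radix"), , drop = FALSE]
    df <- data.frame(tax_id = 9606L, GeneID = a$gene_id, GO_ID = a$term_id,
                     Evidence = ifelse(is.na(a$evidence), "EXP", a$evidence),
                     stringsAsFactors = FALSE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("#tax_id\tGeneID\tGO_ID\tEvidence",
                 do.call(paste, c(df, sep = "\t"))), con, useBytes = TRUE)
  }
  write_corpus_files <- function(corpus, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    man <- data.frame(gene_id = corpus$genes,
                      file = paste0(corpus$genes, ".wiki.txt"),
                      sidecar = paste0(corpus$genes, ".authors.tsv"),
                      stringsAsFactors = FALSE)
    for (g in corpus$genes) {
      con <- file(file.path(dir, paste0(g, ".wiki.txt")), open = "wb")
      writeLines(corpus$raw[[g]], con, useBytes = TRUE)
      close(con)
      b <- corpus$docs[[g]]$blocks
      write_tsv(b[, c("sentence_index", "author", "imported_flag")],
                file.path(dir, paste0(g, ".authors.tsv")))
    }
    write_tsv(man, file.path(dir, "manifest.tsv"))
    file.path(dir, "manifest.tsv")
  }
  paths <- list(dir = out_dir)
  if (preset == "tiny") {
    toy <- make_toy_ontology(12L, relation_mix = c(is_a = 0.8, part_of = 0.2),
                             seed = seed)
    graph <- toy_graph(toy)
    corpus <- make_corpus(toy, n_genes = 6L, mentions_per_gene = 4,
                          markup_rate = 0.3, imported_block_rate = 0.2,
                          seed = seed + 1L)
    noisy <- make_reference(corpus_truth_pairs(corpus), graph,
                            drop_rate = 0.25, generalize_rate = 0.25,
                            seed = seed + 2L)
    paths$obo <- file.path(out_dir, "ontology.obo")
    write_obo(toy, paths$obo)
    paths$manifest <- write_corpus_files(corpus, out_dir)
    paths$reference <- file.path(out_dir, "reference.tsv")
    write_ref_tsv(noisy$refs, paths$reference)
    con <- file(file.path(out_dir, "background.txt"), open = "wb")
    writeLines(corpus$genes, con, useBytes = TRUE)
    close(con)
    paths$background <- file.path(out_dir, "background.txt")
  } else if (preset == "comparison") {
    toy <- make_toy_ontology(60L, relation_mix = c(is_a = 0.7, part_of = 0.2,
                                                   regulates = 0.1),
                             seed = seed)
    graph <- toy_graph(toy)
    corpus <- make_corpus(toy, n_genes = 40L, mentions_per_gene = 5,
                          markup_rate = 0.2, imported_block_rate = 0.1,
                          plantable_terms = toy$ids[-1L],
                          seed = seed + 1L)
    noisy <- make_reference(corpus_truth_pairs(corpus), graph,
                            drop_rate = 0.2, generalize_rate = 0.3,
                            seed = seed + 2L)
    paths$obo <- file.path(out_dir, "ontology.obo")
    write_obo(toy, paths$obo)
    paths$manifest <- write_corpus_files(corpus, out_dir)
    paths$reference <- file.path(out_dir, "reference.tsv")
    write_ref_tsv(noisy$refs, paths$reference)
  } else {
    sc <- make_enrichment_scenario(n_genes = 200L, n_terms = 15L,
                                   planted_term_size = 20L,
                                   signal_base = 0, signal_aug = 1,
                                   seed = seed)
    paths$obo <- file.path(out_dir, "ontology.obo")
    write_obo(sc$toy, paths$obo)
    base_corpus <- scenario_corpus(sc, "baseline")
    aug_corpus <- scenario_corpus(sc, "augmentation")
    paths$manifest <- write_corpus_files(base_corpus, out_dir)
    paths$augmentation_manifest <-
      write_corpus_files(aug_corpus, file.path(out_dir, "augmentation"))
    paths$reference <- file.path(out_dir, "reference.tsv")
    write_ref_tsv(sc$truth, paths$reference)
    con <- file(file.path(out_dir, "background.txt"), open = "wb")
    writeLines(sc$background, con, useBytes = TRUE)
    close(con)
    paths$background <- file.path(out_dir, "background.txt")
  }
  invisible(paths)
}

# view an enrichment scenario's docs as a minimal corpus object so the
# same writers apply
scenario_corpus <- function(sc, which = c("baseline", "augmentation")) {
  which <- match.arg(which)
  docs <- if (which == "baseline") sc$baseline_docs else sc$augmentation_docs
  structure(list(docs = docs,
                 raw = lapply(docs, `[[`, "raw_text"),
                 truth = NULL, genes = names(docs)),
            class = "toy_corpus")
}
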