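# Document -> candidate-annotation mining with post-recognition filters.

#' Default uninformative-term filter lists
#'
#' Labels too generic to carry annotation value, removed after
#' recognition: for GO-style ontologies "chromosome" and
#' "cellular component"; for disease-ontology-style ontologies
#' "disease", "disorder", "syndrome" and "recruitment". Matching is on
#' the normalized preferred label, not the accession.
#'
#' @return Named list of character vectors (`GO`, `DO`).
#' @export
default_term_filters <- function() {
  list(GO = c("chromosome", "cellular component"),
       DO = c("disease", "disorder", "syndrome", "recruitment"))
}

#' Mine candidate annotations from one gene document
#'
#' Runs the recognizer over every sentence of a cleaned document and
#' aggregates mentions into one candidate per distinct (gene, term)
#' pair; each article is assumed to be about exactly one gene, so every
#' concept occurrence proposes an annotation for that gene. Candidates
#' whose term label is in `excluded_labels` are removed. When
#' `drop_imported`, mentions in imported text blocks are discarded
#' before aggregation, so a candidate supported only by imported text
#' disappears.
#'
#' @param doc a [gene_document()].
#' @param dict a [build_dictionary()] result.
#' @param graph the `ontology_graph` behind `dict` (for labels and
#'   namespaces).
#' @param excluded_labels character vector of uninformative labels to
#'   drop (normalized-label matching); see [default_term_filters()].
#' @param drop_imported drop mentions from imported blocks (default
#'   TRUE).
#' @param ontology_name recorded in the output (default "ontology").
#' @return A list of class `candidate_set` with `candidates` (data.frame
#'   `gene_id`, `ontology`, `term_id`, `term_label`, `n_mentions`,
#'   `first_evidence_sentence`, `from_imported_text`) and `mentions`
#'   (per-mention evidence with sentence text).
#' @export
mine_document <- function(doc, dict, graph,
                          excluded_labels = character(),
                          drop_imported = TRUE,
                          ontology_name = "ontology") {
  stopifnot(inherits(doc, "gene_document"))
  blocks <- doc$blocks
  if (drop_imported) {
    doc2 <- filter_imported_blocks(doc)
    blocks <- doc2$blocks
  }
  ml <- lapply(seq_len(nrow(blocks)), function(i) {
    m <- recognize(blocks$text[i], dict,
                   sentence_index = blocks$sentence_index[i])
    if (nrow(m) > 0L) {
      m$sentence <- blocks$text[i]
      m$imported <- blocks$imported_flag[i]
    } else {
      m$sentence <- character()
      m$imported <- logical()
    }
    m
  })
  mentions <- do.call(rbind, c(ml, list(empty_mentions_ev())))
  mentions <- cbind(gene_id = rep(doc$gene_id, nrow(mentions)), mentions,
                    stringsAsFactors = FALSE)
  candidate_set_from_mentions(mentions, graph, excluded_labels, ontology_name)
}

empty_mentions_ev <- function() {
  cbind(empty_mentions(),
        data.frame(sentence = character(), imported = logical(),
                   stringsAsFactors = FALSE))
}

candidate_set_from_mentions <- function(mentions, graph, excluded_labels,
                                        ontology_name) {
  excl <- normalize_label(excluded_labels)
  if (nrow(mentions) > 0L) {
    labs <- vapply(mentions$term_id, function(id) term_label(graph, id),
                   character(1), USE.NAMES = FALSE)
    keep <- !(normalize_label(labs) %in% excl)
    mentions <- mentions[keep, , drop = FALSE]
    labs <- labs[keep]
  } else {
    labs <- character()
  }
  if (nrow(mentions) == 0L) {
    cand <- data.frame(gene_id = character(), ontology = character(),
                       term_id = character(), term_label = character(),
                       n_mentions = integer(),
                       first_evidence_sentence = character(),
                       from_imported_text = logical(),
                       stringsAsFactors = FALSE)
    return(structure(list(candidates = cand, mentions = mentions),
                     class = "candidate_set"))
  }
  mentions$term_label <- labs
  key <- paste(mentions$gene_id, mentions$term_id, sep = "\r")
  ord <- order(mentions$gene_id, mentions$term_id,
               mentions$sentence_index, mentions$char_start)
  mentions <- mentions[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  cand <- data.frame(
    gene_id = mentions$gene_id[first],
    ontology = ontology_name,
    term_id = mentions$term_id[first],
    term_label = mentions$term_label[first],
    n_mentions = as.integer(table(key)[key[first]]),
    first_evidence_sentence = mentions$sentence[first],
    from_imported_text = vapply(split(mentions$imported, key),
                                all, logical(1))[key[first]],
    stringsAsFactors = FALSE)
  rownames(cand) <- NULL
  rownames(mentions) <- NULL
  structure(list(candidates = cand, mentions = mentions),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidates (%d genes, %d mentions)\n",
              nrow(x$candidates), length(unique(x$candidates$gene_id)),
              nrow(x$mentions)))
  invisible(x)
}

#' Mine a whole corpus of gene documents
#'
#' Applies [mine_document()] to each document and concatenates the
#' results. Documents with zero sentences contribute nothing.
#'
#' @inheritParams mine_document
#' @param docs list of [gene_document()] objects.
#' @return A `candidate_set` over all genes.
#' @export
mine_corpus <- function(docs, dict, graph,
                        excluded_labels = character(),
                        drop_imported = TRUE,
                        ontology_name = "ontology") {
  sets <- lapply(docs, mine_document, dict = dict, graph = graph,
                 excluded_labels = excluded_labels,
                 drop_imported = drop_imported,
                 ontology_name = ontology_name)
  structure(list(
    candidates = do.call(rbind, c(lapply(sets, `[[`, "candidates"),
                                  make.row.names = FALSE)),
    mentions = do.call(rbind, c(lapply(sets, `[[`, "mentions"),
                                make.row.names = FALSE))),
    class = "candidate_set")
}

#' Partition candidates by ontology namespace
#'
#' Splits a candidate table by the namespace of each term (for GO:
#' biological_process / molecular_function / cellular_component). For a
#' single-namespace ontology this is a no-op partition. Sizes always
#' sum to the input size.
#'
#' @param candidates a `candidate_set` or its `candidates` data.frame.
#' @param graph the `ontology_graph` resolving the term ids.
#' @return Named list of data.frames, one per namespace present.
#' @export
partition_by_namespace <- function(candidates, graph) {
  cand <- as_candidate_df(candidates)
  if (nrow(cand) == 0L) return(list())
  ns <- vapply(cand$term_id, function(id) term_namespace(graph, id),
               character(1), USE.NAMES = FALSE)
  ns[is.na(ns)] <- "unspecified"
  split(cand, ns)
}

as_candidate_df <- function(x) {
  if (inherits(x, "candidate_set")) x$candidates
  else as.data.frame(x, stringsAsFactors = FALSE)
}

#' Write / read candidate tables as TSV
#'
#' Columns: gene_id, ontology, term_id, term_label, n_mentions,
#' first_evidence_sentence.
#'
#' @param candidates a `candidate_set` or candidates data.frame.
#' @param path output file path.
#' @export
write_candidates <- function(candidates, path) {
  cand <- as_candidate_df(candidates)
  cols <- c("gene_id", "ontology", "term_id", "term_label", "n_mentions",
            "first_evidence_sentence")
  cols <- intersect(cols, names(cand))
  write_tsv(cand[, cols, drop = FALSE], path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character") |>
    transform(n_mentions = as.integer(n_mentions))
}

# deterministic TSV writer (no quoting surprises, LF endings)
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(names(df), collapse = "\t")
  rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
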