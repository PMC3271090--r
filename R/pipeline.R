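# File-level pipeline runners behind the command-line interface.
# Each step reads plain-text inputs (OBO, manifest TSV, gene2go-style
# reference TSV) and writes deterministic TSV output.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA",
                ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                       sprintf("%.6g", x)))
  out
}

#' Mine candidate annotations from a corpus on disk
#'
#' Loads the ontology, builds the matching dictionary, reads the
#' per-gene corpus from its manifest, mines every document and writes
#' the candidate table as TSV. A parameter echo is logged to the
#' console along with input checksums.
#'
#' @param ontology_path OBO file.
#' @param manifest_path corpus manifest TSV (see [read_corpus()]).
#' @param out_path output candidates TSV.
#' @param keep_imported keep text blocks flagged as imported.
#' @param params a [match_params()].
#' @param excluded_labels uninformative labels to filter; default is
#'   the union of [default_term_filters()].
#' @param ontology_name name recorded in the output.
#' @return The `candidate_set`, invisibly.
#' @export
run_mine <- function(ontology_path, manifest_path, out_path,
                     keep_imported = FALSE, params = match_params(),
                     excluded_labels = unlist(default_term_filters(),
                                              use.names = FALSE),
                     ontology_name = "ontology") {
  message(sprintf("mine: ontology=%s (md5 %s) corpus=%s (md5 %s)",
                  ontology_path, tools::md5sum(ontology_path),
                  manifest_path, tools::md5sum(manifest_path)))
  message(sprintf(
    "mine: min_term_size=%d whole_word_only=%s longest_only=%s filter_number=%s keep_imported=%s",
    params$min_term_size, params$whole_word_only, params$longest_only,
    params$filter_number, keep_imported))
  graph <- read_obo(ontology_path)
  dict <- build_dictionary(graph, params)
  docs <- read_corpus(manifest_path)
  cs <- mine_corpus(docs, dict, graph, excluded_labels = excluded_labels,
                    drop_imported = !keep_imported,
                    ontology_name = ontology_name)
  ord <- order(cs$candidates$gene_id, cs$candidates$term_id,
               method = "radix")
  cs$candidates <- cs$candidates[ord, , drop = FALSE]
  rownames(cs$candidates) <- NULL
  write_candidates(cs, out_path)
  message(sprintf("mine: %d candidates -> %s", nrow(cs$candidates), out_path))
  invisible(cs)
}

#' Compare mined candidates with a reference set on disk
#'
#' Classifies every candidate in the TSV against the reference
#' annotations and writes the per-candidate classification table; the
#' category breakdown is printed as a report.
#'
#' @param ontology_path OBO file.
#' @param candidates_path candidates TSV from [run_mine()].
#' @param reference_path gene2go-style TSV ([read_gene2go()]) or GAF
#'   (detected by a leading `!`).
#' @param out_path output classification TSV.
#' @param relations relation labels treated as subsumption; default:
#'   every relation present in the ontology.
#' @return The `comparison`, invisibly.
#' @export
run_compare <- function(ontology_path, candidates_path, reference_path,
                        out_path, relations = NULL) {
  graph <- read_obo(ontology_path)
  if (is.null(relations)) {
    relations <- if (length(graph$relation_types)) graph$relation_types
                 else "is_a"
  }
  policy <- relation_policy(relations)
  cand <- read_candidates(candidates_path)
  first <- readLines(reference_path, n = 1L)
  refs <- if (startsWith(first, "!")) read_gaf(reference_path)
          else read_gene2go(reference_path)
  cmp <- compare_annotations(cand, refs, graph, policy)
  tab <- cmp$table
  tab$matched_reference_term[is.na(tab$matched_reference_term)] <- "NA"
  write_tsv(tab, out_path)
  print(cmp$summary)
  message(sprintf("compare: %d rows -> %s", nrow(tab), out_path))
  invisible(cmp)
}

#' Run the enrichment comparison on disk
#'
#' Builds term -> gene sets from the mined candidates (and the optional
#' augmentation candidates, whose annotations are added to the
#' baseline), tests every truth term with the one-tailed Fisher test
#' and writes the per-term table. Truth annotations with evidence code
#' IEA are excluded.
#'
#' @param reference_path gene2go-style truth TSV.
#' @param mined_path baseline candidates TSV.
#' @param background_path text file of background gene ids (one per
#'   line); defaults to the genes with any truth annotation.
#' @param out_path output TSV.
#' @param augment_path optional TSV of additional mined candidates.
#' @param alpha significance level.
#' @return The `augmentation_comparison`, invisibly.
#' @export
run_enrich <- function(reference_path, mined_path, out_path,
                       background_path = NULL, augment_path = NULL,
                       alpha = 0.01) {
  truth <- filter_evidence(read_gene2go(reference_path), exclude = "IEA")
  base <- read_candidates(mined_path)
  aug <- if (!is.null(augment_path)) {
    rbind(base[, c("gene_id", "term_id")],
          read_candidates(augment_path)[, c("gene_id", "term_id")])
  } else {
    base
  }
  background <- if (!is.null(background_path)) {
    readLines(background_path, warn = FALSE)
  } else {
    unique(truth$annotations$gene_id)
  }
  res <- run_enrichment_experiment(truth, base, aug, background, alpha)
  df <- res$results
  df <- df[order(df$term_id, method = "radix"), , drop = FALSE]
  out <- data.frame(
    term_id = df$term_id,
    a_base = df$a_base, b_base = df$b_base, c_base = df$c_base,
    d_base = df$d_base, a_aug = df$a_aug, b_aug = df$b_aug,
    c_aug = df$c_aug, d_aug = df$d_aug,
    p_base = fmt_num(df$p_base), p_aug = fmt_num(df$p_aug),
    odds_ratio_base = fmt_num(df$odds_ratio_base),
    odds_ratio_aug = fmt_num(df$odds_ratio_aug),
    significant_base = df$significant_base,
    significant_aug = df$significant_aug,
    stringsAsFactors = FALSE)
  write_tsv(out, out_path)
  print(res)
  invisible(res)
}
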