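# Candidate-vs-reference classification via ontology lineage, and
# precision-bound estimation from manual-evaluation tallies.

#' Build a reference annotation set
#'
#' @param annotations data.frame with columns `gene_id`, `term_id` and
#'   optionally `evidence` (evidence code, e.g. "IEA", "EXP").
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(annotations) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!"evidence" %in% names(ann)) {
    ann$evidence <- rep(NA_character_, nrow(ann))
  }
  ann <- unique(ann[, c("gene_id", "term_id", "evidence")])
  rownames(ann) <- NULL
  structure(list(annotations = ann), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d annotations, %d genes\n",
              nrow(x$annotations), length(unique(x$annotations$gene_id))))
  invisible(x)
}

#' Genes and terms of a reference set
#' @param refs a [reference_set()].
#' @param gene_id a gene identifier.
#' @return `ref_terms` returns the term ids annotated to `gene_id`.
#' @export
ref_terms <- function(refs, gene_id) {
  a <- refs$annotations
  unique(a$term_id[a$gene_id == gene_id])
}

#' Filter a reference set by evidence code
#'
#' Electronically inferred annotations (evidence code "IEA") are kept
#' for candidate comparison but excluded from enrichment truth sets.
#'
#' @param refs a [reference_set()].
#' @param exclude evidence codes to remove (default "IEA").
#' @return A filtered [reference_set()].
#' @export
filter_evidence <- function(refs, exclude = "IEA") {
  a <- refs$annotations
  keep <- is.na(a$evidence) | !(a$evidence %in% exclude)
  reference_set(a[keep, , drop = FALSE])
}

#' Read gene2go-style reference annotations
#'
#' Expects a TSV with (at least) columns `GeneID`, `GO_ID` and
#' `Evidence` (header names as in NCBI's gene2go); leading `#` on the
#' header is tolerated. Rows for other columns are ignored.
#'
#' @param path TSV path.
#' @return A [reference_set()].
#' @export
read_gene2go <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- strsplit(sub("^#", "", first), "\t")[[1]]
  df <- utils::read.delim(path, skip = 1L, header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = make.names(hdr))
  need <- c("GeneID", "GO_ID", "Evidence")
  if (!all(need %in% names(df))) {
    stop("gene2go file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  reference_set(data.frame(gene_id = as.character(df$GeneID),
                           term_id = df$GO_ID, evidence = df$Evidence,
                           stringsAsFactors = FALSE))
}

#' Read GAF 2.x reference annotations
#'
#' Reads a Gene Association File: `!`-prefixed comment lines skipped;
#' column 2 = object id, column 5 = term id, column 7 = evidence code.
#'
#' @param path GAF path.
#' @return A [reference_set()].
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) stop("no annotation rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 7L)
  if (length(bad) > 0L) stop("malformed GAF row(s): ", bad[1])
  reference_set(data.frame(
    gene_id = vapply(parts, `[[`, character(1), 2L),
    term_id = vapply(parts, `[[`, character(1), 5L),
    evidence = vapply(parts, `[[`, character(1), 7L),
    stringsAsFactors = FALSE))
}

#' Classify a candidate term against a gene's reference terms
#'
#' EXACT if the candidate is itself a reference term; otherwise
#' MORE_GENERAL if it is an ancestor (broader term) of some reference
#' term, MORE_SPECIFIC if it is a descendant (narrower term) of some
#' reference term, else NONE. When a candidate is simultaneously
#' broader than one reference term and narrower than another, the
#' default precedence reports MORE_SPECIFIC (the narrower hit is the
#' more informative relationship); set
#' `precedence = "general_first"` for the other convention.
#'
#' @param candidate_term term id of the candidate annotation.
#' @param gene_refs character vector of reference term ids for the gene.
#' @param graph an `ontology_graph`.
#' @param policy a [relation_policy()] used for lineage expansion.
#' @param precedence `"specific_first"` (default) or `"general_first"`.
#' @return One of "EXACT", "MORE_SPECIFIC", "MORE_GENERAL", "NONE".
#' @export
classify_candidate <- function(candidate_term, gene_refs, graph,
                               policy = do_policy(),
                               precedence = c("specific_first",
                                              "general_first")) {
  precedence <- match.arg(precedence)
  candidate_term <- resolve_term(graph, candidate_term)
  gene_refs <- unique(vapply(gene_refs, function(r) resolve_term(graph, r),
                             character(1), USE.NAMES = FALSE))
  if (candidate_term %in% gene_refs) return("EXACT")
  anc <- term_ancestors(graph, candidate_term, policy)
  des <- term_descendants(graph, candidate_term, policy)
  is_specific <- any(gene_refs %in% anc)  # some ref is broader => candidate narrower
  is_general <- any(gene_refs %in% des)   # some ref is narrower => candidate broader
  if (precedence == "specific_first") {
    if (is_specific) return("MORE_SPECIFIC")
    if (is_general) return("MORE_GENERAL")
  } else {
    if (is_general) return("MORE_GENERAL")
    if (is_specific) return("MORE_SPECIFIC")
  }
  "NONE"
}

#' Compare a candidate set with a reference annotation set
#'
#' Classifies every candidate and tallies the four match categories.
#' Genes absent from the reference set contribute NONE for all their
#' candidates. The per-candidate table records, for each candidate,
#' every applicable relation so that either precedence convention can
#' be recomputed.
#'
#' @param candidates a `candidate_set` or candidates data.frame (needs
#'   `gene_id`, `term_id`).
#' @param refs a [reference_set()].
#' @param graph an `ontology_graph`.
#' @param policy a [relation_policy()].
#' @param precedence see [classify_candidate()].
#' @return A list of class `comparison` with `summary` (class
#'   `comparison_summary`: counts `exact`, `more_general`, `child`
#'   (= more-specific matches), `none`, `all`) and `table`
#'   (per-candidate: `gene_id`, `term_id`, `classification`,
#'   `matched_reference_term`, `is_broader_than_ref`,
#'   `is_narrower_than_ref`).
#' @export
compare_annotations <- function(candidates, refs, graph,
                                policy = do_policy(),
                                precedence = "specific_first") {
  cand <- as_candidate_df(candidates)
  ann <- refs$annotations
  refs_by_gene <- split(ann$term_id, ann$gene_id)
  n <- nrow(cand)
  cls <- character(n)
  matched <- character(n)
  broader <- logical(n)
  narrower <- logical(n)
  for (i in seq_len(n)) {
    gr <- unique(refs_by_gene[[cand$gene_id[i]]])
    if (is.null(gr) || length(gr) == 0L) {
      cls[i] <- "NONE"; matched[i] <- NA_character_
      next
    }
    term <- resolve_term(graph, cand$term_id[i])
    gr <- vapply(gr, function(r) resolve_term(graph, r), character(1),
                 USE.NAMES = FALSE)
    anc <- term_ancestors(graph, term, policy)
    des <- term_descendants(graph, term, policy)
    broader[i] <- any(gr %in% des)
    narrower[i] <- any(gr %in% anc)
    if (term %in% gr) {
      cls[i] <- "EXACT"; matched[i] <- term
    } else if (precedence == "specific_first" && narrower[i]) {
      cls[i] <- "MORE_SPECIFIC"; matched[i] <- gr[gr %in% anc][1]
    } else if (broader[i]) {
      cls[i] <- "MORE_GENERAL"; matched[i] <- gr[gr %in% des][1]
    } else if (narrower[i]) {
      cls[i] <- "MORE_SPECIFIC"; matched[i] <- gr[gr %in% anc][1]
    } else {
      cls[i] <- "NONE"; matched[i] <- NA_character_
    }
  }
  tab <- data.frame(gene_id = cand$gene_id, term_id = cand$term_id,
                    classification = cls, matched_reference_term = matched,
                    is_broader_than_ref = broader,
                    is_narrower_than_ref = narrower,
                    stringsAsFactors = FALSE)
  summ <- comparison_summary(exact = sum(cls == "EXACT"),
                             more_general = sum(cls == "MORE_GENERAL"),
                             child = sum(cls == "MORE_SPECIFIC"),
                             none = sum(cls == "NONE"))
  structure(list(summary = summ, table = tab), class = "comparison")
}

#' Match-category counts
#'
#' `child` counts matches to a more specific (narrower) term; `none`
#' counts candidates with no lineage match — together they form the
#' "novel candidate" pool from which manual-evaluation samples are
#' drawn.
#'
#' @param exact,more_general,child,none non-negative counts.
#' @return A list of class `comparison_summary` with an `all` total.
#' @export
comparison_summary <- function(exact, more_general, child, none) {
  counts <- c(exact = exact, more_general = more_general,
              child = child, none = none)
  if (any(counts < 0)) stop("category counts must be non-negative")
  structure(as.list(c(counts, all = sum(counts))),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  pct <- function(k) if (x$all > 0) sprintf(" (%.0f%%)", 100 * k / x$all) else ""
  cat(sprintf(paste0(
    "comparison of %d candidate annotations:\n",
    "  exact match:        %d%s\n",
    "  more general match: %d%s\n",
    "  more specific:      %d%s\n",
    "  no match:           %d%s\n"),
    x$all, x$exact, pct(x$exact), x$more_general, pct(x$more_general),
    x$child, pct(x$child), x$none, pct(x$none)))
  invisible(x)
}

#' @export
print.comparison <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Manual-evaluation category tally
#'
#' Verdict counts over a manually evaluated sample of novel candidates:
#' 1A perfect match; 1B correct but more general; 1C correct but too
#' specific; 2A plausible but no evidence found; 2B literature
#' disagrees; 3A wrong concept (polysemy); 3B wrong sentence context;
#' 3C factually false sentence. `e_all` defaults to the category sum.
#'
#' @param e1a,e1b,e1c,e2a,e2b,e3a,e3b,e3c non-negative counts.
#' @param e_all evaluated sample size.
#' @return A list of class `evaluation_tally`.
#' @export
evaluation_tally <- function(e1a = 0, e1b = 0, e1c = 0, e2a = 0, e2b = 0,
                             e3a = 0, e3b = 0, e3c = 0, e_all = NULL) {
  counts <- c(e1a = e1a, e1b = e1b, e1c = e1c, e2a = e2a, e2b = e2b,
              e3a = e3a, e3b = e3b, e3c = e3c)
  if (any(counts < 0)) stop("evaluation counts must be non-negative")
  if (is.null(e_all)) e_all <- sum(counts)
  if (sum(counts) != e_all) {
    stop("category counts must sum to the evaluated sample size")
  }
  structure(as.list(c(counts, e_all = e_all)), class = "evaluation_tally")
}

#' Precision bounds from comparison counts and an evaluation tally
#'
#' Extrapolates the manually observed rate of valid annotations to the
#' whole novel pool (`none + child`). With N = none + child:
#'
#' lower = (exact + more_general + (e1a+e1b+e1c)/e_all * N) / all
#' upper = lower + e2a/e_all * N / all
#'
#' i.e. category-1 verdicts count as true in both bounds, and the
#' undecidable 2A ("plausible, no evidence found") verdicts count as
#' true only in the upper bound. With `include_1c = FALSE`, 1C ("too
#' specific") verdicts are treated as not valid and omitted from both
#' bounds.
#'
#' @param summary a [comparison_summary()].
#' @param tally an [evaluation_tally()] over a sample of the novel pool.
#' @param include_1c count category 1C as valid (default TRUE).
#' @return A list of class `precision_bounds` with `lower` and `upper`
#'   in `[0, 1]`.
#' @export
precision_bounds <- function(summary, tally, include_1c = TRUE) {
  if (tally$e_all <= 0) stop("evaluated sample size must be positive")
  if (summary$all <= 0) stop("comparison summary must be non-empty")
  novel <- summary$none + summary$child
  cat1 <- tally$e1a + tally$e1b + if (include_1c) tally$e1c else 0
  lower <- (summary$exact + summary$more_general +
              cat1 / tally$e_all * novel) / summary$all
  upper <- lower + tally$e2a / tally$e_all * novel / summary$all
  structure(list(lower = lower, upper = upper), class = "precision_bounds")
}

#' @export
print.precision_bounds <- function(x, ...) {
  cat(sprintf("estimated precision: %.1f%% - %.1f%%\n",
              100 * x$lower, 100 * x$upper))
  invisible(x)
}

#' Sample novel candidates for manual evaluation
#'
#' Draws a seeded uniform sample (without replacement) from the
#' candidates classified NONE or MORE_SPECIFIC — the pool with no exact
#' or broader reference match.
#'
#' @param comparison a [compare_annotations()] result.
#' @param n sample size (capped at the pool size).
#' @param seed integer seed.
#' @return The sampled rows of the per-candidate table.
#' @export
sample_novel_candidates <- function(comparison, n, seed = 1L) {
  pool <- comparison$table[
    comparison$table$classification %in% c("NONE", "MORE_SPECIFIC"), ,
    drop = FALSE]
  n <- min(n, nrow(pool))
  idx <- withr::with_seed(seed, sample.int(nrow(pool), n))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
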