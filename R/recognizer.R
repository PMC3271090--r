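# Dictionary-based concept recognition: longest whole-word matching of
# preferred term labels inside sentences.

# Bundled default stopword list (function words). The dictionary never
# contains these labels; kept fixed so matching output is reproducible.
.default_stopwords <- c(
  "a", "about", "above", "after", "again", "against", "all", "also", "am",
  "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot", "could",
  "did", "do", "does", "doing", "down", "during", "each", "few", "for",
  "from", "further", "had", "has", "have", "having", "he", "her", "here",
  "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "just", "may", "me", "might", "more", "most", "must", "my", "no",
  "nor", "not", "now", "of", "off", "on", "once", "only", "or", "other",
  "our", "ours", "out", "over", "own", "same", "she", "should", "so", "some",
  "such", "than", "that", "the", "their", "theirs", "them", "then", "there",
  "these", "they", "this", "those", "through", "to", "too", "under", "until",
  "up", "very", "was", "we", "were", "what", "when", "where", "which",
  "while", "who", "whom", "why", "will", "with", "would", "you", "your",
  "yours"
)

#' Matching parameters for dictionary recognition
#'
#' Mirrors the parameter surface of a precision-oriented annotator run:
#' only the longest whole-word match for a text fragment is returned,
#' labels shorter than `min_term_size` characters are never matched,
#' purely numeric matches are dropped, and a stopword list removes
#' uninformative labels (defaults add "protein" and "gene" to the
#' bundled function-word list). Synonym matching is off by default;
#' when enabled, exact synonyms would be added to the dictionary
#' alongside preferred labels.
#'
#' @param min_term_size minimum label length in characters (default 3).
#' @param whole_word_only require matches bounded by non-alphanumeric
#'   characters or string edges (default TRUE).
#' @param longest_only suppress matches strictly contained in a longer
#'   match (default TRUE).
#' @param filter_number drop matches whose text contains no letters
#'   (default TRUE).
#' @param stopwords labels excluded from the dictionary.
#' @param case_sensitive match labels case-sensitively (default FALSE).
#' @param with_synonyms include exact synonyms in the dictionary
#'   (default FALSE; preferred labels only).
#' @return A list of class `match_params`.
#' @export
match_params <- function(min_term_size = 3L,
                         whole_word_only = TRUE,
                         longest_only = TRUE,
                         filter_number = TRUE,
                         stopwords = c("protein", "gene", .default_stopwords),
                         case_sensitive = FALSE,
                         with_synonyms = FALSE) {
  stopifnot(min_term_size >= 1L)
  structure(list(min_term_size = as.integer(min_term_size),
                 whole_word_only = isTRUE(whole_word_only),
                 longest_only = isTRUE(longest_only),
                 filter_number = isTRUE(filter_number),
                 stopwords = as.character(stopwords),
                 case_sensitive = isTRUE(case_sensitive),
                 with_synonyms = isTRUE(with_synonyms)),
            class = "match_params")
}

normalize_label <- function(x, case_sensitive = FALSE) {
  x <- gsub("\\s+", " ", trimws(x))
  if (!case_sensitive) x <- tolower(x)
  x
}

#' Build a matching dictionary from an ontology
#'
#' One entry per eligible non-obsolete term, keyed by the normalized
#' preferred label (case-folded unless `case_sensitive`, internal
#' whitespace collapsed). Labels shorter than `min_term_size` and
#' stopword labels are excluded. Two terms sharing a normalized label
#' are both retained; matches report all tied term ids.
#'
#' @param graph an `ontology_graph`.
#' @param params a [match_params()] object.
#' @return A list of class `match_dictionary` with elements `entries`
#'   (environment: normalized label -> character vector of term ids),
#'   `labels`, `max_words` and `params`.
#' @export
build_dictionary <- function(graph, params = match_params()) {
  stopifnot(inherits(graph, "ontology_graph"))
  keep <- !graph$obsolete & !is.na(graph$label)
  lab <- normalize_label(graph$label[keep], params$case_sensitive)
  ids <- graph$id[keep]
  stop_norm <- normalize_label(params$stopwords, params$case_sensitive)
  ok <- nchar(lab) >= params$min_term_size & !(lab %in% stop_norm)
  lab <- lab[ok]
  ids <- ids[ok]
  entries <- new.env(parent = emptyenv(), size = max(length(lab), 1L))
  for (i in seq_along(lab)) {
    prev <- entries[[lab[i]]]
    entries[[lab[i]]] <- c(prev, ids[i])
  }
  max_words <- if (length(lab)) max(lengths(strsplit(lab, " ", fixed = TRUE)))
               else 0L
  structure(list(entries = entries, labels = sort(unique(lab)),
                 max_words = max_words, params = params),
            class = "match_dictionary")
}

#' @export
print.match_dictionary <- function(x, ...) {
  cat(sprintf("match_dictionary: %d labels (max %d words)\n",
              length(x$labels), x$max_words))
  invisible(x)
}

empty_mentions <- function() {
  data.frame(term_id = character(), matched_text = character(),
             sentence_index = integer(), char_start = integer(),
             char_end = integer(), stringsAsFactors = FALSE)
}

#' Recognize ontology concepts in a sentence
#'
#' Scans a plain-text sentence for dictionary labels. A word boundary
#' is any character that is not a letter or digit (hyphens are
#' boundaries, so "X-linked" exposes "linked"). With `longest_only`,
#' matches strictly contained in a longer match are suppressed, and of
#' two overlapping equal-length matches only the leftmost is kept;
#' identical spans matching several term ids report all of them. With
#' `filter_number`, matches containing no letters are dropped.
#'
#' @param sentence a plain-text sentence.
#' @param dict a [build_dictionary()] result.
#' @param sentence_index ordinal recorded in the output (default 0).
#' @return A data.frame of mentions with columns `term_id`,
#'   `matched_text`, `sentence_index`, `char_start`, `char_end`
#'   (0-based, half-open, within the sentence), sorted by `char_start`.
#' @export
recognize <- function(sentence, dict, sentence_index = 0L) {
  stopifnot(inherits(dict, "match_dictionary"))
  p <- dict$params
  if (!nzchar(sentence) || length(dict$labels) == 0L) return(empty_mentions())

  if (p$whole_word_only) {
    hits <- scan_tokens(sentence, dict)
  } else {
    hits <- scan_substrings(sentence, dict)
  }
  if (nrow(hits) == 0L) return(empty_mentions())

  if (p$filter_number) {
    hits <- hits[grepl("[A-Za-z]", hits$matched_text), , drop = FALSE]
  }
  if (p$longest_only && nrow(hits) > 1L) {
    hits <- drop_covered(hits)
  }
  if (nrow(hits) == 0L) return(empty_mentions())
  hits$sentence_index <- as.integer(sentence_index)
  hits <- hits[order(hits$char_start, hits$char_end, hits$term_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("term_id", "matched_text", "sentence_index",
           "char_start", "char_end")]
}

# token n-gram scan (whole-word matching)
scan_tokens <- function(sentence, dict) {
  p <- dict$params
  m <- gregexpr("[A-Za-z0-9]+", sentence)[[1]]
  if (m[1] == -1L) return(empty_mentions())
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  ntok <- length(starts)
  out <- list()
  for (i in seq_len(ntok)) {
    for (len in seq_len(min(dict$max_words, ntok - i + 1L))) {
      j <- i + len - 1L
      frag <- substr(sentence, starts[i], ends[j])
      key <- normalize_label(frag, p$case_sensitive)
      ids <- dict$entries[[key]]
      if (!is.null(ids)) {
        out[[length(out) + 1L]] <- data.frame(
          term_id = unique(ids), matched_text = frag,
          sentence_index = 0L,
          char_start = starts[i] - 1L, char_end = ends[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  do.call(rbind, out)
}

# per-label substring scan (whole_word_only = FALSE)
scan_substrings <- function(sentence, dict) {
  p <- dict$params
  # case folding only: offsets must index the original sentence
  hay <- if (p$case_sensitive) sentence else tolower(sentence)
  out <- list()
  for (lab in dict$labels) {
    m <- gregexpr(lab, hay, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (s in as.integer(m)) {
      e <- s + nchar(lab) - 1L
      out[[length(out) + 1L]] <- data.frame(
        term_id = unique(dict$entries[[lab]]),
        matched_text = substr(sentence, s, e),
        sentence_index = 0L, char_start = s - 1L, char_end = e,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  do.call(rbind, out)
}

# longest-only: remove spans strictly contained in another span; then of
# two overlapping equal-length spans keep the leftmost
drop_covered <- function(hits) {
  sp <- unique(hits[, c("char_start", "char_end")])
  n <- nrow(sp)
  keep_span <- rep(TRUE, n)
  for (i in seq_len(n)) {
    contained <- sp$char_start <= sp$char_start[i] &
      sp$char_end >= sp$char_end[i] &
      (sp$char_end - sp$char_start > sp$char_end[i] - sp$char_start[i])
    if (any(contained)) keep_span[i] <- FALSE
  }
  sp <- sp[keep_span, , drop = FALSE]
  sp <- sp[order(sp$char_start, sp$char_end), , drop = FALSE]
  # leftmost-wins among surviving overlapping equal-length spans
  len <- sp$char_end - sp$char_start
  n <- nrow(sp)
  keep2 <- rep(TRUE, n)
  for (i in seq_len(n)) {
    rival <- len == len[i] & sp$char_start < sp$char_start[i] &
      sp$char_end > sp$char_start[i]
    if (any(rival & keep2)) keep2[i] <- FALSE
  }
  sp <- sp[keep2, , drop = FALSE]
  key <- paste(hits$char_start, hits$char_end)
  hits[key %in% paste(sp$char_start, sp$char_end), , drop = FALSE]
}
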