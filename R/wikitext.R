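# Wikitext cleaning, sentence segmentation and provenance filtering.

# Sentence-final abbreviations that must not trigger a split.
.abbreviations <- c(
  "e.g.", "i.e.", "cf.", "vs.", "etc.", "ca.", "al.", "et al.",
  "Fig.", "fig.", "Figs.", "Eq.", "eq.", "No.", "no.", "Dr.", "Prof.",
  "St.", "Mr.", "Mrs.", "Ms.", "Jr.", "Sr.", "approx."
)

#' Remove reference markup and trailing reference sections
#'
#' Drops inline citation tags (`<ref>...</ref>`, self-closing
#' `<ref ... />`) and cuts the document at the first
#' `== References ==`, `== External links ==`, `== Further reading ==`
#' or `== See also ==` heading, so that only main-body prose remains.
#' Best-effort on malformed markup: an unclosed `<ref>` is removed to
#' the end of its line.
#'
#' @param raw_text a wikitext string.
#' @return The text with reference markup removed.
#' @export
strip_references <- function(raw_text) {
  x <- raw_text
  # cut everything from the first reference-type section heading on
  m <- regexpr("(?im)^==+\\s*(References|External links|Further reading|See also|Notes)\\s*==+",
               x, perl = TRUE)
  if (m > 0L) x <- substr(x, 1L, m - 1L)
  x <- gsub("(?s)<ref[^>]*/>", "", x, perl = TRUE)
  x <- gsub("(?s)<ref[^>]*>.*?</ref>", "", x, perl = TRUE)
  # unclosed <ref>: drop to end of line
  x <- gsub("<ref[^>]*>[^\n]*", "", x, perl = TRUE)
  x
}

#' Remove wiki markup from reference-free text
#'
#' Replaces internal links by their display text (`[[a|b]]` -> `b`,
#' `[[a]]` -> `a`), drops file/image links, template blocks
#' (`{{...}}`, nested), HTML comments and tags, bold/italic quote
#' markers, external-link brackets and heading/list markers. Unbalanced
#' markup is left as literal text with a warning.
#'
#' @param text wikitext with references already stripped.
#' @return Plain text.
#' @export
strip_markup <- function(text) {
  x <- text
  # nested templates: innermost-first until fixpoint
  repeat {
    x2 <- gsub("\\{\\{[^{}]*\\}\\}", "", x, perl = TRUE)
    if (identical(x2, x)) break
    x <- x2
  }
  if (grepl("\\{\\{", x)) {
    warning("unbalanced template markup retained as literal text")
  }
  x <- gsub("<!--.*?-->", "", x, perl = TRUE)
  # file/image links (possibly with caption) are dropped entirely
  x <- gsub("\\[\\[(File|Image):[^][]*\\]\\]", "", x, perl = TRUE)
  # piped links keep display text; plain links keep the target
  x <- gsub("\\[\\[[^][|]*\\|([^][]*)\\]\\]", "\\1", x, perl = TRUE)
  x <- gsub("\\[\\[([^][]*)\\]\\]", "\\1", x, perl = TRUE)
  # external links: [url label] -> label, bare [url] dropped
  x <- gsub("\\[\\S+\\s+([^]]*)\\]", "\\1", x, perl = TRUE)
  x <- gsub("\\[\\S+\\]", "", x, perl = TRUE)
  x <- gsub("'{2,}", "", x)                    # bold/italic
  x <- gsub("(?m)^==+\\s*|\\s*==+\\s*$", "", x, perl = TRUE)  # headings
  x <- gsub("(?m)^[*#:;]+\\s*", "", x, perl = TRUE)           # list markers
  x <- gsub("</?[A-Za-z][^>]*>", "", x, perl = TRUE)          # html tags
  x <- gsub("[ \t]+", " ", x)
  x <- gsub("\n{2,}", "\n", x)
  trimws(x)
}

#' Split plain text into sentences
#'
#' A sentence boundary is sentence-final punctuation (`.`, `!`, `?`)
#' followed by whitespace and an uppercase letter or digit. A bundled
#' abbreviation list ("e.g.", "Fig.", "et al.", ...) never splits.
#'
#' @param plain_text a plain-text string.
#' @return Character vector of sentences in order; empty input gives
#'   a zero-length vector.
#' @export
split_sentences <- function(plain_text) {
  x <- gsub("\\s+", " ", trimws(plain_text))
  if (x == "") return(character())
  # protect abbreviation periods with a placeholder (word-initial only,
  # so e.g. "medal." is not mistaken for "al.")
  prot <- x
  for (ab in .abbreviations) {
    pat <- paste0("(^|[\\s(\"'])",
                  gsub("([^A-Za-z0-9])", "\\\\\\1", ab))
    rep <- paste0("\\1", gsub(".", "\x01", ab, fixed = TRUE))
    prot <- gsub(pat, rep, prot, perl = TRUE)
  }
  parts <- strsplit(prot, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Build a gene document from raw wikitext
#'
#' Applies [strip_references()], [strip_markup()] and
#' [split_sentences()] and attaches per-sentence provenance (author and
#' imported flag) when a sidecar table is supplied. Sidecar rows are
#' matched by `sentence_index` (0-based); sentences without a sidecar
#' row get author `"unknown"` and `imported_flag = FALSE`.
#'
#' @param gene_id stable gene identifier.
#' @param raw_text the article wikitext (or already-plain text).
#' @param source_name article title; defaults to `gene_id`.
#' @param provenance optional data.frame with columns `sentence_index`,
#'   `author`, `imported_flag`.
#' @return An object of class `gene_document`: list with `gene_id`,
#'   `source_name`, `raw_text` and `blocks` (data.frame
#'   `sentence_index`, `text`, `author`, `imported_flag`).
#' @export
gene_document <- function(gene_id, raw_text, source_name = gene_id,
                          provenance = NULL) {
  stopifnot(is.character(gene_id), nzchar(gene_id))
  plain <- strip_markup(strip_references(raw_text))
  sents <- split_sentences(plain)
  n <- length(sents)
  blocks <- data.frame(
    sentence_index = seq_len(n) - 1L,
    text = sents,
    author = rep("unknown", n),
    imported_flag = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  if (!is.null(provenance) && n > 0L) {
    idx <- match(blocks$sentence_index, provenance$sentence_index)
    hit <- !is.na(idx)
    blocks$author[hit] <- as.character(provenance$author[idx[hit]])
    if ("imported_flag" %in% names(provenance)) {
      blocks$imported_flag[hit] <-
        as.logical(provenance$imported_flag[idx[hit]])
    }
  }
  structure(list(gene_id = gene_id, source_name = source_name,
                 raw_text = raw_text, blocks = blocks),
            class = "gene_document")
}

#' @export
print.gene_document <- function(x, ...) {
  cat(sprintf("gene_document '%s': %d sentences (%d imported)\n",
              x$gene_id, nrow(x$blocks), sum(x$blocks$imported_flag)))
  invisible(x)
}

#' Drop text blocks that were imported automatically
#'
#' Removes blocks whose author is one of the configured bot accounts or
#' whose imported flag is set, so that mining runs only on text written
#' by human editors. Blocks with unknown authorship are retained.
#' Retained block text is never altered (pure selection).
#'
#' @param doc a [gene_document()].
#' @param bot_authors character vector of bot account names.
#' @return The document with the offending blocks removed.
#' @export
filter_imported_blocks <- function(doc, bot_authors = character()) {
  stopifnot(inherits(doc, "gene_document"))
  b <- doc$blocks
  drop <- b$imported_flag | b$author %in% bot_authors
  doc$blocks <- b[!drop, , drop = FALSE]
  rownames(doc$blocks) <- NULL
  doc
}

#' Read a per-gene corpus from a manifest
#'
#' The manifest is a TSV with columns `gene_id`, `file` and optionally
#' `sidecar` (a provenance TSV with columns `sentence_index`, `author`,
#' `imported_flag`). Paths are resolved relative to the manifest.
#'
#' @param manifest_path path to the manifest TSV.
#' @return A named list of [gene_document()] objects.
#' @export
read_corpus <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "file") %in% names(man)))
  base <- dirname(manifest_path)
  docs <- lapply(seq_len(nrow(man)), function(i) {
    raw <- paste(readLines(file.path(base, man$file[i]), warn = FALSE),
                 collapse = "\n")
    prov <- NULL
    if ("sidecar" %in% names(man) && !is.na(man$sidecar[i]) &&
        nzchar(man$sidecar[i])) {
      prov <- utils::read.delim(file.path(base, man$sidecar[i]),
                                stringsAsFactors = FALSE)
    }
    gene_document(man$gene_id[i], raw, provenance = prov)
  })
  stats::setNames(docs, man$gene_id)
}
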