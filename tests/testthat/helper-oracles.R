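# Independent brute-force oracles and small fixture builders used
# across the suite. Each oracle deliberately takes a different route
# than the implementation it checks.

# --- mini ontology builder -------------------------------------------------

# terms: named character vector id -> label
# edges: data.frame(child, relation, parent)
mini_ontology <- function(terms, edges = NULL, obsolete = character(),
                          namespace = "test_namespace") {
  lines <- c("format-version: 1.2")
  for (id in names(terms)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", id),
               paste0("name: ", terms[[id]]),
               paste0("namespace: ", namespace))
    if (!is.null(edges)) {
      ei <- edges[edges$child == id, , drop = FALSE]
      for (j in seq_len(nrow(ei))) {
        lines <- c(lines, if (ei$relation[j] == "is_a") {
          paste0("is_a: ", ei$parent[j])
        } else {
          paste0("relationship: ", ei$relation[j], " ", ei$parent[j])
        })
      }
    }
    if (id %in% obsolete) lines <- c(lines, "is_obsolete: true")
  }
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  read_obo(path)
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(child = m[, 1], relation = m[, 2], parent = m[, 3],
             stringsAsFactors = FALSE)
}

# --- transitive-closure oracle (boolean matrix powers) ---------------------

oracle_reachability <- function(graph, policy) {
  ids <- graph$id
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- graph$edges[graph$edges$relation %in% unclass(policy), , drop = FALSE]
  if (nrow(e) > 0L) A[cbind(match(e$child, ids), match(e$parent, ids))] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R  # R[x, y] TRUE iff y is reachable upward from x
}

oracle_ancestors <- function(graph, term, policy) {
  R <- oracle_reachability(graph, policy)
  sort(colnames(R)[R[term, ]])
}

oracle_descendants <- function(graph, term, policy) {
  R <- oracle_reachability(graph, policy)
  sort(rownames(R)[R[, term]])
}

# --- recognizer oracle (per-label character scan) --------------------------

# Scans the case-folded sentence for every dictionary label with fixed
# substring search, keeps hits bounded by non-alphanumeric characters,
# then applies the published longest-only contract: drop spans strictly
# contained in longer spans, and of two overlapping equal-length spans
# keep the leftmost.
oracle_recognize <- function(sentence, dict, sentence_index = 0L) {
  p <- dict$params
  hay <- if (p$case_sensitive) sentence else tolower(sentence)
  is_word_char <- function(ch) grepl("[A-Za-z0-9]", ch)
  hits <- list()
  for (lab in dict$labels) {
    m <- gregexpr(lab, hay, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (s in as.integer(m)) {
      e <- s + nchar(lab) - 1L
      if (p$whole_word_only) {
        before <- if (s > 1L) substr(sentence, s - 1L, s - 1L) else ""
        after <- if (e < nchar(sentence)) substr(sentence, e + 1L, e + 1L)
                 else ""
        if (nzchar(before) && is_word_char(before)) next
        if (nzchar(after) && is_word_char(after)) next
      }
      txt <- substr(sentence, s, e)
      if (p$filter_number && !grepl("[A-Za-z]", txt)) next
      for (id in unique(dict$entries[[lab]])) {
        hits[[length(hits) + 1L]] <-
          data.frame(term_id = id, matched_text = txt,
                     sentence_index = as.integer(sentence_index),
                     char_start = s - 1L, char_end = e,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(term_id = character(), matched_text = character(),
                      sentence_index = integer(), char_start = integer(),
                      char_end = integer(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  if (p$longest_only) {
    sp <- unique(h[, c("char_start", "char_end")])
    len <- function(x) x$char_end - x$char_start
    keep <- rep(TRUE, nrow(sp))
    for (i in seq_len(nrow(sp))) {
      for (j in seq_len(nrow(sp))) {
        if (i == j) next
        if (sp$char_start[j] <= sp$char_start[i] &&
            sp$char_end[j] >= sp$char_end[i] &&
            len(sp[j, ]) > len(sp[i, ])) keep[i] <- FALSE
      }
    }
    sp <- sp[keep, , drop = FALSE]
    sp <- sp[order(sp$char_start, sp$char_end), , drop = FALSE]
    alive <- rep(TRUE, nrow(sp))
    for (i in seq_len(nrow(sp))) {
      for (j in seq_len(nrow(sp))) {
        if (j >= i || !alive[j]) next
        if (len(sp[j, ]) == len(sp[i, ]) &&
            sp$char_start[j] < sp$char_start[i] &&
            sp$char_end[j] > sp$char_start[i]) alive[i] <- FALSE
      }
    }
    sp <- sp[alive, , drop = FALSE]
    h <- h[paste(h$char_start, h$char_end) %in%
             paste(sp$char_start, sp$char_end), , drop = FALSE]
  }
  h <- h[order(h$char_start, h$char_end, h$term_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# --- Fisher oracle (log-factorial tail sum) --------------------------------

oracle_fisher_upper <- function(a, b, c, d) {
  lc <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  N <- a + b + c + d
  K <- a + c          # truth genes
  n_draw <- a + b     # mined genes
  ks <- a:min(n_draw, K)
  if (length(ks) == 0L || a == 0L) return(1)
  sum(exp(lc(K, ks) + lc(N - K, n_draw - ks) - lc(N, n_draw)))
}

# exact discordant-significance probabilities for the null simulation:
# random truth sets of size s drawn from N genes, fixed nested mined
# sets Mb (size mb) within Ma (size ma)
oracle_null_rates <- function(mb, ma, N, s, alpha) {
  q_gained <- 0
  q_lost <- 0
  extra <- ma - mb
  for (x in 0:min(mb, s)) {
    for (y in 0:min(extra, s - x)) {
      rest <- s - x - y
      if (rest > N - ma) next
      pr <- exp(lchoose(mb, x) + lchoose(extra, y) +
                  lchoose(N - ma, rest) - lchoose(N, s))
      p_b <- oracle_fisher_upper(x, mb - x, s - x, N - mb - (s - x))
      p_a <- oracle_fisher_upper(x + y, ma - x - y, s - x - y,
                                 N - ma - (s - x - y))
      if (p_a < alpha && p_b >= alpha) q_gained <- q_gained + pr
      if (p_b < alpha && p_a >= alpha) q_lost <- q_lost + pr
    }
  }
  c(gained = q_gained, lost = q_lost)
}

# --- random-sentence generator for recognizer equivalence ------------------

random_sentences <- function(n, label_words, distractors, seed) {
  withr::with_seed(seed, {
    seps <- c(" ", " ", " ", ", ", "-", " ")
    vocab <- c(label_words, distractors, "123", "7", "2026")
    vapply(seq_len(n), function(i) {
      k <- sample(3:12, 1)
      words <- sample(vocab, k, replace = TRUE)
      caps <- runif(k) < 0.2
      words[caps] <- paste0(toupper(substr(words[caps], 1, 1)),
                            substr(words[caps], 2, nchar(words[caps])))
      out <- words[1]
      for (j in seq_len(k - 1L)) {
        out <- paste0(out, sample(seps, 1), words[j + 1L])
      }
      paste0(out, ".")
    }, character(1))
  })
}

# small utility: mention data.frames comparable regardless of rownames
mention_key <- function(m) {
  m <- m[order(m$char_start, m$char_end, m$term_id), , drop = FALSE]
  paste(m$term_id, m$char_start, m$char_end, m$matched_text, sep = "|")
}
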