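# OBO ontology loading and hierarchy queries.

#' Relation policies for hierarchy traversal
#'
#' A relation policy is the set of edge labels that are treated as
#' subsumption ("is a") links when computing broader/narrower closures.
#' Disease-ontology-style comparisons traverse only `is_a`;
#' GO-style comparisons additionally treat `part_of`, `regulates`,
#' `positively_regulates` and `negatively_regulates` as if they were
#' `is_a`, so that e.g. "positive regulation of X" counts as narrower
#' than X.
#'
#' @param allowed_relations character vector of relation labels.
#' @return A character vector of class `relation_policy`.
#' @export
#' @examples
#' do_policy()
#' go_policy()
relation_policy <- function(allowed_relations) {
  allowed_relations <- unique(as.character(allowed_relations))
  if (length(allowed_relations) == 0L) {
    stop("a relation policy must contain at least one relation label")
  }
  structure(allowed_relations, class = "relation_policy")
}

#' @rdname relation_policy
#' @export
do_policy <- function() relation_policy("is_a")

#' @rdname relation_policy
#' @export
go_policy <- function() {
  relation_policy(c("is_a", "part_of", "regulates",
                    "positively_regulates", "negatively_regulates"))
}

#' Read an OBO 1.2 flat file into an ontology graph
#'
#' Parses `[Term]` stanzas into a typed DAG. `is_a:` lines and
#' `relationship: <type> <id>` lines both become parent edges labelled
#' with their relation type. Obsolete terms are loaded and flagged; they
#' are excluded from dictionary building and from hierarchy closures.
#' `alt_id:` accessions are recorded and resolve to their canonical id.
#' Trailing `! comment` text is ignored. Stanza types other than
#' `[Term]` (e.g. `[Typedef]`) are skipped.
#'
#' The graph restricted to any relation subset must be acyclic; a cycle
#' is reported as an error at load time, as is any parent reference to
#' an id that never appears as a `[Term]`.
#'
#' @param path path to an OBO 1.2 flat file.
#' @return An object of class `ontology_graph`: a list with elements
#'   `id`, `label`, `namespace`, `obsolete` (parallel vectors over
#'   terms), `edges` (data.frame `child`, `relation`, `parent`),
#'   `alt_ids` (named character, alt id -> canonical id) and
#'   `relation_types`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanza_line <- 0L
  terms <- list()

  flush_term <- function(cur, stanza_line) {
    if (is.null(cur$id)) {
      stop(sprintf("malformed [Term] stanza starting at line %d: missing id",
                   stanza_line))
    }
    cur
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "" || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      if (in_term) terms[[length(terms) + 1L]] <- flush_term(cur, stanza_line)
      in_term <- identical(line, "[Term]")
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  obsolete = FALSE, alt_ids = character(),
                  parents = character(), relations = character())
      stanza_line <- i
      next
    }
    if (!in_term) next
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 1L) {
      stop(sprintf("malformed line %d in OBO file: %s", i, line))
    }
    key <- substr(line, 1L, colon - 1L)
    value <- trimws(substr(line, colon + 1L, nchar(line)))
    value <- sub("\\s*!.*$", "", value)  # strip trailing comment
    if (key == "id") {
      cur$id <- value
    } else if (key == "name") {
      cur$name <- value
    } else if (key == "namespace") {
      cur$namespace <- value
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(value), "true")
    } else if (key == "alt_id") {
      cur$alt_ids <- c(cur$alt_ids, value)
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, value)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(value, "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop(sprintf("malformed relationship at line %d: %s", i, line))
      }
      cur$parents <- c(cur$parents, parts[[2]])
      cur$relations <- c(cur$relations, parts[[1]])
    }
    # other keys (def, synonym, xref, ...) are ignored
  }
  if (in_term) terms[[length(terms) + 1L]] <- flush_term(cur, stanza_line)
  if (length(terms) == 0L) stop("no [Term] stanzas found in ", path)

  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  edges <- do.call(rbind, lapply(terms, function(t) {
    if (length(t$parents) == 0L) return(NULL)
    data.frame(child = t$id, relation = t$relations, parent = t$parents,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), relation = character(),
                        parent = character(), stringsAsFactors = FALSE)
  }
  dangling <- setdiff(edges$parent, ids)
  if (length(dangling) > 0L) {
    stop("unresolved parent ids: ", paste(sort(dangling), collapse = ", "))
  }
  alt_pairs <- do.call(rbind, lapply(terms, function(t) {
    if (length(t$alt_ids) == 0L) return(NULL)
    cbind(t$alt_ids, t$id)
  }))
  alt_ids <- character()
  if (!is.null(alt_pairs)) {
    alt_ids <- stats::setNames(alt_pairs[, 2], alt_pairs[, 1])
  }

  g <- structure(list(
    id = ids,
    label = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace"),
    obsolete = vapply(terms, `[[`, logical(1), "obsolete"),
    edges = edges,
    alt_ids = alt_ids,
    relation_types = sort(unique(edges$relation))
  ), class = "ontology_graph")
  assert_acyclic(g)
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms (%d obsolete), %d edges [%s]\n",
              length(x$id), sum(x$obsolete), nrow(x$edges),
              paste(x$relation_types, collapse = ", ")))
  invisible(x)
}

# Kahn's algorithm over the full edge set; a cycle under the full set
# implies a cycle under some relation subset, and every subset of an
# acyclic graph is acyclic.
assert_acyclic <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) return(invisible(TRUE))
  ids <- graph$id
  child <- match(e$child, ids)
  parent <- match(e$parent, ids)
  indeg <- tabulate(parent, nbins = length(ids))
  queue <- which(indeg == 0L)
  seen <- 0L
  alive <- rep(TRUE, nrow(e))
  while (length(queue) > 0L) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    out <- which(alive & child == v)
    for (k in out) {
      alive[k] <- FALSE
      indeg[parent[k]] <- indeg[parent[k]] - 1L
      if (indeg[parent[k]] == 0L) queue <- c(queue, parent[k])
    }
  }
  if (seen < length(ids)) {
    stop("ontology contains a relation cycle; hierarchy closures are undefined")
  }
  invisible(TRUE)
}

resolve_term <- function(graph, term_id) {
  if (term_id %in% names(graph$alt_ids)) term_id <- graph$alt_ids[[term_id]]
  if (!term_id %in% graph$id) stop("unknown term id: ", term_id)
  term_id
}

#' Term metadata accessors
#'
#' @param graph an `ontology_graph`.
#' @param term_id a term accession (alt ids resolve to their canonical id).
#' @return `term_label` and `term_namespace` return a character scalar.
#' @export
term_label <- function(graph, term_id) {
  graph$label[match(resolve_term(graph, term_id), graph$id)]
}

#' @rdname term_label
#' @export
term_namespace <- function(graph, term_id) {
  graph$namespace[match(resolve_term(graph, term_id), graph$id)]
}

closure <- function(graph, term_id, policy, up, include_obsolete) {
  term_id <- resolve_term(graph, term_id)
  e <- graph$edges
  keep <- e$relation %in% unclass(policy)
  from <- if (up) e$child[keep] else e$parent[keep]
  to <- if (up) e$parent[keep] else e$child[keep]
  if (!include_obsolete) {
    # obsolete terms are neither reported nor traversed through
    obs <- graph$id[graph$obsolete]
    drop <- from %in% obs | to %in% obs
    from <- from[!drop]
    to <- to[!drop]
  }
  out <- character()
  frontier <- term_id
  while (length(frontier) > 0L) {
    nxt <- unique(to[from %in% frontier])
    nxt <- setdiff(nxt, c(out, term_id))
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

#' Broader and narrower term closures
#'
#' `term_ancestors` returns every term reachable from `term_id` by
#' repeatedly following parent edges whose relation label is in
#' `policy` (the broader terms); `term_descendants` mirrors it on
#' reversed edges (the narrower terms). The query term itself is never
#' included, and obsolete terms are excluded unless
#' `include_obsolete = TRUE`.
#'
#' @param graph an `ontology_graph` from [read_obo()].
#' @param term_id a term accession present in the graph.
#' @param policy a [relation_policy()]; default [do_policy()].
#' @param include_obsolete include obsolete terms in the closure.
#' @return Sorted character vector of term ids (possibly empty).
#' @export
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: GO:0007599", "name: hemostasis",
#'              "[Term]", "id: GO:0007596", "name: blood coagulation",
#'              "is_a: GO:0007599"), obo)
#' g <- read_obo(obo)
#' term_ancestors(g, "GO:0007596")   # "GO:0007599"
term_ancestors <- function(graph, term_id, policy = do_policy(),
                           include_obsolete = FALSE) {
  closure(graph, term_id, policy, up = TRUE, include_obsolete = include_obsolete)
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(graph, term_id, policy = do_policy(),
                             include_obsolete = FALSE) {
  closure(graph, term_id, policy, up = FALSE, include_obsolete = include_obsolete)
}
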