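# Fisher-exact gene-set enrichment and the controlled augmentation
# experiment with its random-gene-set null simulation.

#' 2x2 gene-count contingency table
#'
#' Cell layout for one term: `a` = genes in both the mined set and the
#' truth set; `b` = mined only; `c` = truth only; `d` = background
#' remainder, so `a + b + c + d` is the background size.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return A list of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  if (any(cells != round(cells))) stop("contingency cells must be integers")
  cells <- stats::setNames(as.integer(round(cells)), names(cells))
  structure(as.list(cells), class = "contingency_table")
}

#' One-tailed Fisher exact test (enrichment direction)
#'
#' The probability, with both margins fixed, of an overlap at least as
#' large as observed: p = sum over k = a .. min(a+b, a+c) of the
#' hypergeometric point mass. Equivalent to the hypergeometric
#' upper-tail test used by enrichment tools. Zero overlap gives p = 1
#' exactly.
#'
#' @param table a [contingency_table()].
#' @param two_tailed use the two-tailed Fisher test instead (sum of all
#'   point masses not exceeding the observed one).
#' @return The p-value.
#' @export
fisher_one_tailed <- function(table, two_tailed = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a == 0L && !two_tailed) return(1)
  if (two_tailed) {
    m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    return(stats::fisher.test(m)$p.value)
  }
  # X ~ Hypergeometric(white = a+c truth genes, black = b+d, drawn = a+b)
  stats::phyper(a - 1L, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Sample odds ratio of a 2x2 table
#'
#' (a*d)/(b*c); `Inf` when the denominator is zero with a positive
#' numerator, and `NA` (undefined) for 0/0.
#'
#' @param table a [contingency_table()].
#' @return The odds ratio.
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  num <- as.numeric(table$a) * table$d
  den <- as.numeric(table$b) * table$c
  if (den == 0) {
    if (num > 0) return(Inf)
    return(NA_real_)
  }
  num / den
}

#' Invert candidate annotations into term -> gene sets
#'
#' Direct assignments only: no propagation up the ontology.
#'
#' @param candidates a `candidate_set` or data.frame with `gene_id`,
#'   `term_id` columns; also accepts a [reference_set()].
#' @return Named list: term id -> character vector of gene ids.
#' @export
build_term_gene_sets <- function(candidates) {
  df <- if (inherits(candidates, "reference_set")) candidates$annotations
        else as_candidate_df(candidates)
  if (nrow(df) == 0L) return(stats::setNames(list(), character()))
  lapply(split(df$gene_id, df$term_id), function(g) sort(unique(g)))
}

term_table <- function(mined_genes, truth_genes, background) {
  mined_genes <- intersect(mined_genes, background)
  truth_genes <- intersect(truth_genes, background)
  a <- length(intersect(mined_genes, truth_genes))
  b <- length(mined_genes) - a
  c <- length(truth_genes) - a
  d <- length(background) - a - b - c
  contingency_table(a, b, c, d)
}

#' Controlled enrichment experiment: does corpus augmentation help?
#'
#' For every term with at least one truth gene, builds the 2x2 table of
#' background genes assigned / not assigned to the term by the mined
#' set and by the truth set, computes the one-tailed Fisher p for the
#' baseline mined annotations and for the augmented ones, and tallies
#' per-term significance changes at `alpha`. `gained` counts terms
#' significant only after augmentation; `lost` counts terms significant
#' only before.
#'
#' @param truth a [reference_set()] of curated annotations (typically
#'   non-IEA; see [filter_evidence()]).
#' @param mined_baseline,mined_augmented `candidate_set`s or candidate
#'   data.frames; the augmented set is usually the baseline plus
#'   annotations mined from an additional corpus.
#' @param background character vector: the gene universe (must contain
#'   every gene in the truth and mined sets); conventionally the genes
#'   possessing at least one reference annotation.
#' @param alpha significance level (default 0.01).
#' @return A list of class `augmentation_comparison`: `results`
#'   (per-term data.frame with cells, p-values and odds ratios for both
#'   corpora), `alpha`, and counts `significant_baseline`,
#'   `significant_augmented`, `gained`, `lost`.
#' @export
run_enrichment_experiment <- function(truth, mined_baseline, mined_augmented,
                                      background, alpha = 0.01) {
  if (length(background) == 0L) stop("background gene universe is empty")
  background <- unique(as.character(background))
  truth_sets <- build_term_gene_sets(truth)
  miss <- setdiff(unlist(truth_sets), background)
  if (length(miss) > 0L) {
    stop("background must contain every truth gene; missing: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  base_sets <- build_term_gene_sets(mined_baseline)
  aug_sets <- build_term_gene_sets(mined_augmented)
  terms <- names(truth_sets)[lengths(truth_sets) > 0L]
  rows <- lapply(terms, function(tm) {
    tb <- term_table(base_sets[[tm]], truth_sets[[tm]], background)
    ta <- term_table(aug_sets[[tm]], truth_sets[[tm]], background)
    data.frame(term_id = tm,
               a_base = tb$a, b_base = tb$b, c_base = tb$c, d_base = tb$d,
               a_aug = ta$a, b_aug = ta$b, c_aug = ta$c, d_aug = ta$d,
               p_base = fisher_one_tailed(tb), p_aug = fisher_one_tailed(ta),
               odds_ratio_base = odds_ratio(tb), odds_ratio_aug = odds_ratio(ta),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(res)) stop("truth set contains no terms with genes")
  res$significant_base <- res$p_base < alpha
  res$significant_aug <- res$p_aug < alpha
  res$p_base_bh <- stats::p.adjust(res$p_base, method = "BH")
  res$p_aug_bh <- stats::p.adjust(res$p_aug, method = "BH")
  structure(list(
    results = res,
    alpha = alpha,
    significant_baseline = sum(res$significant_base),
    significant_augmented = sum(res$significant_aug),
    gained = sum(res$significant_aug & !res$significant_base),
    lost = sum(res$significant_base & !res$significant_aug)),
    class = "augmentation_comparison")
}

#' @export
print.augmentation_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "enrichment over %d terms at alpha = %g:\n",
    "  significant with baseline corpus:  %d\n",
    "  significant with augmented corpus: %d\n",
    "  gained: %d, lost: %d\n"),
    nrow(x$results), x$alpha, x$significant_baseline,
    x$significant_augmented, x$gained, x$lost))
  invisible(x)
}

#' Significance counts at several levels
#'
#' The per-term p-values tabulated at conventional alpha levels.
#'
#' @param comparison an `augmentation_comparison`.
#' @param alphas significance levels.
#' @return data.frame with per-alpha baseline/augmented/gained/lost.
#' @export
significance_profile <- function(comparison,
                                 alphas = c(0.05, 0.01, 0.001)) {
  res <- comparison$results
  do.call(rbind, lapply(alphas, function(al) {
    sb <- res$p_base < al
    sa <- res$p_aug < al
    data.frame(alpha = al, significant_baseline = sum(sb),
               significant_augmented = sum(sa),
               gained = sum(sa & !sb), lost = sum(sb & !sa))
  }))
}

#' Random-gene-set null simulation
#'
#' Repeats the focal-term analysis with random truth sets: in each
#' iteration, `set_size` genes are drawn uniformly without replacement
#' from the background and treated as the truth set; the one-tailed
#' Fisher p is computed against the focal term's baseline and augmented
#' mined gene sets. An iteration counts as `gained` when only the
#' augmented p is significant at `alpha`, and as `lost` when only the
#' baseline p is. For mined sets unrelated to the sampled genes both
#' counts should be small — random gene sets should produce almost no
#' discordant significance.
#'
#' @param mined_baseline_genes,mined_augmented_genes character vectors:
#'   the focal term's mined gene sets.
#' @param background character vector, the sampling universe.
#' @param set_size genes per random truth set (must not exceed the
#'   background size).
#' @param iterations number of iterations (> 0).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed.
#' @return A list of class `null_simulation`: `gained`, `lost`,
#'   `iterations`, `alpha` and `log` (per-iteration p-values).
#' @export
null_simulation <- function(mined_baseline_genes, mined_augmented_genes,
                            background, set_size, iterations = 1000L,
                            alpha = 0.01, seed = 1L) {
  if (iterations <= 0L) stop("iterations must be positive")
  background <- unique(as.character(background))
  if (set_size > length(background)) {
    stop("set_size exceeds the background size")
  }
  mb <- intersect(unique(mined_baseline_genes), background)
  ma <- intersect(unique(mined_augmented_genes), background)
  p_base <- numeric(iterations)
  p_aug <- numeric(iterations)
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      truth <- sample(background, set_size)
      p_base[it] <- fisher_one_tailed(term_table(mb, truth, background))
      p_aug[it] <- fisher_one_tailed(term_table(ma, truth, background))
    }
  })
  gained <- sum(p_aug < alpha & p_base >= alpha)
  lost <- sum(p_base < alpha & p_aug >= alpha)
  structure(list(gained = gained, lost = lost, iterations = iterations,
                 alpha = alpha,
                 log = data.frame(iteration = seq_len(iterations),
                                  p_base = p_base, p_aug = p_aug)),
            class = "null_simulation")
}

#' @export
print.null_simulation <- function(x, ...) {
  cat(sprintf(paste0(
    "null simulation, %d iterations at alpha = %g:\n",
    "  significant only with augmented corpus (gained): %d\n",
    "  significant only with baseline corpus (lost):    %d\n"),
    x$iterations, x$alpha, x$gained, x$lost))
  invisible(x)
}
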