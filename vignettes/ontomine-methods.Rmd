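---
title: "Mining ontology-based gene annotations from gene-centric text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining ontology-based gene annotations from gene-centric text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomine)
```

## The annotation-mining model

The package rests on one assumption: in a corpus where each document
is dedicated to a single gene, an occurrence of an ontology term label
inside the document is evidence that the term applies to that gene.
This "one article, one gene" shortcut sidesteps the hardest part of
biomedical relation extraction — deciding *which* gene a statement is
about — at the cost of a characteristic error profile: cell-line names
("SH-SY5Y neuroblastoma cells"), polysemous general terms, and
negated or historical statements all produce false candidates. The
pipeline therefore separates *generation* (recognition is tuned for
precision) from *audit* (classification against references, manual
evaluation categories, precision bounds), and the package implements
both halves.

### Concept recognition

Recognition is dictionary-based. The dictionary holds the preferred
label of every non-obsolete term; synonyms are excluded by default
because ontology synonym sets mix exact with broader/narrower/related
variants, which in early precision-oriented use proved to inject
wrong-concept matches. An `with_synonyms` flag exists (default off)
for dictionaries whose synonyms are known to be exact.

Matching parameters (`match_params()`) mirror a precision-first
annotator configuration:

| parameter | default | meaning |
|---|---|---|
| `min_term_size` | 3 | labels shorter than 3 characters never match |
| `whole_word_only` | `TRUE` | matches bounded by non-alphanumeric characters |
| `longest_only` | `TRUE` | spans strictly inside a longer match are dropped |
| `filter_number` | `TRUE` | matches with no letters are dropped |
| `stopwords` | "protein", "gene" + ~130 function words | labels never entered in the dictionary |
| `case_sensitive` | `FALSE` | case-folded matching |

Two conventions are deliberate and documented because golden outputs
depend on them. First, a word boundary is *any* character that is not
a letter or digit, so hyphens delimit words ("X-linked" exposes
"linked"). Second, with `longest_only`, after containment filtering,
two overlapping equal-length spans are resolved leftmost-wins, and a
span matching several ambiguous labels reports every tied term id.
The recognizer is validated against an independent brute-force
character-scan matcher implementing the same published contract; the
two agree exactly on 10^4 random sentences in the test suite.

### Text cleaning

Wikitext cleaning removes citation markup and trailing
reference-type sections, resolves links to their display text, drops
templates and HTML, and segments sentences at sentence-final
punctuation followed by whitespace and an uppercase letter or digit,
with a bundled abbreviation list ("e.g.", "Fig.", "et al.", ...)
protected. Which markup classes beyond references should be removed is
underdetermined; the rule set here is an explicit approximation and is
frozen by round-trip tests (generated markup in, recorded plain text
out). Provenance-based filtering consumes per-sentence author labels
supplied as a sidecar table rather than recomputing authorship from
edit histories: the defunct trust-scoring service that originally
produced such labels is not reimplemented, but the filtering logic —
drop blocks authored by bot accounts or flagged as imported, keep
unknown authors — is fully preserved and tested.

### Lineage classification

A candidate term is compared with the reference terms of its gene
through the ontology DAG: `EXACT` if present, `MORE_SPECIFIC` if a
descendant of a reference term, `MORE_GENERAL` if an ancestor,
`NONE` otherwise. Relation traversal is policy-driven: `is_a` alone
for DO-style ontologies; for GO, `part_of` and the three regulation
relations are traversed *as if* they were `is_a`, so that "positive
regulation of X" counts as narrower than X. When a candidate is
simultaneously broader than one reference term and narrower than
another, the default precedence reports `MORE_SPECIFIC` — the
narrower hit is the more informative relationship — but the
per-candidate table records both flags so the opposite convention
(`precedence = "general_first"`) can be recomputed from the same
output. Obsolete terms are excluded from dictionaries and closures by
default (`include_obsolete` reverses this); alternate ids resolve to
their canonical term; cycles are rejected at load time because closure
semantics are undefined on them and both target ontologies are DAGs by
construction.

### Precision bounds

With `novel = none + child` candidates lacking any exact-or-broader
match, and a manually evaluated sample of that pool tallied into
categories 1A–3C, the bounds are

$$\mathrm{lower} = \frac{exact + moregeneral + \frac{e_{1a}+e_{1b}+e_{1c}}{e_{all}}(none+child)}{all},
\qquad
\mathrm{upper} = \mathrm{lower} + \frac{e_{2a}}{e_{all}}\cdot\frac{none+child}{all}.$$

Category 1C ("correct but too specific") is counted as valid by
default, matching the printed form of the estimator; `include_1c =
FALSE` removes it from both bounds for users who prefer the stricter
reading. Both conventions coincide whenever no 1C verdicts occur. The
evaluation sample itself is drawn with a seeded uniform sampler over
the novel pool (`sample_novel_candidates()`).

### Enrichment testing

For each term, a 2×2 table counts background genes assigned/not
assigned by the mined set and by the truth set. The implemented
default is the one-tailed (enrichment-direction) Fisher exact test,
equal to the hypergeometric upper tail
$p = \sum_{k \ge a} P(X = k)$ — the form used by mainstream
enrichment tools, and the form under which zero overlap gives exactly
p = 1. A two-tailed option exists for completeness. The odds ratio is
the plain cross-product $(ad)/(bc)$, reported as infinite when only
the denominator vanishes and as missing for 0/0. Truth sets exclude
IEA-coded (electronically inferred) annotations, while candidate
comparison keeps them; both behaviours are flag-reversible. No
ancestor propagation is applied to either gene set by default — terms
are compared as assigned — and no multiple-testing correction is
applied to the headline counts, though Benjamini–Hochberg-adjusted
columns are emitted alongside the raw p-values. Because the
significance threshold in published augmentation counts is typically
unstated, `significance_profile()` always tabulates
$\alpha \in \{0.05, 0.01, 0.001\}$.

The null simulation replaces the truth set with `set_size` genes
drawn uniformly without replacement from the background and repeats
the baseline/augmented comparison; discordant significance (gained:
augmented-only; lost: baseline-only) under this null estimates the
false-gain rate of the whole design.

## What the generators emulate

The synthetic fixtures define the study conditions and are not tuned
per test:

* `make_toy_ontology()` — random DAGs with typed edges (`is_a`,
  `part_of`, regulation relations in chosen proportions), pseudo-word
  labels disjoint from English distractor vocabulary, optional
  obsolete terms. Every later term attaches 1–2 parents among earlier
  terms, so acyclicity holds under every relation subset.
* `make_corpus()` — one article per gene; each sentence embeds exactly
  one planted label between distractor words, with wiki markup
  injected into a configurable fraction of sentences (default 20%)
  and a configurable fraction attributed to a bot author. Because the
  distractor vocabulary is checked against all labels and label
  tokens, recognizer precision and recall are exactly 1 on clean
  fixtures — which is the point: failures indicate recognizer bugs,
  not corpus ambiguity.
* `make_reference()` — models the audit structure: each planted
  annotation is dropped with probability d (producing `NONE`) or
  generalized to a random proper ancestor with probability g
  (producing `MORE_SPECIFIC`), yielding expected class proportions
  $((1-d)(1-g),\,(1-d)g,\,d)$ with 3σ binomial bands. These
  proportions are exact only when each gene carries a single
  annotation; with several annotations per gene, lineage overlap
  between a candidate and the gene's *other* reference terms inflates
  the match classes, so the calibration fixture uses one annotation
  per gene (2,000 genes) and the effect is documented here rather
  than corrected for.
* `make_enrichment_scenario()` — a planted augmentation effect: the
  planted term's label appears in a fraction `signal_base` of its
  truth genes' baseline documents and `signal_aug` of their
  augmentation documents; all other gene–term pairings occur
  independently at a small background rate (default 0.002). The
  default study size (500 genes, 30 terms, planted truth set of 20)
  gives the augmented test essentially unbounded power at
  $\alpha = 0.01$ when the signal goes from 0 to 1, mirroring a
  corpus-augmentation effect on a well-annotated term.

What passing these tests does **not** show: real article text is not
distractor words around verbatim labels — real recall is limited by
paraphrase and synonymy (labels must appear verbatim), and real
precision by polysemy and sentence context, which is exactly why the
manual-evaluation categories and precision bounds exist. The
generators validate the *machinery*, not the linguistic difficulty of
the task.

## Numerical and design choices

* Randomness: all generators and samplers use R's default
  Mersenne-Twister through `withr::with_seed`, restoring RNG state;
  identical spec + seed gives byte-identical files. Character sorts in
  file output use radix (C-locale) ordering for platform stability.
* Fisher p-values are computed from the hypergeometric distribution
  (`phyper`); the suite cross-checks them against an independent
  log-factorial tail sum at 1e-12 relative tolerance over all tables
  with cells ≤ 15, and the null-simulation counts against exact
  discordance probabilities obtained by enumerating the joint overlap
  distribution of nested mined sets.
* Degenerate inputs: empty documents mine to empty candidate sets;
  empty reference sets classify everything `NONE`; a zero-size novel
  pool makes the precision bounds collapse to
  $(exact + moregeneral)/all$ independently of the tally; an empty
  evaluation sample is an error, not a silent zero.
* Problem sizes in the shipped suite: 10^4 sentences for the
  recognizer-equivalence check, 200 random DAGs (5–30 terms) × all 7
  relation subsets for closure checks, a 2,000-annotation
  classification calibration, 65,536 Fisher tables, 1,000 null
  iterations, and 100 seeds of the planted-power scenario. These are
  the sizes at which the checked properties stabilize; all are plain
  package calls and scale up by changing the arguments.

## Known limitations

* Verbatim-label matching bounds recall; enabling exact synonyms
  (`with_synonyms`) is wired but only as useful as the synonym quality
  of the ontology release.
* Sentence-level provenance is only as good as the supplied sidecar;
  unknown authorship is retained rather than dropped, which favours
  recall of human-edited text at some precision risk.
* The enrichment experiment treats mined annotations as flat gene
  sets; no true-path propagation is applied unless requested, so very
  specific mined terms do not credit their ancestors.
* Inter-annotator agreement for the evaluation tallies is out of
  scope: tallies are inputs, and the bounds inherit whatever bias the
  evaluators had.
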