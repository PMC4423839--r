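# Local gene-set enrichment: upper-tail hypergeometric test with
# Benjamini-Hochberg adjustment, plus the per-pair robustness score. This is
# a deliberate offline replacement for web-service enrichment tools (whose
# modified Fisher scores are not reproducible locally): plain hypergeometric
# p-values against a fixed gene universe.

#' Hypergeometric gene-set enrichment
#'
#' For each term, tests whether the query set overlaps the term more than
#' expected when drawing `|query|` genes from the universe without
#' replacement: `p = P(overlap >= observed)`, the upper hypergeometric tail.
#' P-values are Benjamini-Hochberg adjusted across the terms tested. Terms
#' are intersected with the universe first; terms with no universe gene are
#' dropped.
#'
#' @param query Nonempty character vector of gene ids, a subset of
#'   `universe`.
#' @param universe Character vector: all genes that could have been selected.
#' @param gene_sets Named list of gene-id vectors (see [read_gene_sets()]).
#' @param alpha Significance level applied to the adjusted p-value
#'   (default 0.01).
#' @return `data.frame` per term: `term_id`, `n_term`, `n_overlap`,
#'   `p_value`, `p_adjusted`, `significant`; ordered by `p_value`.
#' @examples
#' enrich(c("g1", "g2"), paste0("g", 1:10), list(t1 = c("g1", "g2", "g3")))
#' @export
enrich <- function(query, universe, gene_sets, alpha = 0.01) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query)) abort("empty query gene set")
  stray <- setdiff(query, universe)
  if (length(stray))
    abort("query gene(s) outside the universe: %s",
          paste(head(stray, 5L), collapse = ", "))
  terms <- lapply(gene_sets, intersect, universe)
  terms <- terms[vapply(terms, length, integer(1L)) > 0L]
  if (!length(terms))
    return(data.frame(term_id = character(), n_term = integer(),
                      n_overlap = integer(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  n_universe <- length(universe); n_query <- length(query)
  n_term <- vapply(terms, length, integer(1L))
  n_overlap <- vapply(terms, function(g) length(intersect(g, query)), integer(1L))
  p <- phyper(n_overlap - 1L, n_term, n_universe - n_term, n_query,
              lower.tail = FALSE)
  out <- data.frame(term_id = names(terms), n_term = n_term,
                    n_overlap = n_overlap, p_value = p,
                    p_adjusted = p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

# adjusted p-value of every term in every evaluated human-vs-xeno pair;
# pairs with an empty differential set are skipped
per_pair_enrichment <- function(de, pairs, universe, gene_sets, alpha = 0.01) {
  hx <- pairs[pairs$kind == "human_vs_xeno", , drop = FALSE]
  if (!nrow(hx)) abort("no human-vs-xeno pairs to evaluate")
  gene_lists <- lapply(hx$pair_id, function(pid)
    unique(de$gene_id[de$pair_id == pid]))
  names(gene_lists) <- hx$pair_id
  gene_lists <- gene_lists[vapply(gene_lists, length, integer(1L)) > 0L]
  if (!length(gene_lists))
    abort("every human-vs-xeno pair has an empty differential set")
  lapply(gene_lists, function(g) {
    e <- enrich(intersect(g, universe), universe, gene_sets, alpha)
    setNames(e$p_adjusted, e$term_id)
  })
}

#' Robustness score of an enriched term
#'
#' A term found enriched in the pooled consensus set may be carried by a few
#' extreme comparisons. The robustness score asks instead: in what fraction
#' of individual human-vs-xeno pairs is the term enriched (adjusted
#' p < `alpha`) when testing that pair's own differential gene set? Pairs
#' with an empty differential set are excluded from the denominator.
#'
#' @param term Term id present in `gene_sets`.
#' @param de Long differential table from [differential_table()].
#' @param pairs Pair table; only human-vs-xeno pairs are evaluated.
#' @inheritParams enrich
#' @return A fraction in `[0, 1]`.
#' @seealso [robustness_scores()] for all terms at once.
#' @export
robustness_score <- function(term, de, pairs, universe, gene_sets,
                             alpha = 0.01) {
  if (!(term %in% names(gene_sets)))
    abort("term '%s' absent from the annotation", term)
  robustness_scores(de, pairs, universe, gene_sets, alpha)[[term]]
}

#' @rdname robustness_score
#' @return `robustness_scores()`: named numeric vector, one score per term.
#' @export
robustness_scores <- function(de, pairs, universe, gene_sets, alpha = 0.01) {
  padj <- per_pair_enrichment(de, pairs, universe, gene_sets, alpha)
  vapply(names(gene_sets), function(term) {
    hits <- vapply(padj, function(p) !is.na(p[term]) && p[term] < alpha,
                   logical(1L))
    mean(hits)
  }, numeric(1L))
}
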