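# Per-pair fold-change differential expression, cross-dataset consensus
# selection, leave-one-out stability, and the gene-drug interaction join.

#' Fold-change differential genes for one comparison pair
#'
#' On log2 data a gene is differential when the between-sample ratio reaches
#' the fold-change cutoff: up if `log2(b) - log2(a) >= log2(fc_cutoff)`, down
#' if `<= -log2(fc_cutoff)` (boundary inclusive). Direction is relative to
#' `sample_a`, i.e. xenograft relative to human for human-vs-xeno pairs and
#' later relative to earlier passage otherwise.
#'
#' @param m Log2-scale [expression_matrix()]; linear input is refused.
#' @param pair One row of a pair table ([derive_pairs()]).
#' @param fc_cutoff Linear fold-change cutoff, default 1.5.
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
differential_genes <- function(m, pair, fc_cutoff = 1.5) {
  stopifnot(is_expression_matrix(m))
  if (expr_scale(m) != "log2")
    abort("fold-change screening needs a log2-scale matrix; run log_transform() first")
  if (fc_cutoff <= 1) abort("fc_cutoff must exceed 1")
  for (s in c(pair$sample_a, pair$sample_b))
    if (!(s %in% colnames(m))) abort("pair sample '%s' missing from matrix", s)
  delta <- unclass(m)[, pair$sample_b] - unclass(m)[, pair$sample_a]
  lfc <- log2(fc_cutoff)
  list(up = rownames(m)[delta >= lfc], down = rownames(m)[delta <= -lfc])
}

#' Differential genes for every pair, in long format
#'
#' @param m Log2-scale [expression_matrix()].
#' @param pairs Pair table from [derive_pairs()].
#' @param fc_cutoff Linear fold-change cutoff, default 1.5.
#' @return Long `data.frame`: one row per (pair, differential gene) with the
#'   pair metadata and `direction` (`"up"`/`"down"`). Pairs with no
#'   differential gene contribute no rows but remain countable through
#'   `pairs`.
#' @export
differential_table <- function(m, pairs, fc_cutoff = 1.5) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    de <- differential_genes(m, pairs[i, ], fc_cutoff)
    n_up <- length(de$up); n_dn <- length(de$down)
    if (n_up + n_dn == 0L) return(NULL)
    data.frame(pair_id = pairs$pair_id[i], kind = pairs$kind[i],
               patient_id = pairs$patient_id[i], dataset_id = pairs$dataset_id[i],
               gene_id = c(de$up, de$down),
               direction = rep(c("up", "down"), c(n_up, n_dn)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(pair_id = character(), kind = character(),
                      patient_id = character(), dataset_id = character(),
                      gene_id = character(), direction = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Cross-dataset consensus differential genes
#'
#' Combines per-pair human-vs-xeno differential calls across studies. A gene
#' counts for a patient if it is differential (either direction) in at least
#' one of that patient's human-vs-xeno pairs, and for a dataset if it is
#' differential in at least one of the dataset's human-vs-xeno pairs. A gene
#' is selected iff it is hit in at least `min_datasets` datasets AND in a
#' patient fraction strictly greater than `min_patient_fraction`; the
#' denominator is the number of patients contributing at least one
#' human-vs-xeno pair. Direction is ignored for membership but tallied.
#'
#' @param de Long differential table from [differential_table()].
#' @param pairs Pair table covering the same comparisons.
#' @param min_datasets Minimum datasets hit (default 3, i.e. "more than two").
#' @param min_patient_fraction Strict lower bound on the patient fraction
#'   (default 0.5, i.e. "more than half").
#' @return `data.frame` of selected genes with `n_datasets_hit`,
#'   `n_patients_hit`, `patient_fraction`, `n_up_pairs`, `n_down_pairs`,
#'   ordered by decreasing patient fraction; selection thresholds recorded as
#'   attributes `min_datasets`, `min_patient_fraction`, `n_patients_total`.
#' @export
consensus_genes <- function(de, pairs, min_datasets = 3L,
                            min_patient_fraction = 0.5) {
  hx_pairs <- pairs[pairs$kind == "human_vs_xeno", , drop = FALSE]
  if (!nrow(hx_pairs)) abort("no human-vs-xeno pairs; consensus undefined")
  patients <- unique(hx_pairs$patient_id)
  n_datasets_avail <- length(unique(hx_pairs$dataset_id))
  if (n_datasets_avail < min_datasets)
    abort("only %d dataset(s) contribute human-vs-xeno pairs; need >= %d",
          n_datasets_avail, min_datasets)
  dehx <- de[de$kind == "human_vs_xeno", , drop = FALSE]
  sel <- if (nrow(dehx)) {
    per_gene <- split(dehx, dehx$gene_id)
    stats <- lapply(per_gene, function(g) data.frame(
      gene_id = g$gene_id[1L],
      n_datasets_hit = length(unique(g$dataset_id)),
      n_patients_hit = length(unique(g$patient_id)),
      n_up_pairs = sum(g$direction == "up"),
      n_down_pairs = sum(g$direction == "down"),
      stringsAsFactors = FALSE))
    stats <- do.call(rbind, stats)
    stats$patient_fraction <- stats$n_patients_hit / length(patients)
    stats[stats$n_datasets_hit >= min_datasets &
            stats$patient_fraction > min_patient_fraction, , drop = FALSE]
  } else {
    data.frame(gene_id = character(), n_datasets_hit = integer(),
               n_patients_hit = integer(), n_up_pairs = integer(),
               n_down_pairs = integer(), patient_fraction = numeric(),
               stringsAsFactors = FALSE)
  }
  sel <- sel[order(-sel$patient_fraction, -sel$n_datasets_hit, sel$gene_id), ,
             drop = FALSE]
  rownames(sel) <- NULL
  structure(sel[, c("gene_id", "n_datasets_hit", "n_patients_hit",
                    "patient_fraction", "n_up_pairs", "n_down_pairs")],
            min_datasets = min_datasets,
            min_patient_fraction = min_patient_fraction,
            n_patients_total = length(patients))
}

#' Leave-one-dataset-out stability of the consensus
#'
#' Re-runs [consensus_genes()] with each dataset removed in turn, keeping the
#' selection thresholds fixed, and reports the genes surviving every removal.
#' A consensus dominated by one large study will shrink sharply when that
#' study is dropped; a stable consensus will not.
#'
#' @inheritParams consensus_genes
#' @return List with `per_drop` (named list: dropped dataset -> selected gene
#'   vector) and `intersection` (genes selected under every drop).
#' @export
leave_one_out <- function(de, pairs, min_datasets = 3L,
                          min_patient_fraction = 0.5) {
  hx <- pairs[pairs$kind == "human_vs_xeno", , drop = FALSE]
  datasets <- unique(hx$dataset_id)
  if (length(datasets) < 3L)
    abort("leave-one-out needs >= 3 datasets with human-vs-xeno pairs, found %d",
          length(datasets))
  per_drop <- lapply(datasets, function(d) {
    keep_pairs <- pairs[pairs$dataset_id != d, , drop = FALSE]
    keep_de <- de[de$dataset_id != d, , drop = FALSE]
    consensus_genes(keep_de, keep_pairs, min_datasets, min_patient_fraction)$gene_id
  })
  names(per_drop) <- datasets
  list(per_drop = per_drop, intersection = Reduce(intersect, per_drop))
}

#' Count gene-drug interactions for a gene set
#'
#' Joins a gene list against a gene-to-drug interaction map and tallies both
#' directions: how many drugs interact with each query gene, and how many
#' query genes each drug touches.
#'
#' @param genes Character vector of gene ids.
#' @param drug_map Named list from [read_drug_map()].
#' @return List of two `data.frame`s: `genes` (`gene_id`, `n_drugs`) and
#'   `drugs` (`drug_id`, `n_genes`, decreasing).
#' @export
count_interacting_drugs <- function(genes, drug_map) {
  genes <- unique(genes)
  n_drugs <- vapply(genes, function(g)
    length(drug_map[[g]] %||% character()), integer(1L))
  hit_drugs <- unlist(drug_map[intersect(genes, names(drug_map))],
                      use.names = FALSE)
  drugs <- if (length(hit_drugs)) {
    tab <- sort(table(hit_drugs), decreasing = TRUE)
    data.frame(drug_id = names(tab), n_genes = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(drug_id = character(), n_genes = integer(),
                    stringsAsFactors = FALSE)
  list(genes = data.frame(gene_id = genes, n_drugs = n_drugs,
                          row.names = NULL, stringsAsFactors = FALSE),
       drugs = drugs)
}
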