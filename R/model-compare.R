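# Comparison of a patient biopsy against three candidate model panels:
# the patient's own xenografts, a cell-line panel, and biopsies of other
# patients with the same cancer. Similarity = maximum Spearman correlation
# against any sample in the panel.

#' Harmonize a query matrix with reference panels
#'
#' Restricts every matrix to the common gene set and applies the joint
#' empirical-Bayes batch adjustment ([merge_and_batch_adjust()]) across
#' studies, then splits the merged matrix back into its components. By
#' default each input matrix is one batch.
#'
#' @param query [expression_matrix()] of query samples.
#' @param panels Named list of panel [expression_matrix()] objects.
#' @param batches Optional named vector `sample_id -> batch` overriding the
#'   one-batch-per-matrix default.
#' @return Named list of adjusted matrices: `query` plus one per panel, all
#'   on the common gene set.
#' @export
build_panels <- function(query, panels, batches = NULL) {
  stopifnot(is_expression_matrix(query), is.list(panels), length(panels) >= 1L)
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    abort("panels must be a named list")
  merged <- merge_and_batch_adjust(c(list(query = query), panels), batches)
  pieces <- c(list(query = query), panels)
  lapply(pieces, function(p) merged[, colnames(p), drop = FALSE])
}

#' Most similar panel sample for one query profile
#'
#' @param f0 Named numeric vector (gene -> value) or single-column
#'   [expression_matrix()]: the patient biopsy profile.
#' @param panel [expression_matrix()] sharing the query's gene order.
#' @return List with `sample_id`, `srcc` (the maximum Spearman correlation)
#'   and `n_ties` (panel samples within 1e-12 of the maximum; ties are broken
#'   by panel column order).
#' @export
best_match <- function(f0, panel) {
  stopifnot(is_expression_matrix(panel))
  if (is.matrix(f0)) {
    stopifnot(ncol(f0) == 1L)
    f0 <- setNames(as.numeric(unclass(f0)[, 1L]), rownames(f0))
  }
  if (!ncol(panel)) abort("empty reference panel")
  if (!identical(names(f0), rownames(panel)))
    abort("query and panel gene vectors differ; harmonize with build_panels()")
  srccs <- vapply(seq_len(ncol(panel)), function(j)
    safe_spearman(f0, unclass(panel)[, j]), numeric(1L))
  best <- which.max(srccs)
  list(sample_id = colnames(panel)[best], srcc = srccs[best],
       n_ties = sum(abs(srccs - srccs[best]) < 1e-12))
}

#' Compare patient biopsies against PDX, cell-line and other-patient panels
#'
#' For every patient with an F0 biopsy and at least one xenograft, finds the
#' most similar sample (maximum Spearman correlation) in each of three
#' panels: `pdx_self` (the patient's own xenograft samples), `cell_line`
#' (the full cell-line panel), and `other_patient` (F0 biopsies of *other*
#' patients with the same cancer type). The query patient's own samples are
#' never placed in the cell-line or other-patient panels, and the F0 sample
#' itself is never a candidate match.
#'
#' Cohort and cell-line matrices are first harmonized with
#' [build_panels()] (genes intersected, studies batch-adjusted; cohort
#' batches follow `dataset_id`).
#'
#' @param cohort Log2 [expression_matrix()] with all cohort samples.
#' @param ann Sample sheet for `cohort`.
#' @param cell_lines [expression_matrix()] of the cell-line panel.
#' @param adjust Apply batch adjustment before comparison (default `TRUE`).
#' @return Long `data.frame`: `patient_id`, `panel`, `best_sample`, `srcc` —
#'   one row per patient and available panel.
#' @export
compare_models <- function(cohort, ann, cell_lines, adjust = TRUE) {
  stopifnot(is_expression_matrix(cohort), is_expression_matrix(cell_lines))
  ann <- validate_sample_sheet(ann)
  if (adjust) {
    batches <- c(setNames(ann$dataset_id, ann$sample_id),
                 setNames(rep("cell_line", ncol(cell_lines)),
                          colnames(cell_lines)))
    harmonized <- build_panels(cohort, list(cell_line = cell_lines), batches)
    cohort <- harmonized$query; cell_lines <- harmonized$cell_line
  } else {
    genes <- intersect(rownames(cohort), rownames(cell_lines))
    if (!length(genes)) abort("cohort and cell-line gene sets are disjoint")
    cohort <- cohort[genes, ]; cell_lines <- cell_lines[genes, ]
  }
  rows <- list()
  for (pt in unique(ann$patient_id)) {
    s <- ann[ann$patient_id == pt, , drop = FALSE]
    f0_id <- s$sample_id[s$passage_label == "F0"][1L]
    xeno_ids <- s$sample_id[s$passage_label != "F0"]
    if (is.na(f0_id) || !length(xeno_ids)) next
    f0 <- setNames(unclass(cohort)[, f0_id], rownames(cohort))
    other_ids <- ann$sample_id[ann$passage_label == "F0" &
                                 ann$patient_id != pt &
                                 ann$cancer_type %in% s$cancer_type[1L]]
    panels <- list(pdx_self = cohort[, xeno_ids, drop = FALSE],
                   cell_line = cell_lines)
    if (length(other_ids))
      panels$other_patient <- cohort[, other_ids, drop = FALSE]
    for (lab in names(panels)) {
      bm <- best_match(f0, panels[[lab]])
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pt, panel = lab, best_sample = bm$sample_id,
        srcc = bm$srcc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    abort("no patient has both an F0 biopsy and a xenograft sample")
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
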