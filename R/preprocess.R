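# Normalization, transformation and probe collapse applied to expression
# matrices before any between-sample comparison.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share one empirical distribution — the
#' vector of row-wise means of the column-sorted matrix — while preserving
#' each sample's internal rank order. Tied values receive the mean of the
#' reference values they span. The heavy lifting is delegated to
#' `limma::normalizeQuantiles()`, the standard microarray implementation of
#' exactly this procedure.
#'
#' Quantile normalization is idempotent and, because it is rank-preserving
#' within each sample, leaves Spearman correlations between samples unchanged.
#'
#' @param m An [expression_matrix()]; no missing values (imputation is out of
#'   scope).
#' @return Quantile-normalized `expr_matrix`, same scale flag.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is_expression_matrix(m))
  if (ncol(m) == 1L) return(m)
  out <- limma::normalizeQuantiles(unclass(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  rewrap(out, m)
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param m A linear-scale [expression_matrix()]. Applying this to an already
#'   log2 matrix is refused (double-log guard).
#' @param offset Constant added before taking log2; every `value + offset`
#'   must be positive. Default 0.
#' @return `expr_matrix` on the log2 scale.
#' @export
log_transform <- function(m, offset = 0) {
  stopifnot(is_expression_matrix(m))
  if (expr_scale(m) != "linear")
    abort("matrix is already log2 scale; refusing to log-transform twice")
  shifted <- unclass(m) + offset
  if (any(shifted <= 0)) {
    idx <- which(shifted <= 0, arr.ind = TRUE)
    cells <- apply(head(idx, 5L), 1L, function(rc)
      sprintf("%s/%s", rownames(m)[rc[1L]], colnames(m)[rc[2L]]))
    abort("log2 undefined for %d cell(s) with value + offset <= 0 (e.g. %s)",
          nrow(idx), paste(cells, collapse = ", "))
  }
  rewrap(log2(shifted), m, scale = "log2")
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarray platforms measure a gene through one or more probes; the gene's
#' expression value is taken as the median of its probes' values, sample by
#' sample. Gene order in the output follows first appearance of each gene
#' among the probe rows.
#'
#' @param m Probe-level [expression_matrix()] (duplicate row ids permitted).
#' @param probe_map Either a named character vector (`probe_id -> gene_id`) or
#'   a `data.frame` with columns `probe_id`, `gene_id`. Every probe row of `m`
#'   must be mapped.
#' @return Gene-level `expr_matrix`.
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(is_expression_matrix(m))
  if (is.data.frame(probe_map)) {
    stopifnot(all(c("probe_id", "gene_id") %in% colnames(probe_map)))
    probe_map <- setNames(as.character(probe_map$gene_id),
                          as.character(probe_map$probe_id))
  }
  probes <- rownames(m)
  unmapped <- setdiff(probes, names(probe_map))
  if (length(unmapped))
    abort("probe(s) missing from probe map: %s",
          paste(head(unmapped, 5L), collapse = ", "))
  gene_of_row <- unname(probe_map[probes])
  genes <- unique(gene_of_row)            # first-appearance order
  vals <- unclass(m)
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  rows_by_gene <- split(seq_along(gene_of_row), factor(gene_of_row, levels = genes))
  for (g in seq_along(genes)) {
    idx <- rows_by_gene[[g]]
    out[g, ] <- if (length(idx) == 1L) vals[idx, ] else
      apply(vals[idx, , drop = FALSE], 2L, median)
  }
  expression_matrix(out, scale = expr_scale(m))
}

#' Merge studies on their common genes and remove batch effects
#'
#' Restricts all matrices to the intersection of their gene ids, binds the
#' samples, then applies the empirical-Bayes location/scale batch adjustment
#' of [batch_adjust()] so that between-study shifts do not masquerade as
#' biology. The gene set is never changed beyond the intersection and the
#' sample count is conserved.
#'
#' @param ms List of [expression_matrix()] objects (>= 2) on a common scale.
#' @param batches Named character vector `sample_id -> batch id` covering
#'   every sample; by default each input matrix is its own batch.
#' @return Merged, batch-adjusted `expr_matrix`.
#' @export
merge_and_batch_adjust <- function(ms, batches = NULL) {
  if (length(ms) < 2L) abort("need at least two matrices to merge")
  stopifnot(all(vapply(ms, is_expression_matrix, logical(1L))))
  scales <- vapply(ms, expr_scale, character(1L))
  if (length(unique(scales)) > 1L)
    abort("matrices mix linear and log2 scales; transform before merging")
  genes <- Reduce(intersect, lapply(ms, rownames))
  if (!length(genes)) abort("gene-id intersection across matrices is empty")
  merged <- do.call(cbind, lapply(ms, function(m) unclass(m)[genes, , drop = FALSE]))
  if (anyDuplicated(colnames(merged)))
    abort("sample ids collide across matrices: %s",
          colnames(merged)[duplicated(colnames(merged))][1L])
  if (is.null(batches)) {
    batches <- rep(sprintf("batch%02d", seq_along(ms)),
                   vapply(ms, ncol, integer(1L)))
    names(batches) <- colnames(merged)
  }
  missing_lab <- setdiff(colnames(merged), names(batches))
  if (length(missing_lab))
    abort("sample(s) without batch label: %s", paste(head(missing_lab, 5L), collapse = ", "))
  merged <- expression_matrix(merged, scale = scales[1L])
  batch_adjust(merged, batches[colnames(merged)])
}
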