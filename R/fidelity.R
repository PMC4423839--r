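# Patient/xenograft comparison pairs, Spearman correlation of expression
# profiles, the mean - k*SD outlier rule, and the rank-sum comparison of the
# two pair groups.

#' Derive comparison pairs from a sample sheet
#'
#' Two kinds of pairs drive the fidelity analysis: `human_vs_xeno` (biopsy F0
#' against a xenograft of the same patient — the engraftment step) and
#' `xeno_vs_xeno` (consecutive available passages of the same patient — the
#' passaging steps). The default policy pairs each patient's F0 with every
#' xenograft sample of that patient, and pairs xenografts at adjacent
#' available numeric passages; `F?` samples (unknown generation) pair only
#' with F0. In every pair `sample_a` is the reference side — the biopsy, or
#' the earlier passage.
#'
#' Real cohorts are often matched by hand from sample descriptions; an
#' explicit pair table (`sample_a`, `sample_b`) overrides derivation and is
#' only validated and oriented.
#'
#' @param ann Sample sheet `data.frame` (see [read_sample_sheet()]).
#' @param pairs Optional explicit pair `data.frame` with columns `sample_a`,
#'   `sample_b`; both samples must share a patient.
#' @return `data.frame` with columns `pair_id`, `sample_a`, `sample_b`,
#'   `kind`, `patient_id`, `dataset_id`.
#' @export
derive_pairs <- function(ann, pairs = NULL) {
  ann <- validate_sample_sheet(ann)
  if (!is.null(pairs)) return(orient_pairs(pairs, ann))
  out <- list()
  for (pt in unique(ann$patient_id)) {
    s <- ann[ann$patient_id == pt, , drop = FALSE]
    f0 <- s$sample_id[s$passage_label == "F0"]
    xeno <- s[s$passage_label != "F0", , drop = FALSE]
    if (!length(f0)) {
      if (nrow(xeno) > 1L)
        warning(sprintf("patient '%s' has no F0 biopsy; only xeno-vs-xeno pairs derived", pt),
                call. = FALSE)
      else
        warning(sprintf("patient '%s' has no F0 biopsy; skipped", pt), call. = FALSE)
    } else {
      for (a in f0) for (b in xeno$sample_id)
        out[[length(out) + 1L]] <- data.frame(
          sample_a = a, sample_b = b, kind = "human_vs_xeno",
          patient_id = pt, dataset_id = s$dataset_id[1L],
          stringsAsFactors = FALSE)
    }
    # consecutive available numeric passages
    numeric_x <- xeno[xeno$passage_label != "F?", , drop = FALSE]
    if (nrow(numeric_x)) {
      lev <- sort(unique(as.integer(sub("^F", "", numeric_x$passage_label))))
      if (length(lev) > 1L) for (k in seq_len(length(lev) - 1L)) {
        sa <- numeric_x$sample_id[numeric_x$passage_label == paste0("F", lev[k])]
        sb <- numeric_x$sample_id[numeric_x$passage_label == paste0("F", lev[k + 1L])]
        for (a in sa) for (b in sb)
          out[[length(out) + 1L]] <- data.frame(
            sample_a = a, sample_b = b, kind = "xeno_vs_xeno",
            patient_id = pt, dataset_id = s$dataset_id[1L],
            stringsAsFactors = FALSE)
      }
    }
  }
  finish_pairs(if (length(out)) do.call(rbind, out) else empty_pairs())
}

empty_pairs <- function() {
  data.frame(pair_id = character(), sample_a = character(),
             sample_b = character(), kind = character(),
             patient_id = character(), dataset_id = character(),
             stringsAsFactors = FALSE)
}

finish_pairs <- function(p) {
  if (nrow(p)) p$pair_id <- paste(p$sample_a, p$sample_b, sep = "|")
  else p$pair_id <- character()
  rownames(p) <- NULL
  p[, c("pair_id", "sample_a", "sample_b", "kind", "patient_id", "dataset_id")]
}

passage_rank <- function(label) {
  # F0 < F1 < ... ; F? sorts last (it can only partner F0, staying sample_b)
  r <- rep(Inf, length(label))
  num <- label != "F?"
  r[num] <- as.numeric(sub("^F", "", label[num]))
  r
}

orient_pairs <- function(pairs, ann) {
  stopifnot(all(c("sample_a", "sample_b") %in% colnames(pairs)))
  idx_a <- match(pairs$sample_a, ann$sample_id)
  idx_b <- match(pairs$sample_b, ann$sample_id)
  if (anyNA(idx_a) || anyNA(idx_b))
    abort("pair sample(s) absent from sample sheet: %s",
          paste(head(setdiff(c(pairs$sample_a, pairs$sample_b), ann$sample_id), 5L),
                collapse = ", "))
  if (any(ann$patient_id[idx_a] != ann$patient_id[idx_b]))
    abort("pair (%s, %s) spans two patients",
          pairs$sample_a[which(ann$patient_id[idx_a] != ann$patient_id[idx_b])[1L]],
          pairs$sample_b[which(ann$patient_id[idx_a] != ann$patient_id[idx_b])[1L]])
  lab_a <- ann$passage_label[idx_a]; lab_b <- ann$passage_label[idx_b]
  flip <- passage_rank(lab_a) > passage_rank(lab_b)
  sample_a <- ifelse(flip, pairs$sample_b, pairs$sample_a)
  sample_b <- ifelse(flip, pairs$sample_a, pairs$sample_b)
  kind <- ifelse(xor(lab_a == "F0", lab_b == "F0"), "human_vs_xeno", "xeno_vs_xeno")
  if (any(lab_a == "F0" & lab_b == "F0"))
    abort("pair of two F0 biopsies is neither human-vs-xeno nor xeno-vs-xeno")
  finish_pairs(data.frame(sample_a = sample_a, sample_b = sample_b, kind = kind,
                          patient_id = ann$patient_id[idx_a],
                          dataset_id = ann$dataset_id[idx_a],
                          stringsAsFactors = FALSE))
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of average ranks (ties receive their average rank).
#' Degenerate input — fewer than 3 values, non-finite values, or a constant
#' vector whose ranks carry no information — is an error, never a silent 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A correlation in `[-1, 1]`.
#' @examples
#' spearman_rcc(c(1, 2, 2, 3), c(1, 3, 2, 4))  # 0.9487
#' @export
spearman_rcc <- function(x, y) safe_spearman(x, y)

#' Correlate expression profiles over comparison pairs
#'
#' One Spearman correlation per pair, computed over the full shared gene
#' vector of the matrix.
#'
#' @param m An [expression_matrix()] containing every paired sample.
#' @param pairs Pair table from [derive_pairs()].
#' @return `data.frame`: pair columns plus `srcc`. Summarize with
#'   [correlation_summary()].
#' @export
pair_correlations <- function(m, pairs) {
  stopifnot(is_expression_matrix(m))
  missing_s <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)), colnames(m))
  if (length(missing_s))
    abort("pair sample(s) missing from expression matrix: %s",
          paste(head(missing_s, 5L), collapse = ", "))
  pairs$srcc <- vapply(seq_len(nrow(pairs)), function(i)
    safe_spearman(unclass(m)[, pairs$sample_a[i]], unclass(m)[, pairs$sample_b[i]]),
    numeric(1L))
  pairs
}

#' Summarize a correlation table
#'
#' @param tbl Output of [pair_correlations()], optionally filtered.
#' @return One-row `data.frame` with `n`, `mean`, `median`, `sd`; all-`NA`
#'   statistics (with `n = 0`) for an empty table.
#' @export
correlation_summary <- function(tbl) {
  if (!nrow(tbl))
    return(data.frame(n = 0L, mean = NA_real_, median = NA_real_, sd = NA_real_))
  data.frame(n = nrow(tbl), mean = mean(tbl$srcc), median = median(tbl$srcc),
             sd = sd(tbl$srcc))
}

#' Outlier threshold for pair correlations
#'
#' `mean - k * SD` of the observed correlations, with the sample (n-1)
#' standard deviation. Pairs strictly below the threshold are regarded as
#' low-quality outliers and excluded from downstream analysis. The threshold
#' is computed once over all pairs — flagged pairs are not removed and the
#' rule re-applied.
#'
#' @param srccs Numeric vector of at least 2 correlations.
#' @param k Multiplier on the standard deviation; default 1.5.
#' @return The threshold value.
#' @examples
#' # a printed summary of mean 0.91, sd 0.10 gives threshold 0.76
#' outlier_threshold(0.91 + c(-1, 1) * 0.10 / sqrt(2))
#' @export
outlier_threshold <- function(srccs, k = 1.5) {
  if (length(srccs) < 2L) abort("need >= 2 correlations to set a threshold")
  mean(srccs) - k * sd(srccs)
}

#' @rdname outlier_threshold
#' @param tbl Correlation table from [pair_correlations()].
#' @param threshold Numeric threshold (e.g. from `outlier_threshold()`).
#' @return `flag_outliers()`: the table with a logical `outlier` column,
#'   `TRUE` iff `srcc < threshold` (strict).
#' @export
flag_outliers <- function(tbl, threshold) {
  tbl$outlier <- tbl$srcc < threshold
  tbl
}

#' Compare correlation distributions of the two pair groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of human-vs-xeno against
#' xeno-vs-xeno correlations. The exact null distribution is enumerated when
#' the combined sample size is at most 20 and the data are tie-free;
#' otherwise the normal approximation with tie correction is used. Groups
#' with fewer than 2 values trigger a warning and force the exact test (the
#' approximation is refused at such sizes).
#'
#' @param srccs_hx,srccs_xx Numeric vectors of correlations, both nonempty.
#' @return An `htest` object.
#' @export
compare_pair_groups <- function(srccs_hx, srccs_xx) {
  if (!length(srccs_hx) || !length(srccs_xx))
    abort("both pair groups must be nonempty")
  n_total <- length(srccs_hx) + length(srccs_xx)
  exact <- n_total <= 20L
  if (min(length(srccs_hx), length(srccs_xx)) < 2L) {
    warning("a group has < 2 values; normal approximation refused, exact test used",
            call. = FALSE)
    exact <- TRUE
  }
  has_ties <- anyDuplicated(c(srccs_hx, srccs_xx)) > 0L
  suppressWarnings(
    wilcox.test(srccs_hx, srccs_xx, alternative = "two.sided",
                exact = exact && !has_ties, correct = TRUE)
  )
}
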