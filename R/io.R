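# Readers and writers for the tabular formats the pipeline touches:
# TSV expression matrices, TSV sample sheets, GMT gene sets, TSV gene-drug
# maps and TSV IC50 tables. All files are UTF-8, tab-delimited, "." decimal.
# Readers validate and reject rather than silently coerce; every writer's
# output is parsed back identically by its paired reader.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols))
    abort("%s file %s lacks required column(s): %s", what, path,
          paste(missing_cols, collapse = ", "))
  df
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids with a leading gene-id column (any
#' name), one gene (or probe) per row. Duplicate row ids are only accepted at
#' probe level (`allow_duplicate_ids = TRUE`), flagging the matrix for
#' [collapse_probes()].
#'
#' Public repositories serve series matrices in their own envelope formats;
#' export those to plain TSV first — retrieval and platform annotation parsing
#' are out of scope here.
#'
#' @param path TSV file path.
#' @param scale Scale of the stored values, `"linear"` (default) or `"log2"`.
#' @param allow_duplicate_ids Accept duplicated row ids (probe-level data).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2"),
                                   allow_duplicate_ids = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(path)) abort("expression file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "")
  if (ncol(df) < 2L)
    abort("expression file %s needs a gene-id column plus >=1 sample column", path)
  sample_ids <- colnames(df)[-1L]
  # a file without a header leaves its first data row as column names:
  # sample ids that all parse as numbers betray that
  if (all(!is.na(suppressWarnings(as.numeric(sample_ids)))))
    abort("expression file %s appears to lack a header row of sample ids", path)
  gene_ids <- df[[1L]]
  vals <- matrix(NA_real_, nrow(df), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(col) & !(df[[j + 1L]] %in% c("NA", "")))
    if (length(bad))
      abort("non-numeric value '%s' at row %d, column '%s' of %s",
            df[[j + 1L]][bad[1L]], bad[1L], sample_ids[j], path)
    if (anyNA(col))
      abort("missing value at row %d, column '%s' of %s",
            which(is.na(col))[1L], sample_ids[j], path)
    vals[, j] <- col
  }
  expression_matrix(vals, scale = scale, allow_duplicate_ids = allow_duplicate_ids)
}

#' Write an expression matrix as TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is_expression_matrix(m))
  df <- data.frame(gene_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

passage_pattern <- "^F([0-9]+|\\?)$"

#' Read a sample sheet
#'
#' Sample metadata for a PDX cohort: which patient each array came from, which
#' study, and the passage generation. `F0` is the patient biopsy, `F1` the
#' first xenograft passage and so on; `F?` marks a xenograft of unknown
#' generation. Any other passage label is rejected.
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `dataset_id`,
#'   `passage_label`; optional `cancer_type` and logical `is_outlier`.
#' @return A validated `data.frame`, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "patient_id", "dataset_id",
                                 "passage_label"), "sample sheet")
  if (!("cancer_type" %in% colnames(df))) df$cancer_type <- NA_character_
  if (!("is_outlier" %in% colnames(df))) df$is_outlier <- FALSE
  df$is_outlier <- as.logical(df$is_outlier)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample_id in sample sheet: %s",
          df$sample_id[duplicated(df$sample_id)][1L])
  bad <- !grepl(passage_pattern, df$passage_label)
  if (any(bad))
    abort("invalid passage label '%s' for sample '%s' (expected F<digits> or F?)",
          df$passage_label[bad][1L], df$sample_id[bad][1L])
  df
}

#' Write a sample sheet as TSV
#'
#' @param ann Sample annotation `data.frame` (see [read_sample_sheet()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One term per line: term id, description, then member gene ids, all
#' tab-separated. Genes are deduplicated within a term.
#'
#' @param path GMT file.
#' @return Named list of character vectors (term id -> gene ids) with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      abort("GMT line %d has %d field(s); need term, description and >=1 gene",
            i, length(f))
    term <- f[1L]
    if (term %in% names(sets)) abort("duplicate term id '%s' at GMT line %d", term, i)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) abort("GMT line %d (term '%s') has no genes", i, term)
    sets[[term]] <- genes
    desc[term] <- f[2L]
  }
  structure(sets, descriptions = desc)
}

#' Write gene sets as GMT
#'
#' @param sets Named list of gene-id vectors; an optional `descriptions`
#'   attribute supplies the second GMT field (defaults to the term id).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(term) {
    paste(c(term, desc[[term]] %||% term, sets[[term]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-to-drug interaction table
#'
#' Local, file-based replacement for online drug-interaction lookups: a TSV
#' with columns `gene_id`, `drug_id`, one interaction per row. Duplicated rows
#' collapse to one interaction.
#'
#' @param path TSV file.
#' @return Named list mapping each gene id to its character vector of drugs.
#' @export
read_drug_map <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "drug_id"), "drug map")
  bad <- which(!nzchar(df$gene_id) | !nzchar(df$drug_id) |
                 is.na(df$gene_id) | is.na(df$drug_id))
  if (length(bad))
    abort("malformed drug-map entry at data line %d of %s", bad[1L], path)
  if (!nrow(df)) return(structure(list(), names = character()))
  lapply(split(df$drug_id, df$gene_id), function(d) sort(unique(d)))
}

#' Read a drug-response (log IC50) table
#'
#' @param path TSV with columns `cell_line`, `log_ic50`.
#' @return `data.frame` with one row per cell line.
#' @export
read_ic50 <- function(path) {
  df <- read_tsv_checked(path, c("cell_line", "log_ic50"), "IC50")
  df$log_ic50 <- suppressWarnings(as.numeric(df$log_ic50))
  if (anyNA(df$log_ic50))
    abort("non-numeric log_ic50 at data line %d of %s",
          which(is.na(df$log_ic50))[1L], path)
  if (anyDuplicated(df$cell_line))
    abort("duplicate cell_line in %s: %s", path,
          df$cell_line[duplicated(df$cell_line)][1L])
  df
}

#' Write a drug-response table as TSV
#'
#' @param ic50 `data.frame` with columns `cell_line`, `log_ic50`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ic50 <- function(ic50, path) {
  utils::write.table(format(ic50, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
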