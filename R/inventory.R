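# Cohort bookkeeping: a published-style per-dataset inventory (patients and
# manually matched pair counts per study) can be expanded into a concrete
# sample sheet plus explicit pair list, and any annotation/pair combination
# can be re-counted.

#' Per-dataset PDX cohort inventory
#'
#' Reads a cohort inventory table: one row per expression dataset with its
#' cancer type, number of patients, number of human-vs-xeno and
#' xeno-vs-xeno pairs, and maximum PDX passage (`?` if unknown). The packaged
#' default (`inst/extdata/geo_inventory.tsv`) describes a nine-study,
#' eight-cancer public PDX cohort of 58 patients.
#'
#' @param path Inventory TSV; defaults to the packaged cohort inventory.
#' @return `data.frame` with columns `dataset_id`, `cancer_type`,
#'   `n_patients`, `n_pairs_human_vs_xeno`, `n_pairs_xeno_vs_xeno`,
#'   `max_passage`.
#' @export
pdx_inventory <- function(path = system.file("extdata", "geo_inventory.tsv",
                                             package = "pdxfidelity")) {
  df <- read_tsv_checked(path, c("dataset_id", "cancer_type", "n_patients",
                                 "n_pairs_human_vs_xeno", "n_pairs_xeno_vs_xeno",
                                 "max_passage"), "inventory")
  for (col in c("n_patients", "n_pairs_human_vs_xeno", "n_pairs_xeno_vs_xeno"))
    df[[col]] <- as.integer(df[[col]])
  df
}

#' Expand an inventory into a sample sheet and explicit pair list
#'
#' Constructs a minimal concrete cohort consistent with the per-dataset
#' counts: every patient receives an F0 biopsy; human-vs-xeno pairs are
#' distributed round-robin over the dataset's patients, each adding one
#' xenograft sample; xeno-vs-xeno pairs extend a patient's passage chain by
#' one sample paired with its predecessor. Datasets whose maximum passage is
#' unknown (`?`) receive `F?` xenografts. Pair counts, patient counts and
#' dataset counts of the expansion reproduce the inventory exactly (sample
#' identities are of course synthetic).
#'
#' @param inv Inventory `data.frame` from [pdx_inventory()].
#' @return List with elements `annotation` (sample sheet) and `pairs`
#'   (explicit pair table as accepted by [derive_pairs()]).
#' @export
expand_inventory <- function(inv) {
  ann <- list(); prs <- list()
  for (i in seq_len(nrow(inv))) {
    ds <- inv$dataset_id[i]
    unknown <- inv$max_passage[i] == "?"
    pts <- sprintf("%s_pt%02d", ds, seq_len(inv$n_patients[i]))
    next_passage <- setNames(rep(1L, length(pts)), pts)
    n_unknown <- setNames(rep(0L, length(pts)), pts)
    add_sample <- function(pt, label, id) {
      ann[[length(ann) + 1L]] <<- data.frame(
        sample_id = id, patient_id = pt, dataset_id = ds,
        passage_label = label, cancer_type = inv$cancer_type[i],
        is_outlier = FALSE, stringsAsFactors = FALSE)
      id
    }
    f0 <- setNames(vapply(pts, function(pt)
      add_sample(pt, "F0", paste0(pt, "_F0")), character(1L)), pts)
    new_xeno <- function(pt) {
      if (unknown) {
        n_unknown[pt] <<- n_unknown[pt] + 1L
        add_sample(pt, "F?", sprintf("%s_Fu%d", pt, n_unknown[pt]))
      } else {
        k <- next_passage[pt]; next_passage[pt] <<- k + 1L
        add_sample(pt, paste0("F", k), sprintf("%s_F%d", pt, k))
      }
    }
    last_xeno <- setNames(rep(NA_character_, length(pts)), pts)
    for (j in seq_len(inv$n_pairs_human_vs_xeno[i])) {
      pt <- pts[(j - 1L) %% length(pts) + 1L]
      sb <- new_xeno(pt)
      if (!unknown) last_xeno[pt] <- sb
      prs[[length(prs) + 1L]] <- data.frame(sample_a = f0[pt], sample_b = sb,
                                            stringsAsFactors = FALSE)
    }
    for (j in seq_len(inv$n_pairs_xeno_vs_xeno[i])) {
      pt <- pts[(j - 1L) %% length(pts) + 1L]
      if (is.na(last_xeno[pt])) last_xeno[pt] <- new_xeno(pt)
      sa <- last_xeno[pt]; sb <- new_xeno(pt)
      last_xeno[pt] <- sb
      prs[[length(prs) + 1L]] <- data.frame(sample_a = sa, sample_b = sb,
                                            stringsAsFactors = FALSE)
    }
  }
  annotation <- do.call(rbind, ann); rownames(annotation) <- NULL
  pairs <- derive_pairs(annotation,
                        pairs = do.call(rbind, prs))
  list(annotation = annotation, pairs = pairs)
}

#' Count patients, samples and comparison pairs in a cohort
#'
#' @param ann Sample sheet `data.frame`.
#' @param pairs Pair table from [derive_pairs()].
#' @return One-row `data.frame`: `n_datasets`, `n_patients`, `n_samples`,
#'   `n_pairs_human_vs_xeno`, `n_pairs_xeno_vs_xeno`, `n_pairs_total`.
#' @export
cohort_summary <- function(ann, pairs) {
  data.frame(
    n_datasets = length(unique(ann$dataset_id)),
    n_patients = length(unique(ann$patient_id)),
    n_samples = nrow(ann),
    n_pairs_human_vs_xeno = sum(pairs$kind == "human_vs_xeno"),
    n_pairs_xeno_vs_xeno = sum(pairs$kind == "xeno_vs_xeno"),
    n_pairs_total = nrow(pairs))
}
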