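# Synthetic data with ground truth: PDX cohorts whose expression shift is
# concentrated in the engraftment step, and cell-line panels whose log IC50
# is a sparse linear function of expression. These generators define the
# study conditions for every parameter-recovery and ordering test in the
# package.

#' Configure a synthetic PDX cohort
#'
#' The generative model mirrors what the fidelity analysis assumes about real
#' cohorts, on the log2 scale throughout:
#'
#' * gene baselines `mu_g ~ Normal(8, 2)` log2 units; each patient adds a
#'   per-gene effect `~ Normal(0, 0.5)`;
#' * every sample is its latent profile plus per-gene measurement noise
#'   `Normal(0, sample_noise_sd)`;
#' * the engraftment step (F0 -> F1) shifts a planted fraction of genes by at
#'   least `engraftment_effect_log2` in absolute value, with 80% of planted
#'   genes shifted down (stromal/immune transcripts lost on engraftment
#'   outnumber gains);
#' * later passages drift by `Normal(0, passage_drift_sd)` per gene and
#'   passage, small relative to the engraftment shift so the F0->F1 change
#'   exceeds the Fk->Fk+1 change;
#' * a fraction of samples are low-quality outliers with extra
#'   `Normal(0, outlier_noise_sd)` noise;
#' * patients are spread round-robin over `n_datasets` studies, one cancer
#'   type per study.
#'
#' @param n_patients Number of patients (default 20).
#' @param n_genes Number of genes (>= 10; default 2000).
#' @param passages_per_patient Integer vector, one entry per patient: the
#'   last passage generated for that patient (default 2, i.e. F1 and F2).
#' @param engraftment_gene_fraction Fraction of genes carrying the
#'   engraftment shift (default 0.05).
#' @param engraftment_effect_log2 Minimum absolute engraftment shift in log2
#'   units (default 1, a two-fold change).
#' @param passage_drift_sd Per-passage drift SD (default 0.1); must stay
#'   below the engraftment effect.
#' @param sample_noise_sd Per-sample measurement noise SD (default 0.2).
#' @param outlier_fraction Fraction of samples made low-quality
#'   (default 0.05).
#' @param outlier_noise_sd Extra noise SD for outlier samples (default 1).
#' @param n_datasets Number of studies the patients are split over
#'   (default 5).
#' @param seed Master seed (default 1); the cohort draws from a named
#'   substream of it.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L, n_genes = 2000L,
                          passages_per_patient = NULL,
                          engraftment_gene_fraction = 0.05,
                          engraftment_effect_log2 = 1,
                          passage_drift_sd = 0.1, sample_noise_sd = 0.2,
                          outlier_fraction = 0.05, outlier_noise_sd = 1,
                          n_datasets = 5L, seed = 1L) {
  if (is.null(passages_per_patient))
    passages_per_patient <- rep(2L, n_patients)
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              passages_per_patient = as.integer(passages_per_patient),
              engraftment_gene_fraction = engraftment_gene_fraction,
              engraftment_effect_log2 = engraftment_effect_log2,
              passage_drift_sd = passage_drift_sd,
              sample_noise_sd = sample_noise_sd,
              outlier_fraction = outlier_fraction,
              outlier_noise_sd = outlier_noise_sd,
              n_datasets = as.integer(n_datasets),
              seed = as.integer(seed))
  if (cfg$n_genes < 10L) abort("n_genes must be >= 10")
  if (cfg$n_patients < 1L) abort("n_patients must be >= 1")
  if (length(cfg$passages_per_patient) != cfg$n_patients)
    abort("passages_per_patient has length %d but n_patients is %d",
          length(cfg$passages_per_patient), cfg$n_patients)
  if (any(cfg$passages_per_patient < 1L))
    abort("every patient needs at least one passage")
  for (f in c("engraftment_gene_fraction", "outlier_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort("%s must be in [0, 1]", f)
  for (f in c("passage_drift_sd", "sample_noise_sd"))
    if (cfg[[f]] < 0) abort("%s must be >= 0", f)
  if (cfg$engraftment_effect_log2 <= 0) abort("engraftment_effect_log2 must be > 0")
  if (cfg$outlier_noise_sd <= 0) abort("outlier_noise_sd must be > 0")
  if (cfg$passage_drift_sd >= cfg$engraftment_effect_log2)
    abort("passage_drift_sd must stay below engraftment_effect_log2")
  if (cfg$n_datasets < 1L || cfg$n_datasets > cfg$n_patients)
    abort("n_datasets must be between 1 and n_patients")
  structure(cfg, class = "cohort_config")
}

cancer_type_pool <- c("hepatocellular", "colorectal", "breast",
                      "pancreatic", "lung", "head_and_neck", "leukaemia",
                      "adenoid_cystic")

#' Generate a synthetic PDX cohort with ground truth
#'
#' Draws a cohort from the model described in [cohort_config()]. Ground
#' truth — the planted engraftment genes with their signed shifts, and the
#' identities of outlier samples — is returned alongside, enabling
#' parameter-recovery tests of the consensus-gene procedure.
#'
#' Deterministic: the same config (including seed) yields bit-identical
#' output.
#'
#' @param config A [cohort_config()].
#' @return List with `expr` (log2 [expression_matrix()]), `annotation`
#'   (sample sheet `data.frame`) and `truth` (list: `engraftment_genes`,
#'   `per_gene_shift` named over all genes, `outlier_samples`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  mu <- rnorm(config$n_genes, 8, 2)

  n_shift <- round(config$engraftment_gene_fraction * config$n_genes)
  shift <- setNames(rep(0, config$n_genes), genes)
  planted <- character()
  if (n_shift > 0L) {
    planted <- sample(genes, n_shift)
    sgn <- ifelse(runif(n_shift) < 0.8, -1, 1)
    mag <- config$engraftment_effect_log2 +
      abs(rnorm(n_shift, 0, config$engraftment_effect_log2 / 4))
    shift[planted] <- sgn * mag
  }

  patients <- sprintf("p%03d", seq_len(config$n_patients))
  dataset <- sprintf("d%d", (seq_len(config$n_patients) - 1L) %% config$n_datasets + 1L)
  cancer <- rep_len(cancer_type_pool, config$n_datasets)[
    (seq_len(config$n_patients) - 1L) %% config$n_datasets + 1L]

  cols <- list(); meta <- list()
  for (i in seq_len(config$n_patients)) {
    base <- mu + rnorm(config$n_genes, 0, 0.5)
    add <- function(label, latent) {
      smp <- latent + rnorm(config$n_genes, 0, config$sample_noise_sd)
      id <- sprintf("%s_%s", patients[i], label)
      cols[[id]] <<- smp
      meta[[id]] <<- data.frame(sample_id = id, patient_id = patients[i],
                                dataset_id = dataset[i],
                                passage_label = label,
                                cancer_type = cancer[i], is_outlier = FALSE,
                                stringsAsFactors = FALSE)
    }
    add("F0", base)
    latent <- base + shift
    add("F1", latent)
    k <- 2L
    while (k <= config$passages_per_patient[i]) {
      latent <- latent + rnorm(config$n_genes, 0, config$passage_drift_sd)
      add(sprintf("F%d", k), latent)
      k <- k + 1L
    }
  }
  ann <- do.call(rbind, meta); rownames(ann) <- NULL
  vals <- do.call(cbind, cols)
  rownames(vals) <- genes

  out_flags <- runif(ncol(vals)) < config$outlier_fraction
  if (any(out_flags))
    vals[, out_flags] <- vals[, out_flags, drop = FALSE] +
      matrix(rnorm(config$n_genes * sum(out_flags), 0, config$outlier_noise_sd),
             config$n_genes)
  ann$is_outlier <- out_flags

  list(expr = expression_matrix(vals, scale = "log2"),
       annotation = ann,
       truth = list(engraftment_genes = planted,
                    per_gene_shift = shift,
                    outlier_samples = ann$sample_id[out_flags]))
}

#' Generate a synthetic cell-line drug-response panel
#'
#' Expression is drawn per gene around a gene-specific baseline
#' (`Normal(8, 2)` mean, unit SD across lines, log2 scale); log IC50 is a
#' sparse linear function of the `n_causal` causal genes' expression plus
#' `Normal(0, noise_sd)` noise. With `noise_sd = 0` the response is exactly
#' linear; with `n_causal = 0` it is pure noise and no predictor should beat
#' chance.
#'
#' @param n_lines Number of cell lines (default 200).
#' @param n_genes Number of genes (default 500).
#' @param n_causal Number of causal genes (default 20; `<= n_genes`).
#' @param noise_sd Response noise SD (default 0.5).
#' @param seed Master seed; the panel draws from a named substream.
#' @return List with `expr` (log2 [expression_matrix()]), `ic50`
#'   (`data.frame`: `cell_line`, `log_ic50`) and `truth` (list:
#'   `causal_genes`, `coefficients` named over all genes and nonzero exactly
#'   on the causal ones, `noise_sd`).
#' @export
generate_cellline_panel <- function(n_lines = 200L, n_genes = 500L,
                                    n_causal = 20L, noise_sd = 0.5,
                                    seed = 1L) {
  if (n_causal > n_genes) abort("n_causal (%d) exceeds n_genes (%d)", n_causal, n_genes)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  set.seed(substream_seed(seed, "panel"))
  genes <- sprintf("g%04d", seq_len(n_genes))
  lines <- sprintf("cl%03d", seq_len(n_lines))
  mu <- rnorm(n_genes, 8, 2)
  vals <- mu + matrix(rnorm(n_genes * n_lines), n_genes, n_lines,
                      dimnames = list(genes, lines))
  beta <- setNames(rep(0, n_genes), genes)
  causal <- character()
  if (n_causal > 0L) {
    causal <- sample(genes, n_causal)
    beta[causal] <- rnorm(n_causal)
  }
  y <- c(crossprod(vals, beta)) + rnorm(n_lines, 0, noise_sd)
  list(expr = expression_matrix(vals, scale = "log2"),
       ic50 = data.frame(cell_line = lines, log_ic50 = y,
                         stringsAsFactors = FALSE),
       truth = list(causal_genes = causal, coefficients = beta,
                    noise_sd = noise_sd))
}

#' Generate gene sets around a planted engraftment set
#'
#' Builds an annotation in which exactly one term equals the cohort's planted
#' engraftment gene set and the remaining terms are random decoys of the same
#' size drawn from the gene universe — a fixture for enrichment and
#' robustness tests. Writable as GMT with [write_gene_sets()]; the same seed
#' reproduces identical output byte for byte.
#'
#' @param truth `truth` element of [generate_cohort()].
#' @param n_decoy_terms Number of random decoy terms (default 20).
#' @param term_size Genes per decoy term; defaults to the planted set size.
#' @param seed Master seed; gene sets draw from a named substream.
#' @return Named list of gene sets with a `descriptions` attribute; the
#'   planted term is named `engraftment`.
#' @export
generate_gene_sets <- function(truth, n_decoy_terms = 20L, term_size = NULL,
                               seed = 1L) {
  universe <- names(truth$per_gene_shift)
  if (is.null(term_size)) term_size <- length(truth$engraftment_genes)
  if (term_size > length(universe))
    abort("term_size (%d) exceeds the gene universe (%d)", term_size,
          length(universe))
  set.seed(substream_seed(seed, "gene_sets"))
  sets <- list(engraftment = truth$engraftment_genes)
  desc <- c(engraftment = "planted engraftment-shift genes")
  for (i in seq_len(n_decoy_terms)) {
    id <- sprintf("decoy_%02d", i)
    sets[[id]] <- sample(universe, term_size)
    desc[id] <- "random decoy term"
  }
  structure(sets, descriptions = desc)
}
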