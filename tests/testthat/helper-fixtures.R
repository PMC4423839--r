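# Shared fixtures and independent oracles. Expensive objects are built once
# per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# frozen-seed default cohort used by recovery/ordering tests
default_cohort <- function() {
  fixture("cohort_seed1", function() generate_cohort(cohort_config(seed = 1L)))
}

default_cohort_pairs <- function() {
  fixture("cohort_seed1_pairs", function()
    suppressWarnings(derive_pairs(default_cohort()$annotation)))
}

# frozen-seed cell-line panel + GCV ridge model
default_panel <- function() {
  fixture("panel_seed7", function()
    generate_cellline_panel(n_lines = 200L, n_genes = 500L, n_causal = 20L,
                            noise_sd = 0.5, seed = 7L))
}

default_ridge <- function() {
  fixture("ridge_seed7", function() {
    p <- default_panel()
    train_ridge(p$expr, p$ic50)
  })
}

# tiny expression matrix builder
toy_expr <- function(values, genes = NULL, samples = NULL, scale = "log2") {
  values <- as.matrix(values)
  rownames(values) <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# average ranks by explicit counting: 1 + (# smaller) + (# tied - 1)/2
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1L))
}

# Spearman via explicit rank construction + textbook Pearson sum formula
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# upper-tail hypergeometric p by enumerating every possible draw of the
# query from the universe (feasible for universes <= 12)
oracle_hyper_p <- function(n_universe, n_term, n_query, observed_overlap) {
  draws <- utils::combn(n_universe, n_query)
  term_genes <- seq_len(n_term)  # wlog the term is the first n_term genes
  overlaps <- apply(draws, 2L, function(d) sum(d %in% term_genes))
  mean(overlaps >= observed_overlap)
}

# Benjamini-Hochberg by the hand step-up procedure
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free data)
oracle_wilcox_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(n, n1)
  r_all <- rank(c(x, y))
  ws <- apply(assignments, 2L, function(ix) sum(r_all[ix])) - n1 * (n1 + 1) / 2
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
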