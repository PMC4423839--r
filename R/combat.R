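#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric batch-effect correction for merging expression studies, in the
#' classical empirical-Bayes form: genes are standardized against a pooled
#' grand mean and variance, per-batch per-gene location and scale effects are
#' estimated and shrunk toward their batch-wide moments (normal prior on the
#' location, inverse-gamma on the scale, hyperparameters by method of
#' moments, joint posterior solved iteratively), and the data are
#' reconstructed with those effects removed. No covariate model is fitted:
#' the adjustment is used purely for between-study merging.
#'
#' With a single batch the input is returned unchanged. Batches of one sample
#' are rejected because their scale effect is undefined.
#'
#' @param m An [expression_matrix()] holding all samples.
#' @param batch Character/factor vector of batch labels, one per column of
#'   `m` (in column order), or a named vector keyed by sample id.
#' @param conv Relative-change convergence tolerance of the posterior
#'   iteration.
#' @return Batch-adjusted `expr_matrix` with the same dimensions and scale.
#' @seealso [merge_and_batch_adjust()] which intersects gene sets first.
#' @export
batch_adjust <- function(m, batch, conv = 1e-4) {
  stopifnot(is_expression_matrix(m))
  if (!is.null(names(batch))) {
    missing_lab <- setdiff(colnames(m), names(batch))
    if (length(missing_lab))
      abort("no batch label for sample(s): %s",
            paste(head(missing_lab, 5L), collapse = ", "))
    batch <- batch[colnames(m)]
  }
  if (length(batch) != ncol(m))
    abort("batch vector length %d != %d samples", length(batch), ncol(m))
  batch <- as.character(batch)
  levels_b <- unique(batch)
  n_b <- vapply(levels_b, function(b) sum(batch == b), integer(1L))
  if (any(n_b < 2L))
    abort("batch '%s' has a single sample; scale effect undefined",
          levels_b[n_b < 2L][1L])
  if (length(levels_b) == 1L) return(m)

  dat <- unclass(m)
  n_array <- ncol(dat)
  cols_b <- lapply(levels_b, function(b) which(batch == b))

  # per-batch gene means, pooled grand mean and pooled variance (1/N)
  b_hat <- vapply(cols_b, function(ix) rowMeans(dat[, ix, drop = FALSE]),
                  numeric(nrow(dat)))                       # genes x batches
  grand_mean <- c(b_hat %*% (n_b / n_array))
  resid <- dat - b_hat[, match(batch, levels_b), drop = FALSE]
  var_pooled <- rowSums(resid^2) / n_array
  if (any(var_pooled == 0))
    abort("gene(s) with zero pooled variance cannot be standardized: %s",
          paste(head(rownames(dat)[var_pooled == 0], 5L), collapse = ", "))

  s_data <- (dat - grand_mean) / sqrt(var_pooled)

  adjusted <- s_data
  for (bi in seq_along(levels_b)) {
    ix <- cols_b[[bi]]
    sb <- s_data[, ix, drop = FALSE]
    gamma_hat <- rowMeans(sb)
    delta_hat <- apply(sb, 1L, var)
    gamma_bar <- mean(gamma_hat)
    t2 <- var(gamma_hat)
    # inverse-gamma hyperparameters by method of moments
    dm <- mean(delta_hat); ds2 <- var(delta_hat)
    a_prior <- (2 * ds2 + dm^2) / ds2
    b_prior <- (dm * ds2 + dm^3) / ds2

    n <- length(ix)
    g_old <- gamma_hat; d_old <- delta_hat
    for (iter in seq_len(200L)) {
      g_new <- (n * t2 * gamma_hat + d_old * gamma_bar) / (n * t2 + d_old)
      sum2 <- rowSums((sb - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old), abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (is.finite(change) && change < conv) break
    }
    adjusted[, ix] <- (sb - g_new) / sqrt(d_new)
  }
  out <- adjusted * sqrt(var_pooled) + grand_mean
  rewrap(out, m)
}
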