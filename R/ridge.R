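# Ridge regression predicting log IC50 from expression, the predictor behind
# the perturbation simulation. Closed-form solution via SVD of the
# standardized sample-by-gene matrix; the penalty is either fixed or chosen
# by generalized cross-validation.

#' Train a ridge model of drug response on expression
#'
#' Genes are standardized on the training panel (constant genes are dropped
#' with a warning), the response is centered, and coefficients come from the
#' closed-form ridge solution computed through the SVD. When `lambda` is
#' `NULL` the penalty minimizing the generalized cross-validation criterion
#' `GCV(lambda) = n * RSS / (n - df)^2`, with `df = sum d_i^2/(d_i^2 +
#' lambda)`, is selected over a log-spaced grid.
#'
#' The training-set baseline — the Spearman correlation between fitted and
#' observed response — is stored with the model; the perturbation sweep
#' reports its correlations relative to this baseline. If the fitted values
#' are (numerically) constant, e.g. in the infinite-penalty limit, the
#' baseline is undefined and recorded as `NA` with a warning.
#'
#' @param expr Genes-by-samples [expression_matrix()] of the training panel.
#' @param ic50 `data.frame` with `cell_line`, `log_ic50` covering every
#'   sample of `expr`.
#' @param lambda Nonnegative penalty, `Inf` allowed; `NULL` (default)
#'   selects by GCV.
#' @param lambda_grid Candidate penalties for GCV.
#' @return Object of class `pdx_ridge`: coefficients (on the standardized
#'   scale), intercept, per-gene centering/scaling, `lambda`,
#'   `baseline_srcc`, and training fitted values.
#' @export
train_ridge <- function(expr, ic50, lambda = NULL,
                        lambda_grid = 10^seq(-4, 6, length.out = 51)) {
  stopifnot(is_expression_matrix(expr))
  if (!is.null(lambda) && (!is.numeric(lambda) || lambda < 0))
    abort("lambda must be >= 0")
  idx <- match(colnames(expr), ic50$cell_line)
  if (anyNA(idx))
    abort("no IC50 for cell line(s): %s",
          paste(head(colnames(expr)[is.na(idx)], 5L), collapse = ", "))
  y <- ic50$log_ic50[idx]
  n <- length(y)
  if (n < 3L) abort("need >= 3 training samples, got %d", n)
  if (var(y) == 0) abort("constant IC50: rank correlation undefined")

  X <- t(unclass(expr))                      # samples x genes
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sprintf("%d constant gene(s) dropped from the ridge fit",
                    sum(!keep)), call. = FALSE)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep]), 2L, scl[keep], "/")
  yc <- y - mean(y)

  sv <- svd(Xs)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)                 # U'y

  gcv <- NULL
  if (is.null(lambda)) {
    gcv <- vapply(lambda_grid, function(l) {
      shrink <- d2 / (d2 + l)
      fit <- sv$u %*% (shrink * uty)
      rss <- sum((yc - fit)^2)
      df <- sum(shrink)
      n * rss / (n - df)^2
    }, numeric(1L))
    lambda <- lambda_grid[which.min(gcv)]
  }

  beta_keep <- if (is.infinite(lambda)) rep(0, ncol(Xs)) else
    c(sv$v %*% (sv$d / (d2 + lambda) * uty))
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  beta[keep] <- beta_keep
  intercept <- mean(y)
  fitted <- c(Xs %*% beta_keep) + intercept

  baseline <- if (sd(fitted) <= 1e-10 * sd(y)) {
    warning("fitted values are constant; baseline rank correlation undefined",
            call. = FALSE)
    NA_real_
  } else safe_spearman(fitted, y)

  structure(list(coefficients = beta, intercept = intercept,
                 center = ctr, scale = scl, lambda = lambda,
                 baseline_srcc = baseline, fitted = setNames(fitted, colnames(expr)),
                 gcv = if (!is.null(gcv)) setNames(gcv, lambda_grid)),
            class = "pdx_ridge")
}

#' Predict log IC50 from expression with a trained ridge model
#'
#' @param object A `pdx_ridge` model.
#' @param expr Genes-by-samples [expression_matrix()] containing every
#'   training gene.
#' @param ... Unused.
#' @return Named numeric vector of predictions, one per sample.
#' @export
predict.pdx_ridge <- function(object, expr, ...) {
  stopifnot(is_expression_matrix(expr))
  genes <- names(object$coefficients)
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g))
    abort("matrix lacks model gene(s): %s", paste(head(missing_g, 5L), collapse = ", "))
  X <- t(unclass(expr)[genes, , drop = FALSE])
  keep <- object$scale > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, object$center[keep]),
              2L, object$scale[keep], "/")
  setNames(c(Xs %*% object$coefficients[keep]) + object$intercept, colnames(expr))
}

#' @export
print.pdx_ridge <- function(x, ...) {
  cat(sprintf("ridge drug-response model: %d genes, lambda = %.4g, baseline SRCC = %s\n",
              length(x$coefficients), x$lambda,
              ifelse(is.na(x$baseline_srcc), "NA",
                     sprintf("%.3f", x$baseline_srcc))))
  invisible(x)
}
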