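#' Construct an expression matrix
#'
#' The package's universal data container: a numeric genes-by-samples matrix
#' with unique row (gene) and column (sample) identifiers and a scale flag
#' recording whether values are linear intensities or log2-transformed.
#' Microarray pipelines conventionally work on the log2 scale; fold-change
#' screening and the perturbation simulation require it and refuse linear
#' input.
#'
#' @param values Numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param scale `"log2"` or `"linear"`.
#' @param allow_duplicate_ids Permit duplicate row ids (probe-level matrices
#'   awaiting [collapse_probes()]). Duplicate sample ids are never allowed.
#' @return A matrix of class `expr_matrix` carrying an `expr_scale` attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), scale = "linear")
#' expr_scale(m)
#' @export
expression_matrix <- function(values, scale = c("log2", "linear"),
                              allow_duplicate_ids = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    abort("duplicate sample id: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup) && !allow_duplicate_ids)
    abort("duplicate gene id (enable probe collapse to accept probe-level rows): %s",
          paste(head(dup, 5L), collapse = ", "))
  if (!all(is.finite(values)))
    abort("expression values must be finite (found NA/NaN/Inf)")
  structure(values, class = c("expr_matrix", class(values)),
            expr_scale = scale)
}

#' @rdname expression_matrix
#' @param m An `expr_matrix`.
#' @export
expr_scale <- function(m) attr(m, "expr_scale") %||% "linear"

#' @rdname expression_matrix
#' @export
is_expression_matrix <- function(m) inherits(m, "expr_matrix")

# re-wrap a plain matrix with the metadata of a template expr_matrix
rewrap <- function(values, template, scale = expr_scale(template)) {
  structure(values, class = class(template), expr_scale = scale)
}

#' @export
`[.expr_matrix` <- function(x, i, j, drop = FALSE) {
  y <- unclass(x)
  attr(y, "expr_scale") <- NULL
  if (missing(i)) i <- seq_len(nrow(y))
  if (missing(j)) j <- seq_len(ncol(y))
  y <- y[i, j, drop = drop]
  if (is.matrix(y)) y <- rewrap(y, x)
  y
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s scale]\n",
              nrow(x), ncol(x), expr_scale(x)))
  nr <- min(5L, nrow(x)); nc <- min(5L, ncol(x))
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE], ...)
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}
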