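# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' generators (cohort, cell-line panel, gene sets, each perturbation replicate)
#' draw from substreams named after what they generate, so one component can be
#' regenerated without replaying the others.
#'
#' @param master Integer master seed.
#' @param stream Character label of the substream.
#' @return An integer seed in `[0, 2^31 - 2]`, deterministic in both arguments.
#' @examples
#' substream_seed(1L, "cohort")
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream),
            length(stream) == 1L)
  # polynomial string hash, all arithmetic kept exact in doubles (< 2^53)
  h <- 0
  for (cp in utf8ToInt(stream)) h <- (h * 131 + cp) %% 2147483647
  as.integer(((abs(master) %% 2147483647) * 48271 + h) %% 2147483647)
}

# stop() with sprintf formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Spearman rank correlation with explicit failure on degenerate input.
# Used internally everywhere a silent NA would hide a bug.
safe_spearman <- function(x, y) {
  if (length(x) != length(y)) abort("vectors differ in length (%d vs %d)",
                                    length(x), length(y))
  if (length(x) < 3L) abort("need at least 3 paired observations, got %d", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite values in input")
  if (var(x) == 0 || var(y) == 0)
    abort("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}
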