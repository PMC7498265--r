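#' Derive a reproducible substream seed for a named simulation stage
#'
#' All randomness in the package flows from a single top-level seed. Each
#' stage (exon models, expression, psi, capture, reads, junctions, ...) draws
#' from its own substream so that stages can be re-run independently without
#' perturbing one another.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h * 2654435) %% 2147483647)
}

with_substream <- function(seed, stage, expr) {
  set.seed(substream_seed(seed, stage))
  expr
}

#' Sample from a normal distribution truncated to the unit interval
#'
#' Inverse-CDF sampling; used for per-cell, per-isoform capture probabilities
#' (mean `capture_mean`, variance `capture_variance`, truncated at 0 and 1).
#'
#' @param n Number of draws.
#' @param mean Mean of the untruncated normal.
#' @param variance Variance of the untruncated normal; 0 returns `mean` exactly.
#' @return Numeric vector of draws in `[0, 1]`.
#' @export
rtruncnorm01 <- function(n, mean, variance) {
  stopifnot(variance >= 0)
  if (variance == 0) return(rep(mean, n))
  sd <- sqrt(variance)
  plo <- stats::pnorm(0, mean, sd)
  phi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## integer check with tolerance
is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

assert_matrix_like <- function(x, what = "matrix") {
  if (!is.matrix(x)) stop(sprintf("'%s' must be a matrix", what), call. = FALSE)
  invisible(x)
}

## matrix with cells as rows, ids guaranteed
name_cells_genes <- function(m, prefix_row = "cell", prefix_col = "gene") {
  if (is.null(rownames(m))) rownames(m) <- paste0(prefix_row, "_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0(prefix_col, "_", seq_len(ncol(m)))
  m
}
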