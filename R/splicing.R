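#' Simulate the biological splicing of cassette exons
#'
#' For each cell i and exon j (one exon per gene), the underlying splicing
#' rate is drawn as `Psi_ij ~ Beta(alpha_j, beta_j)`, the inclusion-isoform
#' molecule count as `XA_ij ~ Binomial(X_ig, Psi_ij)`, and the exclusion count
#' as `XB_ij = X_ig - XA_ij`. The realized (true) isoform ratio is
#' `PsiT_ij = XA_ij / X_ig`, missing (NA) where `X_ig = 0`.
#'
#' Two overrides support the simulator variants: `fixed_psi` replaces the Beta
#' draw with a constant `Psi` for all cells and exons; `fixed_ratio = TRUE`
#' sets `XA = XB = X_ig / 2` exactly (all `X_ig` must be even).
#'
#' @param exons Exon-model data frame ([sample_exon_models()]); `gene_id` must
#'   match columns of `true_counts`.
#' @param true_counts Integer matrix of pre-mRNA counts, cells x genes.
#' @param rng_seed Integer seed.
#' @param fixed_psi Optional constant underlying Psi in `[0, 1]`.
#' @param fixed_ratio If `TRUE`, force an exact 50/50 isoform split.
#' @return An object of class `splicing_state`: list with matrices `psi`,
#'   `XA`, `XB`, `psi_true` (cells x exons) and the input `true_counts`.
#' @export
sample_true_splicing <- function(exons, true_counts, rng_seed = 1L,
                                 fixed_psi = NULL, fixed_ratio = FALSE) {
  assert_matrix_like(true_counts, "true_counts")
  true_counts <- name_cells_genes(true_counts)
  if (!all(exons$gene_id %in% colnames(true_counts)))
    stop("every exon must map to a gene column of true_counts")
  set.seed(substream_seed(rng_seed, "psi"))
  n_cells <- nrow(true_counts)
  n_exons <- nrow(exons)
  X <- true_counts[, exons$gene_id, drop = FALSE]
  dn <- list(rownames(true_counts), exons$exon_id)

  if (fixed_ratio) {
    if (any(X %% 2L != 0L))
      stop("fixed_ratio requires even true counts for an exact 50/50 split")
    XA <- X %/% 2L
    psi <- matrix(0.5, n_cells, n_exons, dimnames = dn)
  } else if (!is.null(fixed_psi)) {
    stopifnot(fixed_psi >= 0, fixed_psi <= 1)
    psi <- matrix(fixed_psi, n_cells, n_exons, dimnames = dn)
    XA <- matrix(stats::rbinom(n_cells * n_exons, as.vector(X), fixed_psi),
                 n_cells, n_exons, dimnames = dn)
  } else {
    psi <- matrix(stats::rbeta(n_cells * n_exons,
                               rep(exons$alpha, each = n_cells),
                               rep(exons$beta, each = n_cells)),
                  n_cells, n_exons, dimnames = dn)
    XA <- matrix(stats::rbinom(n_cells * n_exons, as.vector(X), as.vector(psi)),
                 n_cells, n_exons, dimnames = dn)
  }
  XB <- X - XA
  dimnames(XB) <- dn
  psi_true <- ifelse(X > 0, XA / X, NA_real_)
  dimnames(psi_true) <- dn
  structure(list(true_counts = true_counts, psi = psi,
                 XA = XA, XB = XB, psi_true = psi_true, exons = exons),
            class = "splicing_state")
}

#' @export
print.splicing_state <- function(x, ...) {
  cat("<splicing_state> ", nrow(x$psi), " cells x ", ncol(x$psi), " exons\n",
      sep = "")
  cat("  mean underlying Psi: ", round(mean(x$psi), 3),
      "; zero-expression entries: ", sum(is.na(x$psi_true)), "\n", sep = "")
  invisible(x)
}
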