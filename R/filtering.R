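#' mRNA-recovery-aware filter for splicing observations
#'
#' An observation (exon i, cell j) passes when (1) at least `min_mrna`
#' mRNAs of the exon's gene were captured (`m_ij >= min_mrna`) and (2) the
#' observed junction reads reach the number expected if `min_mrna` mRNAs were
#' informative: `SJ_ij >= min_mrna * (1 + Psi-hat_ij) * C_j`, with `C_j` the
#' cell's junction coverage rate. A molecule that includes the exon carries
#' two informative junctions and one that skips it carries one, hence the
#' `1 + Psi-hat` junctions per mRNA. Observations with missing `Psi-hat`
#' carry no splicing information and fail.
#'
#' @param psi_hat Cells x exons matrix of observed Psi-hat (NA = missing).
#' @param mrna Cells x exons matrix of estimated captured mRNAs of each
#'   exon's gene (`m_ij`, e.g. census `Y` columns mapped to exons).
#' @param coverage Per-cell coverage rates: data frame from [coverage_rate()]
#'   or a named numeric vector aligned with rows of `psi_hat`.
#' @param SJ Cells x exons matrix of total junction reads.
#' @param min_mrna Minimum captured mRNAs (default 10).
#' @return Logical cells x exons matrix: `TRUE` where the observation passes.
#' @export
filter_observations <- function(psi_hat, mrna, coverage, SJ, min_mrna = 10) {
  assert_matrix_like(psi_hat, "psi_hat")
  stopifnot(all(dim(psi_hat) == dim(mrna)), all(dim(psi_hat) == dim(SJ)))
  cj <- if (is.data.frame(coverage)) {
    stats::setNames(coverage$coverage_rate, coverage$cell_id)[rownames(psi_hat)]
  } else coverage[rownames(psi_hat)]
  if (any(is.na(cj)))
    warning("cells with missing coverage rate fail the read criterion")
  sj_min <- min_mrna * (1 + psi_hat) * cj
  pass <- !is.na(psi_hat) & mrna >= min_mrna & !is.na(sj_min) & SJ >= sj_min
  dimnames(pass) <- dimnames(psi_hat)
  pass
}

#' Per-cluster exon retention from an observation-level mask
#'
#' An exon is retained in a cluster when at least `min_cell_fraction` of the
#' cluster's cells have a passing observation (boundary inclusive).
#'
#' @param pass Logical cells x exons matrix.
#' @param clusters Cluster labels, one per cell (named or aligned with rows).
#' @param min_cell_fraction Minimum fraction of passing cells (default 0.5).
#' @return Logical clusters x exons matrix.
#' @export
cluster_retention <- function(pass, clusters, min_cell_fraction = 0.5) {
  assert_matrix_like(pass, "pass")
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == nrow(pass))
  groups <- split(seq_len(nrow(pass)), clusters)
  out <- t(vapply(groups, function(idx)
    colMeans(pass[idx, , drop = FALSE]) >= min_cell_fraction,
    logical(ncol(pass))))
  colnames(out) <- colnames(pass)
  out
}

#' Flat read-count baseline filter
#'
#' Benchmark criterion: an exon is retained in a cluster when at least
#' `min_cell_fraction` of the cluster's cells have `SJ >= min_reads`.
#'
#' @param SJ Cells x exons matrix of total junction reads.
#' @param clusters Cluster labels, one per cell.
#' @param min_reads Minimum junction reads per observation (default 10).
#' @param min_cell_fraction Minimum fraction of qualifying cells (default
#'   0.5, boundary inclusive).
#' @return Logical clusters x exons matrix.
#' @export
baseline_filter <- function(SJ, clusters, min_reads = 10,
                            min_cell_fraction = 0.5) {
  cluster_retention(SJ >= min_reads, clusters, min_cell_fraction)
}

#' Collapse per-cluster retention to an exon selection
#'
#' @param retention Logical clusters x exons matrix.
#' @param scope `"any"`: selected if retained in at least one cluster
#'   (default); `"all"`: retained in every cluster.
#' @return Named logical vector over exons.
#' @export
selected_exons <- function(retention, scope = c("any", "all")) {
  scope <- match.arg(scope)
  if (scope == "any") apply(retention, 2, any) else apply(retention, 2, all)
}
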