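#' Observed Psi-hat from a junction-count table
#'
#' Real-data estimator: `Psi-hat = SJA / (SJA + 2 * SJB)`, where `SJA` counts
#' reads on the two inclusion-informative junctions and `SJB` reads on the
#' single exclusion junction; missing where `SJA + 2 * SJB = 0`. Total
#' junction coverage `SJ = SJA + SJB` is recorded alongside.
#'
#' @param junction_table Data frame with columns `cell_id`, `exon_id`, `SJA`,
#'   `SJB` (non-negative integers). Set `from_simulator = TRUE` if the table
#'   came from the simulator's printed estimator (`SJA / (SJA + SJB)`).
#' @param from_simulator Use the simulator weighting instead of the real-data
#'   weighting.
#' @return List with matrices `psi_hat`, `SJ`, `SJA`, `SJB` (cells x exons).
#' @export
estimate_psi_from_junctions <- function(junction_table, from_simulator = FALSE) {
  need <- c("cell_id", "exon_id", "SJA", "SJB")
  if (!all(need %in% names(junction_table)))
    stop("junction_table needs columns: ", paste(need, collapse = ", "))
  if (any(junction_table$SJA < 0 | junction_table$SJB < 0))
    stop("junction read counts must be non-negative")
  cells <- unique(junction_table$cell_id)
  exons <- unique(junction_table$exon_id)
  shape <- function(v, fill = 0) {
    m <- matrix(fill, length(cells), length(exons), dimnames = list(cells, exons))
    m[cbind(match(junction_table$cell_id, cells),
            match(junction_table$exon_id, exons))] <- v
    m
  }
  SJA <- shape(junction_table$SJA)
  SJB <- shape(junction_table$SJB)
  psi_hat <- psi_from_junction_counts(
    SJA, SJB, if (from_simulator) "simulated" else "halved_exclusion")
  list(psi_hat = psi_hat, SJ = SJA + SJB, SJA = SJA, SJB = SJB)
}

## Scott's-rule bandwidth on the natural-log scale
scott_bw <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' Census-style estimate of captured mRNA counts from TPM
#'
#' For each cell i, the mode `x*` of the log-TPM distribution (TPM >
#' `min_tpm`) is located as the peak of a Gaussian kernel density (Scott's
#' bandwidth, 512-point grid) and back-transformed. With `F` the empirical
#' CDF of the cell's TPM values above `min_tpm` (the distribution the kernel
#' density models, so `F(min_tpm) = 0`) and `n_i` the number of genes with
#' TPM in `(min_tpm, x*]`, the total captured mRNA is
#' `M_i = n_i / (F(x*) - F(min_tpm))`, and per-gene captured counts are
#' `Y_ig = TPM_ig * M_i / 1e6`. No capture-efficiency division is applied:
#' `M_i` estimates mRNAs successfully captured into cDNA, not mRNAs in the
#' lysate.
#'
#' Cells whose `M_i` exceeds `outlier_fold` times the cohort median are
#' flagged as outliers (typically multimodal TPM distributions that defeat
#' the kernel density); cells with a degenerate density or an empty CDF
#' interval are flagged too and get `NA` estimates.
#'
#' @param tpm Non-negative numeric matrix, cells x genes, in TPM.
#' @param min_tpm TPM below which no mRNA is assumed present (default 0.1).
#' @param mode_interval `"right_closed"` counts genes in `(min_tpm, x*]`;
#'   `"open"` counts `(min_tpm, x*)`.
#' @param outlier_fold Fold over the median `M_i` that flags a cell.
#' @param min_reads_quantile Optional pre-filter: drop cells in the bottom
#'   quantile of total TPM-weighted signal before estimation (off by default).
#' @return List of class `census_estimate`: `cells` (data frame `cell_id`,
#'   `x_star`, `n_i`, `M_i`, `outlier`, `flagged`), `Y` (cells x genes
#'   captured-count matrix), and the call parameters.
#' @export
census_counts <- function(tpm, min_tpm = 0.1,
                          mode_interval = c("right_closed", "open"),
                          outlier_fold = 10, min_reads_quantile = NULL) {
  assert_matrix_like(tpm, "tpm")
  if (any(tpm < 0)) stop("TPM matrix must be non-negative")
  mode_interval <- match.arg(mode_interval)
  tpm <- name_cells_genes(tpm)
  if (!is.null(min_reads_quantile)) {
    tot <- rowSums(tpm)
    tpm <- tpm[tot > stats::quantile(tot, min_reads_quantile), , drop = FALSE]
  }
  n_cells <- nrow(tpm)
  x_star <- n_i <- M_i <- rep(NA_real_, n_cells)
  flagged <- rep(FALSE, n_cells)
  for (i in seq_len(n_cells)) {
    v <- tpm[i, ]
    pos <- v[v > min_tpm]
    if (length(pos) < 2L || stats::sd(log(pos)) == 0) {
      flagged[i] <- TRUE
      next
    }
    lx <- log(pos)
    d <- stats::density(lx, bw = scott_bw(lx), n = 512)
    x_star[i] <- exp(d$x[which.max(d$y)])
    Fi <- stats::ecdf(pos)
    denom <- Fi(x_star[i]) - Fi(min_tpm)
    n_i[i] <- if (mode_interval == "right_closed")
      sum(v > min_tpm & v <= x_star[i]) else sum(v > min_tpm & v < x_star[i])
    if (denom <= 0 || n_i[i] == 0) {
      flagged[i] <- TRUE
      next
    }
    M_i[i] <- n_i[i] / denom
  }
  outlier <- !is.na(M_i) & M_i > outlier_fold * stats::median(M_i, na.rm = TRUE)
  Y <- tpm * M_i / 1e6
  cells <- data.frame(cell_id = rownames(tpm), x_star = x_star,
                      n_i = n_i, M_i = M_i, outlier = outlier,
                      flagged = flagged, stringsAsFactors = FALSE)
  structure(list(cells = cells, Y = Y, min_tpm = min_tpm,
                 mode_interval = mode_interval, outlier_fold = outlier_fold),
            class = "census_estimate")
}

#' @export
print.census_estimate <- function(x, ...) {
  ok <- !x$cells$flagged
  cat("<census_estimate> ", nrow(x$cells), " cells (",
      sum(x$cells$flagged), " flagged, ", sum(x$cells$outlier), " outliers)\n",
      sep = "")
  cat(sprintf("  median captured mRNAs M_i: %.0f\n",
              stats::median(x$cells$M_i[ok], na.rm = TRUE)))
  invisible(x)
}

#' Per-cell splice-junction coverage rate from constitutive junctions
#'
#' `C_j = sum_k r_jk / sum_k (j_k * m_jk)`: observed constitutive-junction
#' reads over the number of constitutive junctions carried by the estimated
#' captured mRNAs, restricted to genes with at least one estimated captured
#' molecule. This is the expected number of reads covering one splice
#' junction of one captured mRNA in cell j.
#'
#' @param constitutive_table Data frame with columns `cell_id`, `gene_id`,
#'   `constitutive_junction_reads` (`r_jk`), `junctions_per_transcript`
#'   (`j_k`).
#' @param census A `census_estimate` (per-gene captured counts `m_jk` are
#'   looked up in `census$Y`).
#' @param min_mrna Genes enter the denominator when `m_jk >= min_mrna`
#'   (default 1).
#' @return Data frame `cell_id`, `coverage_rate`, `n_genes_used`;
#'   `coverage_rate` is `NA` (cell flagged) when the denominator is empty.
#' @export
coverage_rate <- function(constitutive_table, census, min_mrna = 1) {
  need <- c("cell_id", "gene_id", "constitutive_junction_reads",
            "junctions_per_transcript")
  if (!all(need %in% names(constitutive_table)))
    stop("constitutive_table needs columns: ", paste(need, collapse = ", "))
  stopifnot(inherits(census, "census_estimate"))
  cells <- rownames(census$Y)
  out <- data.frame(cell_id = cells, coverage_rate = NA_real_,
                    n_genes_used = 0L, stringsAsFactors = FALSE)
  tab <- constitutive_table[constitutive_table$cell_id %in% cells, ]
  gi <- match(tab$gene_id, colnames(census$Y))
  ci <- match(tab$cell_id, cells)
  keep <- !is.na(gi)
  tab <- tab[keep, ]; gi <- gi[keep]; ci <- ci[keep]
  m <- census$Y[cbind(ci, gi)]
  use <- !is.na(m) & m >= min_mrna
  if (any(use)) {
    num <- tapply(tab$constitutive_junction_reads[use], tab$cell_id[use], sum)
    den <- tapply(tab$junctions_per_transcript[use] * m[use],
                  tab$cell_id[use], sum)
    cnt <- tapply(rep(1L, sum(use)), tab$cell_id[use], sum)
    idx <- match(names(num), out$cell_id)
    ok <- den > 0
    out$coverage_rate[idx[ok]] <- as.numeric(num[ok] / den[ok])
    out$n_genes_used[idx] <- as.integer(cnt)
  }
  out
}
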