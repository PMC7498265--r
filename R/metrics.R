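#' Binary-observation and bimodality metrics
#'
#' A single observation is *binary* when `Psi-hat` is exactly 0 or exactly 1
#' (only one isoform seen); missing observations count in neither numerator
#' nor denominator. An exon is *intermediate* when its mean observed
#' `Psi-hat` falls in `intermediate_window`.
#'
#' @param psi_hat Cells x exons matrix (NA = missing).
#' @param intermediate_window Mean-Psi-hat window, default `c(0.2, 0.8)`.
#' @return List with `per_exon` (`exon_id`, `n_obs`, `mean_psi`,
#'   `prop_binary`, `intermediate`, `bimodal`) and `per_cell` (`cell_id`,
#'   `n_obs`, `prop_binary`, restricted to intermediate exons) data frames.
#' @export
binary_metrics <- function(psi_hat, intermediate_window = c(0.2, 0.8)) {
  assert_matrix_like(psi_hat, "psi_hat")
  obs <- !is.na(psi_hat)
  n_obs <- colSums(obs)
  binary <- !is.na(psi_hat) & (psi_hat == 0 | psi_hat == 1)
  prop_binary <- ifelse(n_obs > 0, colSums(binary) / n_obs, NA_real_)
  mean_psi <- ifelse(n_obs > 0, colMeans(psi_hat, na.rm = TRUE), NA_real_)
  intermediate <- !is.na(mean_psi) &
    mean_psi >= intermediate_window[1] & mean_psi <= intermediate_window[2]
  bimodal <- vapply(seq_len(ncol(psi_hat)),
                    function(j) bimodality_flag(psi_hat[, j]), logical(1))
  per_exon <- data.frame(
    exon_id = colnames(psi_hat) %||% paste0("exon_", seq_len(ncol(psi_hat))),
    n_obs = n_obs, mean_psi = mean_psi, prop_binary = prop_binary,
    intermediate = intermediate, bimodal = bimodal,
    stringsAsFactors = FALSE, row.names = NULL
  )
  im <- which(intermediate)
  cell_obs <- rowSums(obs[, im, drop = FALSE])
  per_cell <- data.frame(
    cell_id = rownames(psi_hat) %||% paste0("cell_", seq_len(nrow(psi_hat))),
    n_obs = cell_obs,
    prop_binary = ifelse(cell_obs > 0,
                         rowSums(binary[, im, drop = FALSE]) / cell_obs,
                         NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(per_exon = per_exon, per_cell = per_cell)
}

#' Heuristic bimodality flag for one exon
#'
#' `TRUE` when at least `tail_fraction` of the non-missing observations are
#' `<= low` and at least `tail_fraction` are `>= high`.
#'
#' @param psi_column Observed Psi-hat values of one exon across cells.
#' @param low,high Tail cut points (defaults 0.25 and 0.75).
#' @param tail_fraction Minimum fraction per tail (default 0.25).
#' @return Logical; `NA` when there is no non-missing observation.
#' @export
bimodality_flag <- function(psi_column, low = 0.25, high = 0.75,
                            tail_fraction = 0.25) {
  x <- psi_column[!is.na(psi_column)]
  if (length(x) == 0L) return(NA)
  mean(x <= low) >= tail_fraction && mean(x >= high) >= tail_fraction
}

#' Kruskal-Wallis differential-splicing test per exon
#'
#' Groups each exon's observed Psi-hat by cluster and applies the
#' (tie-corrected) Kruskal-Wallis rank test. Clusters with fewer than
#' `min_obs` non-missing observations are dropped from that exon's test;
#' exons with fewer than two usable clusters get `NA`. All-tied data is
#' defined as `p = 1`.
#'
#' @param psi_hat Cells x exons matrix (NA = missing).
#' @param clusters Cluster labels, one per cell.
#' @param min_obs Minimum observations per cluster (default 2).
#' @return Named numeric vector of p-values per exon.
#' @export
kruskal_wallis_by_cluster <- function(psi_hat, clusters, min_obs = 2) {
  assert_matrix_like(psi_hat, "psi_hat")
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == nrow(psi_hat))
  out <- vapply(seq_len(ncol(psi_hat)), function(j) {
    v <- psi_hat[, j]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    cl <- clusters[ok]; v <- v[ok]
    counts <- table(cl)
    keep <- cl %in% names(counts)[counts >= min_obs]
    if (length(unique(cl[keep])) < 2L) return(NA_real_)
    v <- v[keep]; cl <- cl[keep]
    if (length(unique(v)) == 1L) return(1)
    stats::kruskal.test(v, factor(cl))$p.value
  }, numeric(1))
  names(out) <- colnames(psi_hat)
  out
}

#' Fold-enrichment evaluation of a filter's exon selection
#'
#' For each p-value threshold `x`: with `M` the universe of exons, `m` those
#' with `p <= x`, `P` the selected subset and `p` the selected exons with
#' `p <= x`, computes `fold = (|M| * |p|) / (|P| * |m|)`, the upper-tail
#' hypergeometric enrichment p-value, its Benjamini-Hochberg adjustment
#' across the threshold grid, and the confusion-matrix scores (selected
#' exons as predicted positives, low-p exons as condition positives).
#'
#' @param universe_pvalues Named numeric vector of per-exon p-values (the
#'   universe; restrict upstream, e.g. to mean Psi-hat in (0.05, 0.95)).
#'   Exons with `NA` p-values are dropped.
#' @param selected Names of selected exons, or a logical vector over the
#'   universe.
#' @param thresholds P-value threshold grid (default `0.1 ... 1e-5`).
#' @return Data frame, one row per threshold: `threshold`, `M`, `m`, `P`,
#'   `p`, `fold`, `pval`, `qval`, `precision`, `recall`, `specificity`,
#'   `accuracy`, `f1`. `fold` is `NA` when `|m| = 0` or `|P| = 0`.
#' @export
evaluate_filter_enrichment <- function(universe_pvalues, selected,
                                       thresholds = c(0.1, 0.05, 0.01, 1e-3,
                                                      1e-4, 1e-5)) {
  pv <- universe_pvalues[!is.na(universe_pvalues)]
  if (is.logical(selected)) {
    stopifnot(length(selected) == length(universe_pvalues))
    selected <- names(universe_pvalues)[selected]
  }
  if (!all(selected %in% names(universe_pvalues)))
    stop("selected exons must be a subset of the universe")
  sel <- names(pv) %in% selected
  M <- length(pv); P <- sum(sel)
  rows <- lapply(thresholds, function(x) {
    sig <- pv <= x
    m <- sum(sig); p <- sum(sig & sel)
    tn <- sum(!sig & !sel); fp <- P - p; fn <- m - p
    data.frame(
      threshold = x, M = M, m = m, P = P, p = p,
      fold = if (m == 0 || P == 0) NA_real_ else (M * p) / (P * m),
      pval = stats::phyper(p - 1, m, M - m, P, lower.tail = FALSE),
      precision = if (P > 0) p / P else NA_real_,
      recall = if (m > 0) p / m else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = (p + tn) / M,
      f1 = if (2 * p + fp + fn > 0) 2 * p / (2 * p + fp + fn) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out$qval <- stats::p.adjust(out$pval, method = "BH")
  out[, c("threshold", "M", "m", "P", "p", "fold", "pval", "qval",
          "precision", "recall", "specificity", "accuracy", "f1")]
}
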