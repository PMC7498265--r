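#' Two-component expression embedding
#'
#' Principal-component scores of log1p-transformed, per-cell depth-normalized
#' counts; a plain embedding utility for the autocorrelation test. Signs are
#' fixed (largest-magnitude loading positive) so results are deterministic.
#'
#' @param expression Non-negative cells x genes count matrix.
#' @param n_components Number of components (default 2).
#' @return Cells x `n_components` score matrix.
#' @export
compute_embedding <- function(expression, n_components = 2) {
  assert_matrix_like(expression, "expression")
  if (nrow(expression) < 2L) stop("need at least two cells")
  depth <- rowSums(expression)
  if (all(depth == 0)) stop("expression matrix is all zero")
  norm <- expression / pmax(depth, 1) * stats::median(depth[depth > 0])
  lx <- log1p(norm)
  if (all(apply(lx, 2, stats::sd) == 0)) stop("constant expression matrix")
  pc <- stats::prcomp(lx, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  scores <- pc$x
  for (k in seq_len(ncol(scores))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- rownames(expression)
  scores[, seq_len(n_components), drop = FALSE]
}

## Gaussian K-nearest-neighbour weight matrix; w[j, k] = exp(-d_jk^2 / s_j^2)
## for the K nearest neighbours of j (self excluded), else 0. s_j is the
## realized distance to the K-th neighbour; ties broken by stable index order.
knn_weights <- function(embedding, k_neighbors) {
  d <- as.matrix(stats::dist(embedding))
  n <- nrow(d)
  k_neighbors <- min(k_neighbors, n - 1L)
  w <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ord <- order(d[j, -j])  # indices into the n-1 others, stable
    others <- seq_len(n)[-j]
    nb <- others[ord[seq_len(k_neighbors)]]
    sig <- d[j, nb[k_neighbors]]
    if (sig == 0) sig <- .Machine$double.eps
    w[j, nb] <- exp(-d[j, nb]^2 / sig^2)
  }
  w
}

## Batch Geary-style scores for a matrix of (already normalized) exon values.
## X: cells x exons with NA for missing. Pairs with a missing member
## contribute zero to the numerator; missing cells are dropped from the
## denominator. N and W are the global cell count and total weight.
geary_scores <- function(X, w) {
  n <- nrow(X)
  W <- sum(w)
  M <- !is.na(X)
  X0 <- ifelse(M, X, 0)
  storage.mode(M) <- "double"
  X2 <- X0^2
  num <- colSums(X2 * (w %*% M)) + colSums(M * (w %*% X2)) -
    2 * colSums(X0 * (w %*% X0))
  mu <- colSums(X0) / pmax(colSums(M), 1)
  den <- colSums((X0 - rep(mu, each = n))^2 * M)
  score <- 1 - (n - 1) * num / (2 * W * den)
  score[den == 0] <- NA_real_
  score
}

## Folded mean-Psi bins and missingness bins used for the permutation null.
## Mean-Psi bins (folded around 0.5): (0.05-0.1 & 0.9-0.95), (0.1-0.2 &
## 0.8-0.9), (0.2-0.3 & 0.7-0.8), (0.3-0.4 & 0.6-0.7), (0.4-0.6); exons with
## mean Psi-hat outside (0.05, 0.95) are not tested. Missingness bins are
## 10%-wide over the full 0-100% range.
autocorr_bins <- function(mean_psi, missing_frac) {
  folded <- pmin(mean_psi, 1 - mean_psi)
  psi_bin <- cut(folded, breaks = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                 include.lowest = FALSE, right = TRUE)
  miss_bin <- cut(missing_frac, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  list(psi_bin = psi_bin, miss_bin = miss_bin)
}

#' Permutation autocorrelation test for splicing consistency
#'
#' Adaptation of Geary's C: exons whose splicing rate is reliably measured
#' should show similar `Psi-hat` among transcriptionally neighbouring cells.
#' Per cell, `Psi-hat` values are normalized across tested exons
#' (`(value - cell mean) / cell variance` as printed; `normalize_by = "sd"`
#' divides by the standard deviation instead). Neighbourhoods are Gaussian
#' K-nearest-neighbour weights on the embedding with per-cell scale equal to
#' the distance to the K-th neighbour. The score per exon i is
#' \deqn{C' = 1 - \frac{(N-1) \sum_j \sum_k w_{jk} (\Psi'_{ij} - \Psi'_{ik})^2}
#'   {2 W \sum_j (\Psi'_{ij} - \bar\Psi'_i)^2}}
#' A permutation null is built per bin of (folded mean Psi-hat, missingness):
#' exon value vectors are permuted across cells `n_perm` times, pooled within
#' the bin, and `p = (x + 1) / (n_perm + 1)` with `x` the number of permuted
#' scores strictly greater.
#'
#' @param psi_hat Cells x exons matrix of observed Psi-hat (NA = missing).
#' @param embedding Cells x 2 coordinate matrix (e.g. [compute_embedding()]).
#' @param k_neighbors Neighbourhood size K (default: half the cells).
#' @param n_perm Permutations per bin (default 20000).
#' @param rng_seed Integer seed.
#' @param normalize_by `"variance"` (as printed) or `"sd"`.
#' @param psi_range Exons with mean Psi-hat outside this open interval are
#'   not tested (default `c(0.05, 0.95)`).
#' @return Data frame per exon: `exon_id`, `score`, `p_value`, `mean_psi`,
#'   `missing_frac`, `n_obs`, `psi_bin`, `miss_bin`. Untested exons (out of
#'   range, zero variance, or empty bin) have `NA` p-values.
#' @export
autocorrelation_test <- function(psi_hat, embedding,
                                 k_neighbors = floor(nrow(psi_hat) / 2),
                                 n_perm = 20000L, rng_seed = 1L,
                                 normalize_by = c("variance", "sd"),
                                 psi_range = c(0.05, 0.95)) {
  assert_matrix_like(psi_hat, "psi_hat")
  stopifnot(nrow(embedding) == nrow(psi_hat))
  normalize_by <- match.arg(normalize_by)
  n <- nrow(psi_hat)
  mean_psi <- colMeans(psi_hat, na.rm = TRUE)
  missing_frac <- colMeans(is.na(psi_hat))
  tested <- !is.na(mean_psi) & mean_psi > psi_range[1] & mean_psi < psi_range[2]

  # per-cell normalization across tested exons
  sub <- psi_hat[, tested, drop = FALSE]
  mu_j <- rowMeans(sub, na.rm = TRUE)
  var_j <- apply(sub, 1, stats::var, na.rm = TRUE)
  scale_j <- if (normalize_by == "variance") var_j else sqrt(var_j)
  scale_j[!is.finite(scale_j) | scale_j == 0] <- NA_real_
  Xn <- (sub - mu_j) / scale_j

  w <- knn_weights(embedding, k_neighbors)
  score_t <- geary_scores(Xn, w)

  bins <- autocorr_bins(mean_psi[tested], missing_frac[tested])
  bin_id <- interaction(bins$psi_bin, bins$miss_bin, drop = TRUE)

  set.seed(substream_seed(rng_seed, "autocorr_perm"))
  p_t <- rep(NA_real_, sum(tested))
  for (b in levels(bin_id)) {
    members <- which(bin_id == b)
    if (length(members) < 1L) next
    src <- rep_len(members, n_perm)
    null_scores <- numeric(n_perm)
    chunk <- 500L
    done <- 0L
    while (done < n_perm) {
      take <- min(chunk, n_perm - done)
      Xp <- vapply(seq_len(take), function(t)
        Xn[sample.int(n), src[done + t]], numeric(n))
      null_scores[done + seq_len(take)] <- geary_scores(Xp, w)
      done <- done + take
    }
    null_scores <- null_scores[!is.na(null_scores)]
    if (!length(null_scores)) next
    for (e in members) {
      if (is.na(score_t[e])) next
      x <- sum(null_scores > score_t[e])
      p_t[e] <- (x + 1) / (length(null_scores) + 1)
    }
  }

  out <- data.frame(
    exon_id = colnames(psi_hat) %||% paste0("exon_", seq_len(ncol(psi_hat))),
    score = NA_real_, p_value = NA_real_,
    mean_psi = mean_psi, missing_frac = missing_frac,
    n_obs = colSums(!is.na(psi_hat)),
    psi_bin = NA_character_, miss_bin = NA_character_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$score[tested] <- score_t
  out$p_value[tested] <- p_t
  out$psi_bin[tested] <- as.character(bins$psi_bin)
  out$miss_bin[tested] <- as.character(bins$miss_bin)
  out
}
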