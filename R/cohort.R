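#' Synthetic clustered cohort with planted differentially spliced exons
#'
#' Generates a Smart-seq2-like cohort for evaluating the mRNA-recovery filter
#' and the differential-splicing analysis end to end. Cells belong to
#' `n_clusters` groups. A fraction of exons is *planted* as
#' cluster-differential: their underlying Beta mean alternates between
#' `diff_low` and `diff_high` across clusters (concentration
#' `concentration`), so their true splicing differs between cell types. The
#' remaining exons are unimodal and identical across clusters (null exons).
#'
#' Expression follows a realistic two-class transcriptome: a small class of
#' stably, highly expressed genes (fraction `high_frac`; tight kinetics, high
#' transcription scale) on top of a bursty low-expression background. Only
#' genes of the high class recover enough mRNA to clear a 10-molecule filter
#' bar, while background genes produce the sparse, largely binary
#' observations the filter is meant to discard — mirroring the coverage
#' structure of real full-length single-cell data. Cluster identity also
#' boosts a subset of marker genes so an expression embedding separates the
#' clusters.
#'
#' The returned object carries the inputs the quantification pipeline expects
#' from real data: a TPM matrix (captured molecule counts scaled to sum 1e6
#' per cell), a long junction-count table, and a synthetic
#' constitutive-junction table (per gene: `j_k` constitutive junctions; reads
#' Poisson with the cell's true per-junction read rate).
#'
#' @param n_clusters Number of cell clusters (default 3).
#' @param cells_per_cluster Cells per cluster (default 60).
#' @param n_genes Total genes (one cassette exon each; default 1000).
#' @param diff_frac Fraction of exons planted differential (default 0.5).
#' @param high_frac Fraction of genes in the stable high-expression class
#'   (default 0.025).
#' @param diff_low,diff_high Cluster Beta means of planted exons.
#' @param concentration Beta concentration of planted exons.
#' @param tech A [tech_params()] object (default capture 0.1).
#' @param n_marker_genes Background genes per cluster with cluster-specific
#'   expression boost (markers; default 40).
#' @param rng_seed Integer seed.
#' @return List of class `cohort_sim`: `clusters` (labels per cell), `exons`,
#'   `planted` (logical per exon), `high_class` (logical per gene), `psi`
#'   (true per-cell rates), `state`, `junctions`, `tpm`, `junction_table`,
#'   `constitutive_table`, `captured_total` (per-cell true captured
#'   molecules), `mrna` (true captured mRNAs per gene, cells x exons) and
#'   `config` notes.
#' @export
simulate_cluster_cohort <- function(n_clusters = 3L, cells_per_cluster = 60L,
                                    n_genes = 1000L, diff_frac = 0.5,
                                    high_frac = 0.025,
                                    diff_low = 0.4, diff_high = 0.6,
                                    concentration = 30,
                                    tech = tech_params(),
                                    n_marker_genes = 40L, rng_seed = 1L) {
  n_cells <- n_clusters * cells_per_cluster
  clusters <- rep(paste0("cluster_", seq_len(n_clusters)),
                  each = cells_per_cluster)

  exons <- sample_exon_models(c(unimodal = n_genes), rng_seed = rng_seed)

  set.seed(substream_seed(rng_seed, "cohort_design"))
  n_high <- max(1L, round(high_frac * n_genes))
  high_class <- seq_len(n_genes) %in% sample(n_genes, n_high)
  planted <- seq_len(n_genes) %in% sample(n_genes, round(diff_frac * n_genes))

  # bursty low-expression background + stable high class
  kin <- sample_kinetics(n_genes, rng_seed, scale_meanlog = log(15),
                         scale_sdlog = 1)
  kin$k_on[high_class] <- stats::rlnorm(n_high, log(9), 0.3)
  kin$k_off[high_class] <- stats::rlnorm(n_high, log(3), 0.3)
  kin$scale[high_class] <- stats::rlnorm(n_high, log(1100), 0.3)
  X <- simulate_expression(kin, n_cells, rng_seed)
  rownames(X) <- paste0("cell_", seq_len(n_cells))

  # cluster-specific marker expression so the embedding separates clusters
  set.seed(substream_seed(rng_seed, "cohort_markers"))
  marker_of <- rep(seq_len(n_clusters), each = n_marker_genes)
  marker_gene <- sample(which(!high_class), length(marker_of))
  for (k in seq_along(marker_gene)) {
    on <- clusters == paste0("cluster_", marker_of[k])
    X[on, marker_gene[k]] <- X[on, marker_gene[k]] +
      stats::rpois(sum(on), mean(X[, marker_gene[k]]) * 2 + 5)
  }

  # per-cell underlying Psi: planted exons get cluster-specific Beta means
  set.seed(substream_seed(rng_seed, "cohort_psi"))
  psi <- matrix(stats::rbeta(n_cells * n_genes,
                             rep(exons$alpha, each = n_cells),
                             rep(exons$beta, each = n_cells)),
                n_cells, n_genes,
                dimnames = list(rownames(X), exons$exon_id))
  cl_idx <- as.integer(factor(clusters))
  for (j in which(planted)) {
    mu <- ifelse((cl_idx + j) %% 2L == 0L, diff_low, diff_high)
    psi[, j] <- stats::rbeta(n_cells, mu * concentration,
                             (1 - mu) * concentration)
  }
  XA <- matrix(stats::rbinom(n_cells * n_genes, as.vector(X), as.vector(psi)),
               n_cells, n_genes, dimnames = dimnames(psi))
  XB <- X - XA
  psi_true <- ifelse(X > 0, XA / X, NA_real_)
  state <- structure(list(true_counts = X, psi = psi, XA = XA, XB = XB,
                          psi_true = psi_true, exons = exons),
                     class = "splicing_state")

  captured <- capture_molecules(state, tech, rng_seed)
  reads <- generate_reads(captured, exons, tech, rng_seed)
  junctions <- sample_junction_reads(reads, exons, tech, rng_seed)

  mrna <- captured$CA + captured$CB            # true captured mRNAs per gene
  tot <- rowSums(mrna)
  tpm <- mrna / pmax(tot, 1) * 1e6
  dimnames(tpm) <- list(rownames(X), exons$gene_id)

  # synthetic constitutive-junction table: per-junction read rate equals the
  # simulator's per-molecule junction coverage (depth * 2 * (lr - 1) / 1000)
  set.seed(substream_seed(rng_seed, "cohort_constitutive"))
  jk <- sample(2:12, n_genes, replace = TRUE)
  rate_per_junction <- tech$depth_factor * 2 * (tech$read_length - 1) / 1000
  const_rows <- expand.grid(cell = seq_len(n_cells), gene = seq_len(n_genes))
  lambda <- mrna[cbind(const_rows$cell, const_rows$gene)] *
    jk[const_rows$gene] * rate_per_junction
  constitutive_table <- data.frame(
    cell_id = rownames(X)[const_rows$cell],
    gene_id = exons$gene_id[const_rows$gene],
    constitutive_junction_reads = stats::rpois(nrow(const_rows), lambda),
    junctions_per_transcript = jk[const_rows$gene],
    stringsAsFactors = FALSE
  )

  junction_table <- data.frame(
    cell_id = rep(rownames(X), times = n_genes),
    exon_id = rep(exons$exon_id, each = n_cells),
    gene_id = rep(exons$gene_id, each = n_cells),
    SJA = as.vector(junctions$SJA), SJB = as.vector(junctions$SJB),
    stringsAsFactors = FALSE
  )

  structure(list(clusters = clusters, exons = exons, planted = planted,
                 high_class = high_class,
                 psi = psi, state = state, junctions = junctions,
                 expression = X, tpm = tpm, mrna = mrna,
                 captured_total = tot, junction_table = junction_table,
                 constitutive_table = constitutive_table,
                 config = list(n_clusters = n_clusters,
                               cells_per_cluster = cells_per_cluster,
                               tech = tech, seed = rng_seed)),
            class = "cohort_sim")
}

#' Synthetic cohort with embedding-smooth splicing structure
#'
#' Cells sit on a one-dimensional developmental gradient that drives both
#' expression (so the principal-component embedding recovers it) and, for
#' *planted* exons, the underlying splicing rate (logistic in the gradient).
#' Null exons have a cell-independent unimodal rate. Observed Psi-hat is a
#' binomial read-sampling of the rate with a missing-at-random mask,
#' emulating the sparse observations the autocorrelation test faces.
#'
#' @param n_cells Number of cells (default 150).
#' @param n_planted,n_null Planted / null exon counts.
#' @param n_reads Junction reads per observed entry (binomial denominator).
#' @param missing_frac Fraction of entries masked missing (default 0.55).
#' @param slope Logistic slope of planted Psi along the gradient.
#' @param n_genes Expression genes used to build the embedding.
#' @param rng_seed Integer seed.
#' @return List: `psi_hat` (cells x exons), `planted` (logical), `embedding`,
#'   `expression`, `gradient`, `psi_true`.
#' @export
simulate_gradient_cohort <- function(n_cells = 150L, n_planted = 40L,
                                     n_null = 160L, n_reads = 20L,
                                     missing_frac = 0.55, slope = 6,
                                     n_genes = 120L, rng_seed = 1L) {
  set.seed(substream_seed(rng_seed, "gradient"))
  t <- sort(stats::runif(n_cells, -1, 1))
  a <- stats::runif(n_genes, 1, 3)
  b <- stats::rnorm(n_genes, 0, 1.2)
  lambda <- exp(rep(a, each = n_cells) + outer(t, b))
  expr <- matrix(stats::rpois(n_cells * n_genes, lambda), n_cells,
                 dimnames = list(paste0("cell_", seq_len(n_cells)),
                                 paste0("gene_", seq_len(n_genes))))
  n_exons <- n_planted + n_null
  psi_true <- matrix(NA_real_, n_cells, n_exons,
                     dimnames = list(rownames(expr),
                                     paste0("exon_", seq_len(n_exons))))
  planted <- seq_len(n_exons) <= n_planted
  for (j in seq_len(n_exons)) {
    if (planted[j]) {
      dir <- if (j %% 2L == 0L) 1 else -1
      psi_true[, j] <- stats::plogis(dir * slope * t +
                                       stats::rnorm(n_cells, 0, 0.3))
    } else {
      mu <- stats::runif(1, 0.25, 0.75)
      psi_true[, j] <- stats::rbeta(n_cells, mu * 10, (1 - mu) * 10)
    }
  }
  psi_hat <- matrix(stats::rbinom(n_cells * n_exons, n_reads,
                                  as.vector(psi_true)) / n_reads,
                    n_cells, n_exons, dimnames = dimnames(psi_true))
  mask <- matrix(stats::runif(n_cells * n_exons) < missing_frac, n_cells)
  psi_hat[mask] <- NA_real_
  list(psi_hat = psi_hat, planted = planted,
       embedding = compute_embedding(expr), expression = expr,
       gradient = t, psi_true = psi_true)
}
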