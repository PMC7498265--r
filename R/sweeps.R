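#' Fixed-expression sweep: effect of absolute mRNA count on binary Psi-hat
#'
#' Simulator variant: 300 cells, genes indexed `g = 1..n_genes` with
#' expression fixed at `X_ig = g` in every cell, underlying splicing rate
#' fixed at each value of `psi_values` for all exons and cells, mean capture
#' efficiency `capture_mean`. Per replicate, exon models (isoform lengths)
#' are redrawn and the full technical stage is simulated; the proportion of
#' binary observations (`Psi-hat` exactly 0 or 1, among non-missing) is
#' averaged over cells and replicates per expression level.
#'
#' @param psi_values Underlying Psi values to sweep (paper design:
#'   `seq(0.01, 0.5, 0.01)`).
#' @param n_genes Number of expression levels (default 500).
#' @param n_cells Cells per simulation (default 300).
#' @param n_replicates Replicate simulations per Psi (default 30).
#' @param tech A [tech_params()] object (default: capture 0.1).
#' @param length_config See [sample_exon_models()].
#' @param rng_seed Top-level seed; replicates use derived substreams.
#' @return Data frame `psi`, `expression_level`, `mean_binary_proportion`,
#'   `n_obs` (total non-missing observations averaged over).
#' @export
sweep_expression <- function(psi_values = seq(0.01, 0.5, 0.01),
                             n_genes = 500L, n_cells = 300L,
                             n_replicates = 30L,
                             tech = tech_params(capture_mean = 0.1),
                             length_config = default_length_config(),
                             rng_seed = 1L) {
  stopifnot(length(psi_values) >= 1, all(psi_values >= 0 & psi_values <= 1))
  rows <- list()
  for (psi in psi_values) {
    binary_sum <- obs_sum <- numeric(n_genes)
    for (rep in seq_len(n_replicates)) {
      seed <- substream_seed(rng_seed, sprintf("sweep_expr_%g_%d", psi, rep))
      cfg <- sim_config(n_cells = n_cells,
                        n_per_regime = c(unimodal = n_genes),
                        tech = tech, length_config = length_config,
                        fixed_psi = psi,
                        expression_override = seq_len(n_genes), seed = seed)
      sim <- run_simulation(cfg)
      ph <- sim$junctions$psi_hat
      obs <- !is.na(ph)
      binary_sum <- binary_sum + colSums(obs & (ph == 0 | ph == 1))
      obs_sum <- obs_sum + colSums(obs)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      psi = psi, expression_level = seq_len(n_genes),
      mean_binary_proportion = ifelse(obs_sum > 0, binary_sum / obs_sum,
                                      NA_real_),
      n_obs = obs_sum
    )
  }
  do.call(rbind, rows)
}

#' Smallest expression level where the binary proportion drops to one half
#'
#' @param sweep_table Output of [sweep_expression()].
#' @param psi The Psi value to extract.
#' @param target Proportion threshold (default 0.5).
#' @return The smallest expression level (molecules per cell) whose average
#'   binary proportion is `<= target`; `NA` if never reached.
#' @export
binary_half_threshold <- function(sweep_table, psi, target = 0.5) {
  sub <- sweep_table[abs(sweep_table$psi - psi) < 1e-9, ]
  if (nrow(sub) == 0L) stop("psi value not present in sweep table")
  sub <- sub[order(sub$expression_level), ]
  hit <- which(!is.na(sub$mean_binary_proportion) &
                 sub$mean_binary_proportion <= target)
  if (!length(hit)) return(NA_integer_)
  sub$expression_level[hit[1]]
}

#' Capture-efficiency sweep at a fixed 50/50 isoform split
#'
#' Simulator variant: the true splicing rate of all exons is fixed at
#' `PsiT = 0.5` by setting `XA = XB = X_ig / 2` exactly (counts forced even),
#' and the average capture efficiency is swept over `capture_grid`. Exons are
#' ranked by their mean informative junction-read coverage; the per-exon
#' proportion of cells with only one isoform type observed is reported.
#'
#' @param capture_grid Capture efficiencies (paper design:
#'   `seq(0.01, 0.1, 0.001)`).
#' @param n_genes,n_cells Simulation dimensions.
#' @param tech Baseline [tech_params()]; `capture_mean` is overridden by the
#'   grid.
#' @param rng_seed Top-level seed (shared across the grid so runs are
#'   comparable).
#' @return Data frame `capture_efficiency`, `exon_id`, `expression_rank`
#'   (1 = highest junction coverage), `mean_coverage`, `binary_proportion`,
#'   `n_obs`.
#' @export
sweep_capture <- function(capture_grid = seq(0.01, 0.1, 0.001),
                          n_genes = 500L, n_cells = 300L,
                          tech = tech_params(), rng_seed = 1L) {
  stopifnot(all(capture_grid > 0 & capture_grid <= 1))
  kin <- sample_kinetics(n_genes, rng_seed)
  rows <- list()
  for (cap in capture_grid) {
    tp <- tech
    tp$capture_mean <- cap
    cfg <- sim_config(n_cells = n_cells, n_per_regime = c(unimodal = n_genes),
                      tech = tp, kinetics = kin, fixed_ratio = TRUE,
                      seed = rng_seed)
    sim <- run_simulation(cfg)
    ph <- sim$junctions$psi_hat
    obs <- !is.na(ph)
    n_obs <- colSums(obs)
    cov <- colMeans(sim$junctions$SJ)
    rows[[length(rows) + 1L]] <- data.frame(
      capture_efficiency = cap, exon_id = colnames(ph),
      expression_rank = rank(-cov, ties.method = "first"),
      mean_coverage = cov,
      binary_proportion = ifelse(n_obs > 0,
                                 colSums(obs & (ph == 0 | ph == 1)) / n_obs,
                                 NA_real_),
      n_obs = n_obs, stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, rows)
}

#' Bimodal-vs-unimodal regime comparison over a capture grid
#'
#' Runs the default 1500-gene design under both splicing regimes with shared
#' seeds and technical settings for each capture efficiency, and returns
#' per-exon Psi / Psi-hat histogram tables (21 bins of width 0.05 on [0, 1],
#' exons ranked by junction coverage) plus per-exon binary-vs-coverage
#' tables.
#'
#' @param capture_grid Capture efficiencies to compare.
#' @param n_cells Cells per run.
#' @param tech Baseline [tech_params()]; `capture_mean` is overridden.
#' @param rng_seed Shared top-level seed.
#' @return List with `binary` (data frame: regime, capture, exon, regime
#'   label, coverage, binary proportion, mean true/observed Psi) and
#'   `histograms` (data frame of 21-bin Psi-hat histograms per exon).
#' @export
run_regime_comparison <- function(capture_grid = c(0.025, 0.05, 0.1),
                                  n_cells = 300L, tech = tech_params(),
                                  rng_seed = 1L) {
  bin_breaks <- seq(0, 1.05, 0.05) - 0.025
  bin_breaks[1] <- -1e-9; bin_breaks[22] <- 1 + 1e-9
  binary <- list(); histograms <- list()
  for (regime in c("bimodal", "unimodal")) {
    for (cap in capture_grid) {
      tp <- tech
      tp$capture_mean <- cap
      cfg <- sim_config(n_cells = n_cells, regime = regime, tech = tp,
                        seed = rng_seed)
      sim <- run_simulation(cfg)
      ph <- sim$junctions$psi_hat
      obs <- !is.na(ph)
      n_obs <- colSums(obs)
      cov <- colMeans(sim$junctions$SJ)
      binary[[length(binary) + 1L]] <- data.frame(
        regime = regime, capture_efficiency = cap, exon_id = colnames(ph),
        exon_regime = sim$exons$regime,
        coverage_rank = rank(-cov, ties.method = "first"),
        mean_coverage = cov,
        binary_proportion = ifelse(n_obs > 0,
                                   colSums(obs & (ph == 0 | ph == 1)) / n_obs,
                                   NA_real_),
        mean_psi_true = colMeans(sim$state$psi),
        mean_psi_hat = ifelse(n_obs > 0, colMeans(ph, na.rm = TRUE), NA_real_),
        n_obs = n_obs, stringsAsFactors = FALSE, row.names = NULL
      )
      alt <- sim$exons$regime %in% c("bimodal", "unimodal")
      hmat <- t(apply(ph[, alt, drop = FALSE], 2, function(v)
        as.integer(table(cut(v[!is.na(v)], bin_breaks)))))
      hdf <- data.frame(regime = regime, capture_efficiency = cap,
                        exon_id = colnames(ph)[alt], stringsAsFactors = FALSE,
                        row.names = NULL)
      colnames(hmat) <- paste0("bin_", sprintf("%.2f", seq(0, 1, 0.05)))
      histograms[[length(histograms) + 1L]] <- cbind(hdf, hmat)
    }
  }
  list(binary = do.call(rbind, binary),
       histograms = do.call(rbind, histograms))
}
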