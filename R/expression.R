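#' Default transcriptional burst kinetics for simulated genes
#'
#' Two-state (Beta-Poisson) kinetics: the per-cell burst fraction is
#' `B ~ Beta(k_on, k_off)` and the pre-mRNA count `X ~ Poisson(scale * B)`,
#' so the marginal per-gene mean is approximately
#' `scale * k_on / (k_on + k_off)`. Hyper-parameter defaults:
#' `k_on ~ LogNormal(log 0.5, 1)`, `k_off ~ LogNormal(log 1, 1)`,
#' `scale ~ LogNormal(log 50, 1.5)`.
#'
#' @param n_genes Number of genes.
#' @param rng_seed Integer seed.
#' @param k_on_meanlog,k_on_sdlog,k_off_meanlog,k_off_sdlog,scale_meanlog,scale_sdlog
#'   Log-normal hyper-parameters of the three kinetic rates.
#' @return Data frame with columns `gene_id`, `k_on`, `k_off`, `scale`.
#' @export
sample_kinetics <- function(n_genes, rng_seed = 1L,
                            k_on_meanlog = log(0.5), k_on_sdlog = 1,
                            k_off_meanlog = log(1), k_off_sdlog = 1,
                            scale_meanlog = log(50), scale_sdlog = 1.5) {
  set.seed(substream_seed(rng_seed, "kinetics"))
  data.frame(
    gene_id = paste0("gene_", seq_len(n_genes)),
    k_on = stats::rlnorm(n_genes, k_on_meanlog, k_on_sdlog),
    k_off = stats::rlnorm(n_genes, k_off_meanlog, k_off_sdlog),
    scale = stats::rlnorm(n_genes, scale_meanlog, scale_sdlog),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-cell pre-mRNA counts from burst kinetics
#'
#' Beta-Poisson sampling per cell and gene: `X_ig ~ Poisson(scale_g * B_ig)`
#' with `B_ig ~ Beta(k_on_g, k_off_g)`. This reproduces the over-dispersed,
#' bursty count behaviour needed by the splicing simulation without any
#' external expression simulator.
#'
#' @param kinetics Data frame from [sample_kinetics()] (columns `gene_id`,
#'   `k_on`, `k_off`, `scale`; all strictly positive).
#' @param n_cells Number of cells (>= 1).
#' @param rng_seed Integer seed.
#' @return Integer matrix, cells x genes, with dimnames.
#' @export
simulate_expression <- function(kinetics, n_cells, rng_seed = 1L) {
  if (!is.data.frame(kinetics) || nrow(kinetics) == 0L)
    stop("kinetics must be a non-empty data frame")
  if (any(kinetics$k_on <= 0 | kinetics$k_off <= 0 | kinetics$scale < 0))
    stop("kinetic parameters must be positive (scale may be zero)")
  stopifnot(n_cells >= 1)
  set.seed(substream_seed(rng_seed, "expression"))
  n_genes <- nrow(kinetics)
  n <- n_cells * n_genes
  burst <- stats::rbeta(n, rep(kinetics$k_on, each = n_cells),
                        rep(kinetics$k_off, each = n_cells))
  x <- stats::rpois(n, rep(kinetics$scale, each = n_cells) * burst)
  m <- matrix(as.integer(x), nrow = n_cells, ncol = n_genes,
              dimnames = list(paste0("cell_", seq_len(n_cells)), kinetics$gene_id))
  m
}

#' Build a fixed-expression count matrix (expression override)
#'
#' Simulator variant in which gene `g` has constant expression `levels[g]`
#' in every cell; used to sweep the effect of the absolute mRNA count on the
#' observed splicing estimate.
#'
#' @param levels Integer vector of per-gene expression levels.
#' @param n_cells Number of cells.
#' @return Integer matrix, cells x genes.
#' @export
fixed_expression <- function(levels, n_cells) {
  stopifnot(all(levels >= 0), n_cells >= 1)
  m <- matrix(rep(as.integer(levels), each = n_cells), nrow = n_cells,
              dimnames = list(paste0("cell_", seq_len(n_cells)),
                              paste0("gene_", seq_along(levels))))
  m
}
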