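#' Splicing regimes for simulated cassette exons
#'
#' The across-cell distribution of an exon's underlying splicing rate
#' \eqn{\Psi_{ij}} is Beta(\eqn{\alpha_j, \beta_j}); the shape parameters
#' determine the regime:
#' \itemize{
#'   \item `bimodal`: \eqn{\alpha, \beta < 1}, modes at 0 and 1 (binary-bimodal
#'     splicing: both isoforms in the population, rarely in the same cell);
#'   \item `unimodal`: \eqn{\alpha, \beta > 1}, interior mode (cells co-express
#'     both isoforms);
#'   \item `included`: \eqn{\alpha \ge 1 > \beta}, mode 1 (near-constitutive
#'     inclusion);
#'   \item `excluded`: \eqn{\alpha < 1 \le \beta}, mode 0.
#' }
#' @name splicing-regimes
NULL

SPLICE_REGIMES <- c("bimodal", "unimodal", "included", "excluded")

#' Default isoform length configuration
#'
#' Lengths are log-normal stand-ins matching typical human transcript and
#' skipped-exon length scales: the exclusion isoform length `lgB` ~
#' LogNormal(log 1900, 0.6) clipped to `[200, 20000]` nt and the skipped exon
#' length `leA` ~ LogNormal(log 120, 0.5) clipped to `[25, 2000]` nt, rounded
#' to integers. The inclusion isoform length is `lgA = lgB + leA`.
#'
#' @return A list of length-distribution parameters.
#' @export
default_length_config <- function() {
  list(
    lgB_meanlog = log(1900), lgB_sdlog = 0.6, lgB_range = c(200, 20000),
    leA_meanlog = log(120),  leA_sdlog = 0.5, leA_range = c(25, 2000)
  )
}

draw_lengths <- function(n, cfg) {
  lgB <- round(pmin(pmax(stats::rlnorm(n, cfg$lgB_meanlog, cfg$lgB_sdlog),
                         cfg$lgB_range[1]), cfg$lgB_range[2]))
  leA <- round(pmin(pmax(stats::rlnorm(n, cfg$leA_meanlog, cfg$leA_sdlog),
                         cfg$leA_range[1]), cfg$leA_range[2]))
  list(exclusion_length = lgB, exon_length = leA, inclusion_length = lgB + leA)
}

draw_shapes <- function(n, regime) {
  switch(regime,
    bimodal  = list(alpha = 1 / stats::runif(n, 1, 30),
                    beta  = 1 / stats::runif(n, 1, 30)),
    unimodal = list(alpha = stats::runif(n, 1, 30),
                    beta  = stats::runif(n, 1, 30)),
    included = list(alpha = stats::runif(n, 1, 30),
                    beta  = 1 / stats::runif(n, 1, 5)),
    excluded = list(alpha = 1 / stats::runif(n, 1, 5),
                    beta  = stats::runif(n, 1, 30)),
    stop("unknown regime: ", regime)
  )
}

#' Sample exon models (Beta shape parameters and isoform lengths)
#'
#' Draws one cassette exon per gene. Shape parameters follow the regime laws
#' (see [splicing-regimes]): bimodal shapes are reciprocals of Uniform(1, 30)
#' draws, unimodal shapes Uniform(1, 30) draws, and included/excluded use the
#' asymmetric Uniform(1, 30) / 1/Uniform(1, 5) laws. Lengths come from
#' [default_length_config()] unless overridden.
#'
#' @param n_per_regime Named integer vector/list, e.g.
#'   `c(bimodal = 500, included = 500, excluded = 500)`.
#' @param length_config Length-distribution parameters; see
#'   [default_length_config()]. A data frame with columns `exclusion_length`
#'   and `exon_length` may be supplied instead to use an external length table
#'   (sampled without replacement).
#' @param rng_seed Integer seed.
#' @return A data frame with one row per exon: `exon_id`, `gene_id`, `alpha`,
#'   `beta`, `regime`, `exclusion_length`, `exon_length`, `inclusion_length`.
#' @export
sample_exon_models <- function(n_per_regime, length_config = default_length_config(),
                               rng_seed = 1L) {
  n_per_regime <- unlist(n_per_regime)
  if (is.null(names(n_per_regime)) || !all(names(n_per_regime) %in% SPLICE_REGIMES))
    stop("n_per_regime must be named with regimes: ",
         paste(SPLICE_REGIMES, collapse = ", "))
  if (any(n_per_regime < 0)) stop("regime counts must be non-negative")
  use_table <- is.data.frame(length_config)
  if (!use_table &&
      (any(unlist(length_config[c("lgB_range", "leA_range")]) <= 0)))
    stop("length distribution parameters must be positive")

  set.seed(substream_seed(rng_seed, "exon_models"))
  total <- sum(n_per_regime)
  if (total == 0L) {
    return(data.frame(exon_id = character(), gene_id = character(),
                      alpha = numeric(), beta = numeric(), regime = character(),
                      exclusion_length = integer(), exon_length = integer(),
                      inclusion_length = integer(), stringsAsFactors = FALSE))
  }
  regime <- rep(names(n_per_regime), times = n_per_regime)
  shapes <- lapply(names(n_per_regime), function(r)
    draw_shapes(n_per_regime[[r]], r))
  alpha <- unlist(lapply(shapes, `[[`, "alpha"))
  beta  <- unlist(lapply(shapes, `[[`, "beta"))
  if (use_table) {
    if (!all(c("exclusion_length", "exon_length") %in% names(length_config)))
      stop("length table needs columns exclusion_length and exon_length")
    idx <- sample(nrow(length_config), total, replace = nrow(length_config) < total)
    lens <- list(exclusion_length = length_config$exclusion_length[idx],
                 exon_length = length_config$exon_length[idx])
    lens$inclusion_length <- lens$exclusion_length + lens$exon_length
  } else {
    lens <- draw_lengths(total, length_config)
  }
  data.frame(
    exon_id = paste0("exon_", seq_len(total)),
    gene_id = paste0("gene_", seq_len(total)),
    alpha = alpha, beta = beta, regime = regime,
    exclusion_length = as.integer(lens$exclusion_length),
    exon_length = as.integer(lens$exon_length),
    inclusion_length = as.integer(lens$inclusion_length),
    stringsAsFactors = FALSE
  )
}

#' Validate an exon-model table
#'
#' Checks positivity of shapes, the length identity
#' `inclusion_length = exclusion_length + exon_length`, and regime/shape
#' consistency.
#'
#' @param exons Data frame from [sample_exon_models()].
#' @return Invisibly `exons`; stops on violation.
#' @export
validate_exon_models <- function(exons) {
  stopifnot(is.data.frame(exons))
  if (nrow(exons) == 0L) return(invisible(exons))
  if (any(exons$alpha <= 0 | exons$beta <= 0))
    stop("Beta shape parameters must be strictly positive")
  if (any(exons$inclusion_length != exons$exclusion_length + exons$exon_length))
    stop("inclusion_length must equal exclusion_length + exon_length")
  ok <- rep(TRUE, nrow(exons))
  ok[exons$regime == "bimodal"]  <- with(exons[exons$regime == "bimodal", ],
                                         alpha < 1 & beta < 1)
  ok[exons$regime == "unimodal"] <- with(exons[exons$regime == "unimodal", ],
                                         alpha > 1 & beta > 1)
  ok[exons$regime == "included"] <- with(exons[exons$regime == "included", ],
                                         alpha >= 1 & beta < 1)
  ok[exons$regime == "excluded"] <- with(exons[exons$regime == "excluded", ],
                                         alpha < 1 & beta >= 1)
  if (!all(ok)) stop("regime/shape inconsistency in rows: ",
                     paste(which(!ok), collapse = ", "))
  invisible(exons)
}
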