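#' Configuration for an end-to-end splicing simulation
#'
#' Defaults reproduce the reference design: 300 cells and 1500 genes, of which
#' 500 exons are alternatively spliced (bimodal or unimodal regime), 500 are
#' near-constitutively included and 500 near-constitutively excluded, with
#' mean capture efficiency 0.1.
#'
#' @param n_cells Number of cells.
#' @param regime Regime of the 500 alternatively spliced exons, `"bimodal"`
#'   or `"unimodal"`.
#' @param n_per_regime Named counts per regime; overrides `regime` if given.
#' @param tech A [tech_params()] object.
#' @param kinetics Optional kinetics data frame; sampled with
#'   [sample_kinetics()] defaults when `NULL`.
#' @param length_config See [sample_exon_models()].
#' @param fixed_psi,fixed_ratio Splicing overrides, see
#'   [sample_true_splicing()].
#' @param expression_override Optional integer vector of fixed per-gene
#'   expression levels (replaces kinetic expression).
#' @param seed Top-level integer seed (mandatory for reproducibility).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cells = 300L, regime = c("bimodal", "unimodal"),
                       n_per_regime = NULL, tech = tech_params(),
                       kinetics = NULL, length_config = default_length_config(),
                       fixed_psi = NULL, fixed_ratio = FALSE,
                       expression_override = NULL, seed = 1L) {
  if (is.null(n_per_regime)) {
    regime <- match.arg(regime)
    n_per_regime <- stats::setNames(c(500L, 500L, 500L),
                                    c(regime, "included", "excluded"))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(n_cells = as.integer(n_cells), n_per_regime = n_per_regime,
                 tech = tech, kinetics = kinetics,
                 length_config = length_config, fixed_psi = fixed_psi,
                 fixed_ratio = fixed_ratio,
                 expression_override = expression_override,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Run the full splicing simulation pipeline
#'
#' Chains the biological stage (exon models, expression, splicing) and the
#' technical stage (capture, read generation, junction subsampling), keeping
#' every intermediate matrix. All randomness derives from `config$seed`
#' through named substreams, so identical configurations give bit-identical
#' results.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `splice_sim`: list with `exons`, `kinetics`,
#'   `state` (`splicing_state`), `captured`, `reads`, `junctions`
#'   (`junction_reads`), `config` and a `provenance` record.
#' @export
run_simulation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  exons <- sample_exon_models(config$n_per_regime, config$length_config, seed)
  n_genes <- nrow(exons)
  if (!is.null(config$expression_override)) {
    lev <- config$expression_override
    if (length(lev) != n_genes)
      stop("expression_override must supply one level per gene")
    if (config$fixed_ratio) lev <- 2L * as.integer(round(lev / 2)) # even split
    X <- fixed_expression(lev, config$n_cells)
    kinetics <- NULL
  } else {
    kinetics <- config$kinetics
    if (is.null(kinetics)) kinetics <- sample_kinetics(n_genes, seed)
    if (nrow(kinetics) != n_genes)
      stop("kinetics must supply one row per gene")
    X <- simulate_expression(kinetics, config$n_cells, seed)
    if (config$fixed_ratio) {
      X <- matrix(2L * as.integer(round(X / 2)), nrow = config$n_cells,
                  dimnames = dimnames(X))
    }
  }
  colnames(X) <- exons$gene_id
  state <- sample_true_splicing(exons, X, seed,
                                fixed_psi = config$fixed_psi,
                                fixed_ratio = config$fixed_ratio)
  captured <- capture_molecules(state, config$tech, seed)
  reads <- generate_reads(captured, exons, config$tech, seed)
  junctions <- sample_junction_reads(reads, exons, config$tech, seed)
  structure(list(exons = exons, kinetics = kinetics, state = state,
                 captured = captured, reads = reads, junctions = junctions,
                 config = config,
                 provenance = provenance_record(config)),
            class = "splice_sim")
}

#' @export
print.splice_sim <- function(x, ...) {
  jr <- x$junctions
  cat("<splice_sim> ", nrow(jr$psi_hat), " cells x ", ncol(jr$psi_hat),
      " exons\n", sep = "")
  cat("  regimes: ", paste(sprintf("%s=%d", names(x$config$n_per_regime),
                                   x$config$n_per_regime), collapse = ", "),
      "\n", sep = "")
  cat("  capture mean ", x$config$tech$capture_mean,
      ", depth ", x$config$tech$depth_factor, " reads/molecule/kb\n", sep = "")
  obs <- !is.na(jr$psi_hat)
  cat(sprintf("  observed Psi-hat: %.1f%% non-missing, %.1f%% binary among observed\n",
              100 * mean(obs),
              100 * mean(jr$psi_hat[obs] %in% c(0, 1))))
  invisible(x)
}

#' @export
summary.splice_sim <- function(object, ...) {
  jr <- object$junctions
  obs <- !is.na(jr$psi_hat)
  per_regime <- vapply(split(seq_len(ncol(jr$psi_hat)), object$exons$regime),
                       function(idx) {
                         v <- jr$psi_hat[, idx]
                         mean(v[!is.na(v)] %in% c(0, 1))
                       }, numeric(1))
  out <- list(
    n_cells = nrow(jr$psi_hat), n_exons = ncol(jr$psi_hat),
    mean_true_counts = mean(object$state$true_counts),
    mean_junction_reads = mean(jr$SJ),
    frac_missing = mean(!obs),
    binary_by_regime = per_regime
  )
  class(out) <- "summary.splice_sim"
  out
}

#' @export
print.summary.splice_sim <- function(x, ...) {
  cat("Splicing simulation summary\n")
  cat(sprintf("  %d cells x %d exons; mean true counts %.1f; mean SJ reads %.2f\n",
              x$n_cells, x$n_exons, x$mean_true_counts, x$mean_junction_reads))
  cat(sprintf("  missing observations: %.1f%%\n", 100 * x$frac_missing))
  cat("  binary fraction among observed, by regime:\n")
  for (r in names(x$binary_by_regime))
    cat(sprintf("    %-9s %.3f\n", r, x$binary_by_regime[[r]]))
  invisible(x)
}

provenance_record <- function(config) {
  list(
    package = "scpsi",
    version = as.character(utils::packageVersion("scpsi")),
    seed = config$seed,
    substreams = vapply(c("exon_models", "kinetics", "expression", "psi",
                          "capture", "reads", "junctions"),
                        function(s) substream_seed(config$seed, s), integer(1)),
    n_cells = config$n_cells,
    n_per_regime = config$n_per_regime,
    capture_mean = config$tech$capture_mean,
    capture_variance = config$tech$capture_variance,
    read_length = config$tech$read_length,
    depth_factor = config$tech$depth_factor,
    amp_bias_halflength = config$tech$amp_bias_halflength %||% NA,
    junction_weighting = config$tech$junction_weighting,
    fixed_psi = config$fixed_psi %||% NA,
    fixed_ratio = config$fixed_ratio
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
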