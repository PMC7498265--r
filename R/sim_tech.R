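#' Technical-process parameters
#'
#' @param capture_mean Mean mRNA capture efficiency `c` in (0, 1]. A captured
#'   molecule is one successfully converted to sequenceable cDNA; full-length
#'   single-cell protocols are commonly near 0.1.
#' @param capture_variance Variance of the per-cell/per-isoform capture
#'   probability (normal truncated to `[0, 1]`); default 0.002.
#' @param read_length Read length `lr` in nt (>= 2).
#' @param depth_factor Expected reads per captured molecule per kb of
#'   transcript.
#' @param amp_bias_halflength Length scale (nt) of an optional exponential
#'   amplification bias `2^(-l / halflength)`, normalized to 1 at the median
#'   isoform length; `NULL` (default) disables the bias.
#' @param junction_weighting How observed Psi-hat is computed from junction
#'   reads: `"simulated"` uses `SJA / (SJA + SJB)`; `"halved_exclusion"` uses
#'   `SJA / (SJA + 2 * SJB)`, which accounts for the inclusion isoform carrying
#'   two informative junctions.
#' @return A list of class `tech_params`.
#' @export
tech_params <- function(capture_mean = 0.1, capture_variance = 0.002,
                        read_length = 50L, depth_factor = 5,
                        amp_bias_halflength = NULL,
                        junction_weighting = c("simulated", "halved_exclusion")) {
  stopifnot(capture_mean > 0, capture_mean <= 1, capture_variance >= 0,
            read_length >= 2, depth_factor >= 0)
  structure(list(capture_mean = capture_mean,
                 capture_variance = capture_variance,
                 read_length = as.integer(read_length),
                 depth_factor = depth_factor,
                 amp_bias_halflength = amp_bias_halflength,
                 junction_weighting = match.arg(junction_weighting)),
            class = "tech_params")
}

#' Simulate mRNA capture into cDNA
#'
#' Each cell x isoform entry receives its own capture probability drawn from a
#' normal with mean `capture_mean` and variance `capture_variance`, truncated
#' to `[0, 1]`; the captured molecule count is a binomial sample of the true
#' isoform count with that probability.
#'
#' @param state A `splicing_state` from [sample_true_splicing()].
#' @param params A [tech_params()] object.
#' @param rng_seed Integer seed.
#' @return List of class `captured_counts` with integer matrices `CA`, `CB`
#'   (captured inclusion/exclusion molecules, cells x exons) and the capture
#'   probability matrices `cA`, `cB`.
#' @export
capture_molecules <- function(state, params = tech_params(), rng_seed = 1L) {
  stopifnot(inherits(state, "splicing_state"))
  set.seed(substream_seed(rng_seed, "capture"))
  n <- length(state$XA)
  dn <- dimnames(state$XA)
  cA <- matrix(rtruncnorm01(n, params$capture_mean, params$capture_variance),
               nrow(state$XA), dimnames = dn)
  cB <- matrix(rtruncnorm01(n, params$capture_mean, params$capture_variance),
               nrow(state$XA), dimnames = dn)
  CA <- matrix(stats::rbinom(n, as.vector(state$XA), as.vector(cA)),
               nrow(state$XA), dimnames = dn)
  CB <- matrix(stats::rbinom(n, as.vector(state$XB), as.vector(cB)),
               nrow(state$XA), dimnames = dn)
  structure(list(CA = CA, CB = CB, cA = cA, cB = cB), class = "captured_counts")
}

## length-dependent amplification bias, normalized to 1 at the median length
amp_bias <- function(lengths, halflength, ref_length = stats::median(lengths)) {
  if (is.null(halflength)) return(rep(1, length(lengths)))
  2^(-(lengths - ref_length) / halflength)
}

#' Simulate read generation from captured molecules
#'
#' Reads per isoform are Poisson with rate
#' `C * depth_factor * (l / 1000) * bias(l)`: read counts grow with molecule
#' number and transcript length, with an optional exponential length bias
#' standing in for amplification effects. Reads are exactly zero where no
#' molecule was captured.
#'
#' @param captured A `captured_counts` object.
#' @param exons Exon-model data frame (isoform lengths).
#' @param params A [tech_params()] object.
#' @param rng_seed Integer seed.
#' @return List of class `read_counts` with integer matrices `RA`, `RB`.
#' @export
generate_reads <- function(captured, exons, params = tech_params(), rng_seed = 1L) {
  stopifnot(inherits(captured, "captured_counts"))
  if (any(exons$inclusion_length <= 0 | exons$exclusion_length <= 0))
    stop("isoform lengths must be positive")
  set.seed(substream_seed(rng_seed, "reads"))
  n_cells <- nrow(captured$CA)
  all_len <- c(exons$inclusion_length, exons$exclusion_length)
  biasA <- amp_bias(exons$inclusion_length, params$amp_bias_halflength,
                    stats::median(all_len))
  biasB <- amp_bias(exons$exclusion_length, params$amp_bias_halflength,
                    stats::median(all_len))
  rateA <- captured$CA * params$depth_factor *
    rep(exons$inclusion_length / 1000 * biasA, each = n_cells)
  rateB <- captured$CB * params$depth_factor *
    rep(exons$exclusion_length / 1000 * biasB, each = n_cells)
  dn <- dimnames(captured$CA)
  RA <- matrix(stats::rpois(length(rateA), as.vector(rateA)), n_cells,
               dimnames = dn)
  RB <- matrix(stats::rpois(length(rateB), as.vector(rateB)), n_cells,
               dimnames = dn)
  structure(list(RA = RA, RB = RB), class = "read_counts")
}

#' Per-exon splice-junction coverage probabilities
#'
#' A read maps to `2 * (lr - 1)` positions overlapping one given junction, so
#' the probability of covering the two inclusion-informative junctions is
#' `jA = 4 * (lr - 1) / lgA` and of the single exclusion junction
#' `jB = 2 * (lr - 1) / lgB`.
#'
#' @param exons Exon-model data frame.
#' @param read_length Read length in nt.
#' @return Data frame with `exon_id`, `jA`, `jB`.
#' @export
junction_probabilities <- function(exons, read_length) {
  jA <- 4 * (read_length - 1) / exons$inclusion_length
  jB <- 2 * (read_length - 1) / exons$exclusion_length
  bad <- which(jA >= 1 | jB >= 1)
  if (length(bad))
    stop("junction coverage probability >= 1 for exon(s): ",
         paste(exons$exon_id[bad], collapse = ", "),
         " (isoform shorter than the informative window)")
  data.frame(exon_id = exons$exon_id, jA = jA, jB = jB,
             stringsAsFactors = FALSE)
}

#' Subsample splice-junction reads and compute observed Psi-hat
#'
#' Junction reads are binomial subsamples of the isoform reads with the
#' coverage probabilities of [junction_probabilities()]. The observed splicing
#' estimate is `SJA / (SJA + SJB)` (`junction_weighting = "simulated"`) or the
#' junction-count-aware `SJA / (SJA + 2 * SJB)` (`"halved_exclusion"`), and is
#' missing (NA) where `SJA + SJB = 0`.
#'
#' @param reads A `read_counts` object.
#' @param exons Exon-model data frame.
#' @param params A [tech_params()] object.
#' @param rng_seed Integer seed.
#' @return List of class `junction_reads` with matrices `SJA`, `SJB`, `SJ`
#'   (total) and `psi_hat`.
#' @export
sample_junction_reads <- function(reads, exons, params = tech_params(),
                                  rng_seed = 1L) {
  stopifnot(inherits(reads, "read_counts"))
  jp <- junction_probabilities(exons, params$read_length)
  set.seed(substream_seed(rng_seed, "junctions"))
  n_cells <- nrow(reads$RA)
  dn <- dimnames(reads$RA)
  SJA <- matrix(stats::rbinom(length(reads$RA), as.vector(reads$RA),
                              rep(jp$jA, each = n_cells)), n_cells, dimnames = dn)
  SJB <- matrix(stats::rbinom(length(reads$RB), as.vector(reads$RB),
                              rep(jp$jB, each = n_cells)), n_cells, dimnames = dn)
  SJ <- SJA + SJB
  psi_hat <- psi_from_junction_counts(SJA, SJB, params$junction_weighting)
  structure(list(SJA = SJA, SJB = SJB, SJ = SJ, psi_hat = psi_hat,
                 junction_weighting = params$junction_weighting),
            class = "junction_reads")
}

#' Observed Psi-hat from inclusion/exclusion junction read counts
#'
#' @param SJA,SJB Non-negative inclusion/exclusion junction read counts
#'   (vectors or matrices of equal shape).
#' @param weighting `"simulated"`: `SJA / (SJA + SJB)`; `"halved_exclusion"`:
#'   `SJA / (SJA + 2 * SJB)` (one informative junction per exclusion molecule
#'   vs two per inclusion molecule).
#' @return Psi-hat of the same shape, NA where no junction read was observed.
#' @export
psi_from_junction_counts <- function(SJA, SJB,
                                     weighting = c("simulated", "halved_exclusion")) {
  weighting <- match.arg(weighting)
  if (any(SJA < 0, na.rm = TRUE) || any(SJB < 0, na.rm = TRUE))
    stop("junction read counts must be non-negative")
  denom <- if (weighting == "simulated") SJA + SJB else SJA + 2 * SJB
  out <- ifelse(SJA + SJB > 0, SJA / denom, NA_real_)
  if (is.matrix(SJA)) dimnames(out) <- dimnames(SJA)
  out
}
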