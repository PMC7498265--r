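#' Closed-form observation model for splicing under limited capture
#'
#' These functions quantify how far an observed splicing estimate
#' \eqn{\hat\Psi = a / r} (a of r captured molecules carry the inclusion
#' isoform) can stray from the true rate \eqn{\Psi} when a gene expresses `m`
#' molecules and each is captured independently with probability `c`.
#' Sampling without replacement of `r` molecules from `m` (with
#' \eqn{m\Psi} inclusion molecules) gives a hypergeometric law; the unknown
#' `m` can be marginalized under a uniform prior using the binomial capture
#' likelihood, whose normalization over `m >= r` equals `1/c` exactly.
#'
#' @name observation-theory
NULL

## Inclusion-molecule counts for a (possibly non-integer) m * psi, with a
## weight for each candidate split. Non-integer values round to the nearest
## integer; an exact half-integer averages the floor and ceiling splits with
## weight 1/2 each -- the unique choice that keeps the distributions at psi
## and 1 - psi exact mirror images (including psi = 0.5 with odd m, where no
## single deterministic split can be self-symmetric).
inclusion_count <- function(psi, m, round_mpsi = FALSE) {
  x <- round(psi * m, 9)   # snap floating-point representation error
  if (!round_mpsi && !is_whole(x))
    stop("m * psi is not an integer; use round_mpsi = TRUE to opt in to ",
         "nearest-integer rounding")
  if (abs(x - floor(x) - 0.5) < 1e-9)
    list(mA = c(floor(x), floor(x) + 1), weight = c(0.5, 0.5))
  else
    list(mA = round(x), weight = 1)
}

## Hypergeometric composition probabilities over a = 0:r, averaging tied
## splits of m * psi
hyper_probs <- function(psi, m, r, round_mpsi = FALSE) {
  ic <- inclusion_count(psi, m, round_mpsi)
  a <- 0:r
  out <- numeric(r + 1)
  for (k in seq_along(ic$mA)) {
    mA <- ic$mA[k]
    out <- out + ic$weight[k] *
      exp(lchoose(mA, a) + lchoose(m - mA, r - a) - lchoose(m, r))
  }
  out
}

#' Distribution of the observed splicing estimate given m and r
#'
#' `Pr(Psi-hat | Psi, r, m)`: hypergeometric sampling without replacement of
#' `r` captured molecules from `m`, of which `m * Psi` carry the inclusion
#' isoform. Support is `Psi-hat = a / r`, `a = 0..r`.
#'
#' @param psi True splicing rate in `[0, 1]`; `m * psi` must be an integer
#'   unless `round_mpsi = TRUE`.
#' @param r Number of captured molecules, `1 <= r <= m`.
#' @param m Total molecules of the gene in the cell.
#' @param round_mpsi Opt in to nearest-integer rounding of `m * psi`.
#' @return Data frame with columns `psi_hat` and `prob` (sums to 1).
#' @export
psi_hat_pmf_given_m_r <- function(psi, r, m, round_mpsi = FALSE) {
  stopifnot(psi >= 0, psi <= 1, r >= 1, r <= m)
  data.frame(psi_hat = (0:r) / r, prob = hyper_probs(psi, m, r, round_mpsi))
}

#' Posterior probability of the molecule count given capture
#'
#' `Pr(m | r, c) = C(m, r) c^(r+1) (1 - c)^(m - r)` under a uniform prior on
#' `m`: the binomial capture likelihood `Pr(r | c, m)` normalized by the
#' closed-form evidence `1/c` (see [capture_evidence_sum()]).
#'
#' @param m Molecule counts (vectorized), `m >= r`.
#' @param r Captured molecules.
#' @param c Capture efficiency in (0, 1]; 0 gives an improper posterior.
#' @return Posterior probabilities, 0 where `m < r`.
#' @export
posterior_m_given_r_c <- function(m, r, c) {
  if (c <= 0) stop("capture efficiency must be positive (improper posterior at c = 0)")
  stopifnot(c <= 1, r >= 0)
  out <- exp(lchoose(m, r) + (r + 1) * log(c) + log1mc_pow(m - r, c))
  out[m < r] <- 0
  out
}

## k * log(1 - c), with the k = 0, c = 1 corner defined as 0
log1mc_pow <- function(k, c) {
  out <- k * log1p(-c)
  out[k == 0] <- 0
  out
}

#' Numeric check of the capture-evidence identity
#'
#' Sums the binomial capture likelihood `Pr(r | c, m) = C(m, r) c^r (1-c)^(m-r)`
#' over `m >= r` with adaptive truncation; the closed form of this series is
#' exactly `1/c`.
#'
#' @param r Captured molecules.
#' @param c Capture efficiency in (0, 1].
#' @param rel_tol Relative tail tolerance for truncation.
#' @return The numeric sum (approximately `1/c`).
#' @export
capture_evidence_sum <- function(r, c, rel_tol = 1e-10) {
  stopifnot(c > 0, c <= 1, r >= 0)
  total <- 0
  m0 <- r
  block <- max(64L, ceiling(4 * r / c))
  repeat {
    m <- m0:(m0 + block - 1L)
    terms <- exp(lchoose(m, r) + r * log(c) + log1mc_pow(m - r, c))
    total <- total + sum(terms)
    # geometric tail bound: terms eventually decay faster than (1-c)
    if (terms[block] / (1 - (1 - c)) < rel_tol * total || c == 1) break
    m0 <- m0 + block
  }
  total
}

#' Distribution of the observed splicing estimate with m marginalized
#'
#' `Pr(Psi-hat | Psi, r, c)`: the hypergeometric law of
#' [psi_hat_pmf_given_m_r()] marginalized over the molecule count `m` with
#' posterior [posterior_m_given_r_c()], truncating the sum at
#' `ceiling(cap_multiplier * r / c)` (the posterior mean of `m` is about
#' `r / c`; ten times that is the default cap).
#'
#' @inheritParams psi_hat_pmf_given_m_r
#' @param c Capture efficiency in (0, 1].
#' @param cap_multiplier Truncation cap as a multiple of `r / c`.
#' @param round_mpsi Rounding mode for non-integer `m * psi` inside the sum
#'   (default `TRUE`: marginalization cannot guarantee integrality).
#' @return Data frame with `psi_hat = a / r` and `prob`; the attribute
#'   `"mass"` records the (near-1) truncated posterior mass.
#' @export
psi_hat_pmf_given_r_c <- function(psi, r, c, cap_multiplier = 10,
                                  round_mpsi = TRUE) {
  stopifnot(psi >= 0, psi <= 1, r >= 1, c > 0, c <= 1)
  m_max <- max(r, ceiling(cap_multiplier * r / c))
  ms <- r:m_max
  w <- posterior_m_given_r_c(ms, r, c)
  prob <- numeric(r + 1)
  for (k in seq_along(ms))
    prob <- prob + w[k] * hyper_probs(psi, ms[k], r, round_mpsi)
  out <- data.frame(psi_hat = (0:r) / r, prob = prob)
  attr(out, "mass") <- sum(w)
  out
}

#' Probability that the observed estimate is within delta of the truth
#'
#' `Pr(|Psi-hat - Psi| < delta | Psi, r, c)`, a monotone non-decreasing
#' function of `delta`, computed from [psi_hat_pmf_given_r_c()].
#'
#' @inheritParams psi_hat_pmf_given_r_c
#' @param delta Tolerance in (0, 1].
#' @return A probability.
#' @export
prob_within_delta <- function(psi, r, c, delta, cap_multiplier = 10,
                              round_mpsi = TRUE) {
  stopifnot(delta > 0, delta <= 1)
  pmf <- psi_hat_pmf_given_r_c(psi, r, c, cap_multiplier, round_mpsi)
  sum(pmf$prob[abs(pmf$psi_hat - psi) < delta + 1e-12])
}

#' Distribution of the observed estimate given m, c and detection
#'
#' `Pr(Psi-hat | Psi, c, m, d)`: the number of captured molecules `r` is
#' marginalized from 1 to `m` (binomial capture), conditioned on the gene
#' being detected at all, `Pr(d | c, m) = 1 - (1 - c)^m`. The support pools
#' all achievable fractions `a / r`.
#'
#' @inheritParams psi_hat_pmf_given_m_r
#' @param c Capture efficiency in (0, 1].
#' @return Data frame with `psi_hat` (unique, sorted) and `prob`
#'   (sums to 1).
#' @export
psi_hat_pmf_given_m_c_detected <- function(psi, m, c, round_mpsi = FALSE) {
  stopifnot(psi >= 0, psi <= 1, m >= 1, c > 0, c <= 1)
  ic <- inclusion_count(psi, m, round_mpsi)
  vals <- numeric(0); keys <- numeric(0)
  for (r in 1:m) {
    a <- 0:r
    # the hypergeometric's 1/C(m,r) cancels against the binomial's C(m,r)
    pr <- 0
    for (k in seq_along(ic$mA)) {
      mA <- ic$mA[k]
      pr <- pr + ic$weight[k] *
        exp(lchoose(mA, a) + lchoose(m - mA, r - a) +
              r * log(c) + log1mc_pow(m - r, c))
    }
    keys <- c(keys, a / r)
    vals <- c(vals, pr)
  }
  key_r <- round(keys, 12)
  agg <- tapply(vals, key_r, sum)
  psi_hat <- as.numeric(names(agg))
  prob <- as.numeric(agg) / (1 - (1 - c)^m)
  ord <- order(psi_hat)
  data.frame(psi_hat = psi_hat[ord], prob = prob[ord])
}

#' Probability of a binary observation (only one isoform seen)
#'
#' Sums the probability of `Psi-hat` exactly 0 or exactly 1 under one of the
#' observation models.
#'
#' @param pmf A data frame with columns `psi_hat`, `prob` from any of the
#'   `psi_hat_pmf_*` functions.
#' @return A probability.
#' @export
binary_probability <- function(pmf) {
  sum(pmf$prob[pmf$psi_hat %in% c(0, 1)])
}
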