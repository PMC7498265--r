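test_that("hypergeometric observation pmf matches direct evaluation", {
  # m = 20, Psi = 0.5, r = 2: Pr(Psi-hat = 0.5) = 100/190, Pr(binary) = 90/190
  pmf <- psi_hat_pmf_given_m_r(0.5, 2, 20)
  expect_equal(sum(pmf$prob), 1)
  expect_equal(pmf$prob[pmf$psi_hat == 0.5], 100 / 190)
  expect_equal(binary_probability(pmf), 90 / 190)
  # degenerate composition: Psi = 1 forces Psi-hat = 1
  pmf1 <- psi_hat_pmf_given_m_r(1, 3, 12)
  expect_equal(pmf1$prob[pmf1$psi_hat == 1], 1)
  expect_equal(sum(pmf1$prob), 1)
  # non-integer m * Psi is an explicit opt-in
  expect_error(psi_hat_pmf_given_m_r(0.33, 2, 20), "round")
  expect_silent(psi_hat_pmf_given_m_r(0.33, 2, 20, round_mpsi = TRUE))
})

test_that("molecule-count posterior normalizes and the evidence equals 1/c", {
  # c = 1: point mass at m = r
  expect_equal(posterior_m_given_r_c(4, 4, 1), 1)
  expect_equal(posterior_m_given_r_c(5:10, 4, 1), rep(0, 6))
  # numeric summation oracle of the stated series
  expect_lt(abs(sum(posterior_m_given_r_c(5:2000, 5, 0.3)) - 1), 1e-9)
  expect_lt(abs(capture_evidence_sum(3, 0.1) - 10) / 10, 1e-6)
  expect_lt(abs(capture_evidence_sum(5, 0.3) - 1 / 0.3) * 0.3, 1e-6)
  expect_error(posterior_m_given_r_c(5, 2, 0), "improper")
})

test_that("marginalized pmf agrees with a Monte-Carlo oracle", {
  pmf <- psi_hat_pmf_given_r_c(0.5, 2, 0.1)
  expect_lt(abs(sum(pmf$prob) - 1), 1e-6)
  set.seed(1234)
  n <- 1e6
  m <- 2 + stats::rnbinom(n, size = 3, prob = 0.1)  # posterior of m given r=2
  mA <- round(0.5 * m)
  a <- stats::rhyper(n, mA, m - mA, 2)
  emp <- tabulate(a + 1L, 3L) / n
  expect_lt(sum(abs(pmf$prob - emp)) / 2, 0.005)   # total variation
  # degenerate: Psi = 0 puts all mass on 0
  p0 <- psi_hat_pmf_given_r_c(0, 4, 0.2)
  expect_equal(p0$prob[p0$psi_hat == 0], 1, tolerance = 1e-6)
})

test_that("truncation cap is insensitive beyond the default 10 r / c", {
  a <- psi_hat_pmf_given_r_c(0.5, 4, 0.15, cap_multiplier = 10)
  b <- psi_hat_pmf_given_r_c(0.5, 4, 0.15, cap_multiplier = 50)
  expect_lt(max(abs(a$prob - b$prob)), 1e-4)
})

test_that("within-delta probability is monotone with full support at delta 1", {
  expect_equal(prob_within_delta(0.3, 5, 0.1, 1), 1, tolerance = 1e-6)
  v1 <- prob_within_delta(0.5, 10, 0.1, 0.1)
  v2 <- prob_within_delta(0.5, 10, 0.1, 0.2)
  expect_gte(v2, v1)
  # Monte-Carlo oracle for the delta = 0.1 value
  set.seed(99)
  n <- 1e6
  m <- 10 + stats::rnbinom(n, size = 11, prob = 0.1)
  a <- stats::rhyper(n, round(0.5 * m), m - round(0.5 * m), 10)
  expect_lt(abs(v1 - mean(abs(a / 10 - 0.5) < 0.1 + 1e-12)), 0.005)
})

test_that("detected-gene pmf matches exhaustive enumeration over captures", {
  psi <- 0.5; m <- 20; c <- 0.1
  pmf <- psi_hat_pmf_given_m_c_detected(psi, m, c)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  # independent oracle: enumerate captured inclusion/exclusion molecule
  # compositions (rA, rB) with independent binomial capture per molecule
  mA <- psi * m; mB <- m - mA
  grid <- expand.grid(rA = 0:mA, rB = 0:mB)
  grid <- grid[grid$rA + grid$rB > 0, ]
  pr <- stats::dbinom(grid$rA, mA, c) * stats::dbinom(grid$rB, mB, c)
  key <- round(grid$rA / (grid$rA + grid$rB), 12)
  oracle <- tapply(pr, key, sum) / (1 - (1 - c)^m)
  got <- oracle[as.character(round(pmf$psi_hat, 12))]
  got[is.na(got)] <- 0   # support points the enumeration cannot reach
  expect_lt(max(abs(pmf$prob - got)), 1e-10)
  # single molecule is always binary; certain capture reduces to the r = m law
  expect_equal(binary_probability(psi_hat_pmf_given_m_c_detected(0.5, 1,
                                                                 0.2,
                                                                 round_mpsi = TRUE)),
               1)
  full <- psi_hat_pmf_given_m_c_detected(0.5, 10, 1)
  full <- full[full$prob > 1e-15, ]   # capture 1 leaves only the r = m layer
  ref <- psi_hat_pmf_given_m_r(0.5, 10, 10)
  ref <- ref[ref$prob > 1e-15, ]      # seeing all molecules is deterministic
  expect_equal(full$psi_hat, ref$psi_hat)
  expect_equal(full$prob, ref$prob, tolerance = 1e-12)
})

test_that("observation distributions mirror exactly under Psi -> 1 - Psi", {
  for (m in c(5, 20, 33)) for (psi in c(0.3, 0.25, 0.5)) {
    a <- psi_hat_pmf_given_r_c(psi, 3, 0.2, round_mpsi = TRUE)
    b <- psi_hat_pmf_given_r_c(1 - psi, 3, 0.2, round_mpsi = TRUE)
    expect_equal(a$prob, rev(b$prob), tolerance = 1e-12)
    d1 <- psi_hat_pmf_given_m_c_detected(psi, m, 0.15, round_mpsi = TRUE)
    d2 <- psi_hat_pmf_given_m_c_detected(1 - psi, m, 0.15, round_mpsi = TRUE)
    expect_equal(d1$prob, rev(d2$prob), tolerance = 1e-12)
  }
})

test_that("binary probability decreases with molecules and with capture", {
  bp_m <- sapply(c(2, 10, 20, 50, 100, 200), function(m)
    binary_probability(psi_hat_pmf_given_m_c_detected(0.5, m, 0.1)))
  expect_true(all(diff(bp_m) < 0))
  bp_c <- sapply(c(0.01, 0.05, 0.1, 0.3, 1), function(cc)
    binary_probability(psi_hat_pmf_given_m_c_detected(0.5, 20, cc)))
  expect_true(all(diff(bp_c) < 0))
})

test_that("theory tracks the simulator when junction capture is exhaustive", {
  # theory: binary probability for m = 20, Psi = 0.5, c = 0.1
  th <- binary_probability(psi_hat_pmf_given_m_c_detected(0.5, 20, 0.1))
  # simulator with no capture variance, no amplification bias and depth high
  # enough that every captured molecule yields junction reads
  tp <- tech_params(capture_mean = 0.1, capture_variance = 0,
                    depth_factor = 2000)
  cfg <- sim_config(n_cells = 8000, n_per_regime = c(unimodal = 1), tech = tp,
                    fixed_ratio = TRUE,
                    expression_override = 20L, seed = 21)
  sim <- run_simulation(cfg)
  ph <- sim$junctions$psi_hat
  emp <- mean(ph[!is.na(ph)] %in% c(0, 1))
  expect_lt(abs(emp - th), 0.03)
  # with realistic (lossy) junction sampling the binary rate can only grow
  tp2 <- tech_params(capture_mean = 0.1, capture_variance = 0, depth_factor = 5)
  sim2 <- run_simulation(sim_config(n_cells = 8000,
                                    n_per_regime = c(unimodal = 1), tech = tp2,
                                    fixed_ratio = TRUE,
                                    expression_override = 20L, seed = 22))
  ph2 <- sim2$junctions$psi_hat
  expect_gt(mean(ph2[!is.na(ph2)] %in% c(0, 1)), th)
})
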