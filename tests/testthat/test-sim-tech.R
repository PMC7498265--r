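test_that("perfect capture returns the true molecule counts", {
  st <- state_with_counts(XA = rep(7L, 20), XB = rep(5L, 20))
  cap <- capture_molecules(st, tiny_tech(capture_mean = 1), 1)
  expect_identical(cap$CA, st$XA)
  expect_identical(cap$CB, st$XB)
})

test_that("captured counts match the binomial mean oracle", {
  st <- state_with_counts(XA = rep(20L, 100000), XB = rep(0L, 100000))
  cap <- capture_molecules(st, tiny_tech(capture_mean = 0.1), 2)
  se <- stats::sd(cap$CA) / sqrt(length(cap$CA))
  expect_lt(abs(mean(cap$CA) - 2), 3 * se)
  expect_true(all(cap$CA <= st$XA))
})

test_that("capture probabilities are truncated-normal around the mean", {
  p <- rtruncnorm01(200000, 0.1, 0.002)
  expect_true(all(p >= 0 & p <= 1))
  # mean slightly above 0.1 because the mass below 0 is clipped
  expect_lt(abs(mean(p) - 0.1), 0.01)
  expect_lt(abs(stats::sd(p) - sqrt(0.002)), 0.01)
})

test_that("read generation follows the Poisson length model", {
  st <- state_with_counts(XA = rep(10L, 100000), XB = rep(0L, 100000),
                          exon = data.frame(exon_id = "e", gene_id = "g",
                                            alpha = 2, beta = 2,
                                            regime = "unimodal",
                                            exclusion_length = 900L,
                                            exon_length = 100L,
                                            inclusion_length = 1000L,
                                            stringsAsFactors = FALSE))
  cap <- capture_molecules(st, tiny_tech(capture_mean = 1), 1)
  # depth 0 -> no reads at all
  r0 <- generate_reads(cap, st$exons, tiny_tech(depth_factor = 0), 1)
  expect_true(all(r0$RA == 0) && all(r0$RB == 0))
  # C = 10, l = 1000 nt, depth 5/kb -> mean reads 50
  rd <- generate_reads(cap, st$exons, tiny_tech(depth_factor = 5), 3)
  se <- stats::sd(rd$RA) / sqrt(length(rd$RA))
  expect_lt(abs(mean(rd$RA) - 50), 3 * se)
  expect_true(all(rd$RA[cap$CA == 0] == 0))
})

test_that("amplification bias decays monotonically with length", {
  lens <- c(500, 1000, 3000, 8000)
  b <- scpsi:::amp_bias(lens, halflength = 3000, ref_length = 1000)
  expect_true(all(diff(b) < 0))
  expect_equal(b[2], 1)
  expect_equal(scpsi:::amp_bias(lens, NULL), rep(1, 4))
})

test_that("junction probabilities follow the positional formula", {
  ex <- data.frame(exon_id = "e", gene_id = "g", alpha = 1, beta = 1,
                   regime = "unimodal", exclusion_length = 1900L,
                   exon_length = 100L, inclusion_length = 2000L,
                   stringsAsFactors = FALSE)
  jp <- junction_probabilities(ex, 50L)
  expect_equal(jp$jA, 4 * 49 / 2000)   # 0.098
  expect_equal(jp$jB, 2 * 49 / 1900)
  short <- ex
  short$exclusion_length <- 60L
  short$inclusion_length <- 160L
  expect_error(junction_probabilities(short, 50L), "e")
})

test_that("junction read subsampling matches binomial means and Psi-hat rules", {
  # constant read counts via enormous depth would be slow; inject reads directly
  ex <- data.frame(exon_id = "e", gene_id = "g", alpha = 1, beta = 1,
                   regime = "unimodal", exclusion_length = 1960L,
                   exon_length = 100L, inclusion_length = 2060L,
                   stringsAsFactors = FALSE)
  n <- 50000
  reads <- structure(list(
    RA = matrix(1000L, n, 1, dimnames = list(NULL, "e")),
    RB = matrix(1000L, n, 1, dimnames = list(NULL, "e"))), class = "read_counts")
  jr <- sample_junction_reads(reads, ex, tiny_tech(read_length = 50L), 4)
  jA <- 4 * 49 / 2060; jB <- 2 * 49 / 1960
  expect_lt(abs(mean(jr$SJA) - 1000 * jA), 3 * stats::sd(jr$SJA) / sqrt(n))
  expect_lt(abs(mean(jr$SJB) - 1000 * jB), 3 * stats::sd(jr$SJB) / sqrt(n))
  expect_identical(jr$SJ, jr$SJA + jr$SJB)
  # Psi-hat mean close to the junction-share ratio under the printed weighting
  expect_lt(abs(mean(jr$psi_hat) - 1000 * jA / (1000 * jA + 1000 * jB)), 0.01)
})

test_that("Psi-hat weighting formulas and missingness rules hold", {
  SJA <- matrix(c(6L, 5L, 0L, 0L), 2)
  SJB <- matrix(c(3L, 0L, 0L, 4L), 2)
  expect_equal(psi_from_junction_counts(SJA, SJB, "simulated"),
               matrix(c(6 / 9, 1, NA, 0), 2))
  expect_equal(psi_from_junction_counts(SJA, SJB, "halved_exclusion"),
               matrix(c(0.5, 1, NA, 0), 2))
  expect_error(psi_from_junction_counts(-1L, 2L), "non-negative")
})

test_that("end-to-end simulation keeps intermediates and reproduces exactly", {
  cfg <- sim_config(n_cells = 30, n_per_regime = c(unimodal = 40), seed = 77)
  sim <- run_simulation(cfg)
  expect_s3_class(sim, "splice_sim")
  expect_equal(dim(sim$junctions$psi_hat), c(30, 40))
  expect_identical(unname(sim$state$XA + sim$state$XB),
                   unname(sim$state$true_counts))
  expect_true(all(is.na(sim$junctions$psi_hat) == (sim$junctions$SJ == 0)))
  sim2 <- run_simulation(cfg)
  expect_identical(sim$junctions$SJA, sim2$junctions$SJA)
  expect_identical(sim$provenance$substreams, sim2$provenance$substreams)
  expect_output(print(sim), "splice_sim")
  expect_output(print(summary(sim)), "binary fraction")
})

test_that("no-distortion limit: perfect capture and deep coverage recover PsiT", {
  tp <- tech_params(capture_mean = 1, capture_variance = 0,
                    depth_factor = 3000)
  cfg <- sim_config(n_cells = 40, n_per_regime = c(unimodal = 5), tech = tp,
                    fixed_psi = 0.5, seed = 3)
  sim <- run_simulation(cfg)
  ok <- !is.na(sim$junctions$psi_hat) & sim$state$true_counts[, 1] > 0
  # printed weighting converges to 2 Psi / (1 + Psi); the junction-count-aware
  # weighting recovers PsiT itself
  ph <- psi_from_junction_counts(sim$junctions$SJA, sim$junctions$SJB,
                                 "halved_exclusion")
  expect_lt(mean(abs(ph[ok] - sim$state$psi_true[ok])), 0.05)
})

test_that("estimate fidelity improves with capture and depth", {
  err <- function(cap, depth, seed) {
    tp <- tech_params(capture_mean = cap, depth_factor = depth)
    cfg <- sim_config(n_cells = 60, n_per_regime = c(unimodal = 80),
                      tech = tp, seed = seed)
    sim <- run_simulation(cfg)
    ph <- psi_from_junction_counts(sim$junctions$SJA, sim$junctions$SJB,
                                   "halved_exclusion")
    ok <- !is.na(ph) & !is.na(sim$state$psi_true)
    mean(abs(ph[ok] - sim$state$psi_true[ok]))
  }
  seeds <- 1:6
  e_cap <- sapply(c(0.05, 0.2, 0.8), function(cap)
    mean(sapply(seeds, function(s) err(cap, 5, s))))
  expect_true(all(diff(e_cap) < 0.02))   # non-increasing up to MC tolerance
  e_dep <- sapply(c(1, 5, 25), function(d)
    mean(sapply(seeds, function(s) err(0.1, d, s))))
  expect_true(all(diff(e_dep) < 0.02))
})
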