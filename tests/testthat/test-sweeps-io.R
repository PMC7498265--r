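test_that("fixed-expression sweep: single molecules are always binary and the
           binary proportion falls with expression", {
  tab <- sweep_expression(psi_values = 0.5, n_genes = 60L, n_cells = 60L,
                          n_replicates = 3L, rng_seed = 5)
  g1 <- tab$mean_binary_proportion[tab$expression_level == 1]
  expect_equal(g1, 1)   # one molecule can only show one isoform
  lo <- mean(tab$mean_binary_proportion[tab$expression_level <= 10], na.rm = TRUE)
  hi <- mean(tab$mean_binary_proportion[tab$expression_level > 50], na.rm = TRUE)
  expect_gt(lo, hi + 0.1)
})

test_that("half-binary threshold extraction scans in expression order", {
  tab <- data.frame(psi = 0.5, expression_level = 1:5,
                    mean_binary_proportion = c(0.9, 0.7, 0.5, 0.6, 0.3),
                    n_obs = 100)
  expect_equal(binary_half_threshold(tab, 0.5), 3L)
  tab$mean_binary_proportion <- rep(0.8, 5)
  expect_true(is.na(binary_half_threshold(tab, 0.5)))
  expect_error(binary_half_threshold(tab, 0.2), "not present")
})

test_that("capture sweep enforces the exact 50/50 split and improves with capture", {
  tab <- sweep_capture(capture_grid = c(0.02, 0.1), n_genes = 120L,
                       n_cells = 80L, rng_seed = 6)
  lo <- tab[tab$capture_efficiency == 0.02, ]
  hi <- tab[tab$capture_efficiency == 0.1, ]
  expect_gt(mean(lo$binary_proportion, na.rm = TRUE),
            mean(hi$binary_proportion, na.rm = TRUE))
  expect_true(all(tab$binary_proportion >= 0 & tab$binary_proportion <= 1,
                  na.rm = TRUE))
  # the underlying split is exact: rerun the config and inspect the state
  kin <- sample_kinetics(120L, 6)
  cfg <- sim_config(n_cells = 80L, n_per_regime = c(unimodal = 120L),
                    kinetics = kin, fixed_ratio = TRUE, seed = 6)
  sim <- run_simulation(cfg)
  expect_identical(unname(sim$state$XA), unname(sim$state$XB))
  expect_true(all(sim$state$true_counts %% 2 == 0))
})

test_that("regime comparison contrasts coverage dependence of binary outcomes", {
  rc <- run_regime_comparison(capture_grid = 0.1, n_cells = 80L, rng_seed = 8)
  b <- rc$binary
  sp <- function(rg) {
    sub <- b[b$regime == rg & b$exon_regime == rg, ]
    ok <- !is.na(sub$binary_proportion)
    stats::cor(sub$mean_coverage[ok], sub$binary_proportion[ok],
               method = "spearman")
  }
  expect_lt(sp("unimodal"), -0.3)
  # histograms: 21 bins summing to the number of observations
  h <- rc$histograms
  expect_equal(ncol(h), 3 + 21)
  counts <- rowSums(h[, -(1:3)])
  sub <- b[b$regime == "bimodal", ]
  expect_equal(unname(counts[h$regime == "bimodal"][1:5]),
               sub$n_obs[match(h$exon_id[h$regime == "bimodal"][1:5],
                               sub$exon_id)][1:5])
  # unimodal regime: interior-mode exons concentrate in the top coverage decile
  sub_u <- b[b$regime == "unimodal" & b$exon_regime == "unimodal", ]
  interior <- sub_u$binary_proportion < 0.5
  top <- sub_u$coverage_rank <= ceiling(nrow(sub_u) / 10)
  bottom <- sub_u$coverage_rank > floor(nrow(sub_u) * 9 / 10)
  expect_gt(mean(interior[top], na.rm = TRUE),
            mean(interior[bottom], na.rm = TRUE))
})

test_that("tables and matrices round-trip byte-identically", {
  dir <- withr::local_tempdir()
  m <- matrix(c(0.5, 1.25, 0, 3), 2,
              dimnames = list(c("cell_1", "cell_2"), c("g1", "g2")))
  p1 <- file.path(dir, "m1.tsv"); p2 <- file.path(dir, "m2.tsv")
  write_matrix_tsv(m, p1)
  m2 <- read_matrix_tsv(p1)
  expect_equal(m2, m)
  write_matrix_tsv(m2, p2)
  expect_identical(readLines(p1), readLines(p2))

  sim <- run_simulation(sim_config(n_cells = 5, n_per_regime = c(bimodal = 4),
                                   seed = 2))
  jt <- file.path(dir, "junctions.tsv")
  write_junction_table(sim, jt)
  tab <- read_table_tsv(jt)
  expect_equal(nrow(tab), 20L)
  expect_equal(tab$SJA, as.vector(sim$junctions$SJA))
  pv <- file.path(dir, "provenance.txt")
  write_provenance(sim, pv)
  lines <- readLines(pv)
  expect_true(any(grepl("^seed: 2$", lines)))
  expect_true(any(grepl("^substreams\\.", lines)))
})

test_that("cohort generator conserves molecules and plants cluster effects", {
  co <- simulate_cluster_cohort(n_genes = 200L, cells_per_cluster = 25L,
                                rng_seed = 9)
  expect_identical(unname(co$state$XA + co$state$XB),
                   unname(co$state$true_counts))
  expect_equal(unname(rowSums(co$tpm)), rep(1e6, nrow(co$tpm)))
  # planted exons separate cluster means of the true Psi; nulls do not
  cl <- factor(co$clusters)
  spread <- apply(co$psi, 2, function(v)
    diff(range(tapply(v, cl, mean))))
  expect_gt(stats::median(spread[co$planted]), 0.15)
  expect_lt(stats::median(spread[!co$planted]), 0.1)
})
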