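Package: scpsi
Title: Simulation, Theory and Filtering of Cassette-Exon Splicing in Single Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how limited mRNA capture and read coverage distort
    percent-spliced-in (PSI) estimates of cassette exons in full-length single-cell
    RNA-seq. Provides a seeded probabilistic simulator of exon splicing and of the
    technical process (mRNA capture, read generation, splice-junction subsampling),
    closed-form hypergeometric observation models with the transcript count
    marginalized under limited capture, a Census-style estimator of captured mRNA
    counts from TPM, a per-cell splice-junction coverage rate and an
    mRNA-recovery-aware filter for junction-count observations, and evaluation
    statistics: binary/bimodality metrics, Kruskal-Wallis differential splicing with
    fold-enrichment assessment, and a binned-permutation spatial autocorrelation test
    on an expression embedding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
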