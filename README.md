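# scpsi

Bimodal splicing in single cells is often an artifact of coverage. Full-length
single-cell RNA-seq (Smart-seq / Smart-seq2) captures only a small fraction of
a cell's mRNA — commonly around 10% — so the percent spliced-in of a cassette
exon estimated in one cell from splice-junction reads, Ψ̂, is frequently
exactly 0 or 1 (*binary*) even when the cell truly expresses both isoforms at
an intermediate rate Ψ. Across cells this produces apparently *bimodal* Ψ̂
distributions from an underlying unimodal reality. `scpsi` is a toolkit for
quantifying, simulating and correcting this distortion, aimed at
computational biologists analysing alternative splicing in full-length
scRNA-seq data.

It provides four connected components:

1. **A probabilistic simulator.** Per gene g and cell i, pre-mRNA counts
   X<sub>ig</sub> follow Beta–Poisson (two-state transcriptional bursting)
   kinetics; the splicing rate of the gene's cassette exon is
   Ψ<sub>ij</sub> ~ Beta(α<sub>j</sub>, β<sub>j</sub>) with regime-controlled
   shapes (bimodal, unimodal, near-constitutively included/excluded), and
   inclusion molecules are XA<sub>ij</sub> ~ Binomial(X<sub>ig</sub>,
   Ψ<sub>ij</sub>). The technical stage models mRNA capture
   (C ~ Binomial(X, c) with per-cell truncated-normal capture probability),
   read generation (Poisson, proportional to molecules × length), and
   splice-junction subsampling with coverage probabilities
   j<sub>A</sub> = 4(l<sub>r</sub>−1)/l<sub>gA</sub>,
   j<sub>B</sub> = 2(l<sub>r</sub>−1)/l<sub>gB</sub>.
2. **Closed-form observation theory.** With m molecules, mΨ of them carrying
   the exon, and r captured, Ψ̂ = a/r follows a hypergeometric law; the
   unknown m is marginalized under a uniform prior using the binomial capture
   likelihood (whose normalization over m ≥ r equals 1/c exactly), giving
   Pr(Ψ̂ | Ψ, r, c), Pr(|Ψ̂ − Ψ| < δ), and the detection-conditioned
   Pr(Ψ̂ | Ψ, c, m, d).
3. **mRNA-recovery-aware quantification and filtering.** A Census-style
   estimator converts a cell's TPM profile into captured-mRNA counts
   (M<sub>i</sub> from the mode of the log-TPM density;
   Y<sub>ig</sub> = X<sub>ig</sub>·M<sub>i</sub>/10⁶), a per-cell junction
   coverage rate C<sub>j</sub> is calibrated on constitutive junctions, and an
   observation passes the filter iff the gene has ≥ 10 captured mRNAs *and*
   SJ<sub>ij</sub> ≥ 10·(1+Ψ̂<sub>ij</sub>)·C<sub>j</sub> junction reads.
4. **Evaluation statistics.** Binary/bimodality metrics, per-exon
   Kruskal–Wallis differential splicing across cell clusters with
   hypergeometric fold-enrichment evaluation of a filter's selection
   (Benjamini–Hochberg across thresholds), and a binned-permutation spatial
   autocorrelation test (a Geary's C variant over a K-nearest-neighbour
   expression embedding).

## Worked example

How informative are two captured molecules from a gene with 20 transcripts
spliced at Ψ = 0.5?

```r
library(scpsi)
psi_hat_pmf_given_m_r(psi = 0.5, r = 2, m = 20)
#   psi_hat      prob
# 1     0.0 0.2368421
# 2     0.5 0.5263158
# 3     1.0 0.2368421
```

With probability 0.474 the two molecules carry the same isoform, so the cell
looks binary. Conditioning only on the gene being detected at capture
efficiency 10%, the chance of a binary observation is still above one half:

```r
binary_probability(psi_hat_pmf_given_m_c_detected(psi = 0.5, m = 20, c = 0.1))
# [1] 0.5170668
```

The simulator shows the same effect at cohort scale — 300 cells, 1500 genes
(500 unimodal alternative exons, 500 near-included, 500 near-excluded),
capture 10%:

```r
sim <- run_simulation(sim_config(regime = "unimodal", seed = 7))
sim
# <splice_sim> 300 cells x 1500 exons
#   regimes: unimodal=500, included=500, excluded=500
#   capture mean 0.1, depth 5 reads/molecule/kb
#   observed Psi-hat: 42.1% non-missing, 79.1% binary among observed
```

Although every alternative exon's true Ψ is drawn from an interior-mode Beta
distribution, 79% of its observed estimates are binary; `binary_metrics()`
and `run_regime_comparison()` quantify how this tracks junction coverage,
and `filter_observations()` removes the affected observations on real
junction-count tables.

A command-line interface over the same functions is installed at
`inst/cli/scpsi.R` (`Rscript scpsi.R simulate|theory|census|coverage|filter|
diffsplice|autocorr|sweep-expression|sweep-capture|regime-compare ...`).

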