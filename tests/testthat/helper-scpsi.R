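# Small shared fixtures for fast tests.

tiny_tech <- function(...) tech_params(capture_variance = 0, ...)

# splicing_state with one exon and explicit counts, for technical-stage tests
state_with_counts <- function(XA, XB, exon = NULL) {
  n <- length(XA)
  if (is.null(exon))
    exon <- data.frame(exon_id = "exon_1", gene_id = "gene_1",
                       alpha = 2, beta = 2, regime = "unimodal",
                       exclusion_length = 1900L, exon_length = 120L,
                       inclusion_length = 2020L, stringsAsFactors = FALSE)
  X <- matrix(as.integer(XA + XB), ncol = 1,
              dimnames = list(paste0("cell_", seq_len(n)), exon$gene_id))
  structure(list(
    true_counts = X,
    psi = matrix(0.5, n, 1, dimnames = list(rownames(X), exon$exon_id)),
    XA = matrix(as.integer(XA), ncol = 1,
                dimnames = list(rownames(X), exon$exon_id)),
    XB = matrix(as.integer(XB), ncol = 1,
                dimnames = list(rownames(X), exon$exon_id)),
    psi_true = matrix(ifelse(XA + XB > 0, XA / (XA + XB), NA_real_), ncol = 1,
                      dimnames = list(rownames(X), exon$exon_id)),
    exons = exon), class = "splicing_state")
}
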