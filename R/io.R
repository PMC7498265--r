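#' Read and write the package's tab-separated tables and matrices
#'
#' Matrices are written with cell identifiers in the first column (`cell_id`)
#' and gene/exon identifiers in the header; plain tables are written with a
#' header line. All writers/readers round-trip losslessly (write -> read ->
#' write reproduces the file byte for byte).
#'
#' @param m Numeric matrix with dimnames (cells x features).
#' @param path File path.
#' @return `write_matrix_tsv` invisibly returns `path`; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  assert_matrix_like(m)
  m <- name_cells_genes(m)
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @param tab A data frame.
#' @rdname write_matrix_tsv
#' @export
write_table_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a junction-read table from a simulation
#'
#' Long format: `cell_id`, `exon_id`, `SJA`, `SJB`, `psi_hat`.
#'
#' @param sim A `splice_sim` object.
#' @param path File path.
#' @export
write_junction_table <- function(sim, path) {
  jr <- sim$junctions
  tab <- data.frame(
    cell_id = rep(rownames(jr$SJA), times = ncol(jr$SJA)),
    exon_id = rep(colnames(jr$SJA), each = nrow(jr$SJA)),
    SJA = as.vector(jr$SJA), SJB = as.vector(jr$SJB),
    psi_hat = as.vector(jr$psi_hat), stringsAsFactors = FALSE
  )
  write_table_tsv(tab, path)
}

#' Write a provenance record as `key: value` lines
#'
#' @param sim A `splice_sim` object (or any list with a `provenance` entry).
#' @param path File path.
#' @export
write_provenance <- function(sim, path) {
  prov <- if (!is.null(sim$provenance)) sim$provenance else sim
  lines <- unlist(lapply(names(prov), function(k) {
    v <- prov[[k]]
    if (length(v) > 1 && !is.null(names(v)))
      paste0(k, ".", names(v), ": ", unname(v))
    else paste0(k, ": ", paste(v, collapse = ","))
  }))
  writeLines(lines, path)
  invisible(path)
}
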