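#' Read a gene-by-condition expression matrix from TSV
#'
#' The file must have a header row of condition ids and a first column of
#' gene ids; remaining cells are numeric log-ratios or empty (missing).
#' Row and column order are preserved; empty cells become `NA`.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes x conditions) with dimnames and `NA` for
#'   missing entries.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stopf("empty expression file: %s", path)
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]]
  header <- split_row(lines[1])
  conditions <- header[-1]
  dup <- conditions[duplicated(conditions)]
  if (length(dup) > 0) stopf("duplicate condition id in header: %s", dup[1])
  rows <- lapply(lines[-1], split_row)
  genes <- vapply(rows, `[`, character(1), 1)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) stopf("duplicate gene id: %s", dup[1])
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(conditions),
                dimnames = list(genes, conditions))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1]
    length(cells) <- length(conditions)
    empty <- is.na(cells) | cells == ""
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(!empty & is.na(vals))
    if (length(bad) > 0) {
      stopf("non-numeric cell at gene '%s' (row %d), condition '%s': '%s'",
            genes[i], i, conditions[bad[1]], cells[bad[1]])
    }
    mat[i, ] <- vals
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; `NA` entries are written as empty
#' cells.
#'
#' @param mat Numeric matrix with gene rownames and condition colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  fmt <- function(v) {
    out <- vapply(v, function(x) if (is.na(x)) "" else format(x, digits = 15), character(1))
    out
  }
  lines <- c(paste(c("gene", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
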