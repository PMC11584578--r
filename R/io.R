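#' Export an editome as MTX with companion tables
#'
#' Writes the edited-count matrix in MatrixMarket format together with
#' `features.tsv` (genes), `barcodes.tsv` (cells), and a per-cell `qc.tsv`
#' carrying the QC totals.
#'
#' @param ed an [Editome-class]
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
writeEditomeMtx <- function(ed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(assay(ed, "edited"), "CsparseMatrix"),
                   "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(ed), file.path(dir, "features.tsv"))
  writeLines(colnames(ed), file.path(dir, "barcodes.tsv"))
  qc <- data.frame(barcode = colnames(ed),
                   as.data.frame(colData(ed)),
                   check.names = FALSE)
  writeTsv(qc, file.path(dir, "qc.tsv"))
  invisible(dir)
}

#' Read an editome written by [writeEditomeMtx()]
#' @param dir directory with `matrix.mtx`, `features.tsv`, `barcodes.tsv`,
#'   `qc.tsv`
#' @return an [Editome-class]
#' @export
readEditomeMtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  qc <- readTsv(file.path(dir, "qc.tsv"))
  cd <- DataFrame(qc[setdiff(colnames(qc),
                             c("barcode", "totalUMIs", "editedUMIs",
                               "editedTranscripts", "mitoFraction"))],
                  row.names = qc$barcode)
  makeEditome(m, stats::setNames(qc$totalUMIs, qc$barcode),
              colData = cd,
              mitoFraction = stats::setNames(qc$mitoFraction, qc$barcode))
}
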