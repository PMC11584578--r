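#' Build the genes-by-cells editome from significant sites
#'
#' Aggregates, for every gene and cell, the edited UMIs over the gene's
#' significant exonic sites. Intronic sites (not covered by any exon of
#' their gene) are excluded and their count reported in a message.
#'
#' @param se a UMI-level [SiteExperiment-class], strand-calibrated, tested,
#'   and filtered (rows are the significant sites; alternatively pass
#'   `keepAll = TRUE` output and the `significant` flag is honored).
#' @param annotation gene models with exons ([readGeneModels()] list or GTF
#'   path).
#' @param totalUMIs named numeric vector of per-cell transcriptome UMI
#'   totals (names matching `colnames(se)`).
#' @param mitoFraction optional named per-cell mitochondrial fraction
#'   (default 0; supply from the expression matrix, see
#'   [mitoFractionFromCounts()]).
#' @return an [Editome-class] with assay `edited` and per-cell QC totals.
#' @export
buildEditome <- function(se, annotation, totalUMIs, mitoFraction = NULL) {
  if (countingMode(se) != "umis")
    stop("buildEditome expects UMI-level counts")
  ann <- if (is.list(annotation)) annotation else readGeneModels(annotation)
  rd <- rowData(se)
  if (!is.null(rd$significant)) se <- se[rd$significant, ]
  if (is.null(rowData(se)$gene_id))
    stop("sites lack gene assignment; run calibrateStrand() first")

  hits <- GenomicRanges::findOverlaps(rowRanges(se), ann$exons,
                                      ignore.strand = TRUE)
  sameGene <- rowData(se)$gene_id[S4Vectors::queryHits(hits)] ==
    ann$exons$gene_id[S4Vectors::subjectHits(hits)]
  exonic <- seq_len(nrow(se)) %in% S4Vectors::queryHits(hits)[sameGene]
  if (any(!exonic))
    message(sum(!exonic), " significant site(s) outside exons skipped")
  se <- se[exonic, ]

  genes <- factor(rowData(se)$gene_id)
  ind <- Matrix::sparseMatrix(seq_len(nrow(se)), as.integer(genes),
                              x = 1, dims = c(nrow(se), nlevels(genes)))
  counts <- Matrix::t(ind) %*% assay(se, "edited")
  dimnames(counts) <- list(levels(genes), colnames(se))

  miss <- setdiff(colnames(counts), names(totalUMIs))
  if (length(miss))
    stop("totalUMIs missing for ", length(miss), " cell(s)")
  tot <- totalUMIs[colnames(counts)]
  mito <- if (is.null(mitoFraction)) rep(0, ncol(counts)) else
    mitoFraction[colnames(counts)]

  cd <- colData(se)[, intersect(c("sample", "barcode"),
                                colnames(colData(se))), drop = FALSE]
  makeEditome(counts, tot, colData = cd, mitoFraction = mito)
}

#' Per-cell mitochondrial fraction from an expression count matrix
#' @param counts genes-by-cells expression counts
#' @param prefix gene-name prefix identifying mitochondrial genes
#' @return named numeric vector of fractions
#' @export
mitoFractionFromCounts <- function(counts, prefix = "mt-") {
  isMito <- startsWith(rownames(counts), prefix)
  tot <- Matrix::colSums(counts)
  frac <- ifelse(tot > 0, Matrix::colSums(counts[isMito, , drop = FALSE]) /
                   tot, 0)
  stats::setNames(as.vector(frac), colnames(counts))
}

#' Cell quality control on the editome
#'
#' Keeps cells with at least `minEditedTranscripts` edited genes and
#' `minEditedUmis` edited UMIs, a transcriptome UMI total inside `umiRange`,
#' and a mitochondrial fraction not exceeding `maxMito`. Idempotent.
#'
#' @param ed an [Editome-class]
#' @param minEditedTranscripts,minEditedUmis editome QC thresholds (keep if
#'   `>=`)
#' @param umiRange inclusive total-UMI window
#' @param maxMito maximum mitochondrial fraction (keep if `<=`)
#' @param keepAll return all cells with a `passQC` flag instead of the
#'   surviving subset
#' @return the filtered `Editome`; `colData$passQC` records the decision.
#' @export
filterCells <- function(ed, minEditedTranscripts = 2, minEditedUmis = 20,
                        umiRange = c(2000, 100000), maxMito = 0.10,
                        keepAll = FALSE) {
  cd <- colData(ed)
  pass <- cd$editedTranscripts >= minEditedTranscripts &
    cd$editedUMIs >= minEditedUmis &
    cd$totalUMIs >= umiRange[1] & cd$totalUMIs <= umiRange[2] &
    cd$mitoFraction <= maxMito
  ed$passQC <- pass
  if (keepAll) ed else ed[, pass]
}

#' Binding-intensity normalization
#'
#' Converts edited-UMI counts to binding intensity
#' `b = log1p(k / totalUMIs * 1e4)` (natural log): edited UMIs per 10,000
#' total UMIs of the cell, log-transformed. Stored as assay `binding`.
#'
#' @param ed an [Editome-class] with positive `totalUMIs` for every cell
#' @param scaleFactor per-cell depth scaling (default 10,000)
#' @return `ed` with a `binding` assay added.
#' @export
normalizeBinding <- function(ed, scaleFactor = 1e4) {
  tot <- colData(ed)$totalUMIs
  if (any(tot <= 0))
    stop("cells with zero total UMIs must be filtered before normalization")
  k <- assay(ed, "edited")
  b <- log1p(Matrix::t(Matrix::t(k) * (scaleFactor / tot)))
  SummarizedExperiment::assay(ed, "binding") <- b
  ed
}

#' @describeIn normalizeBinding binding-intensity assay accessor
#' @export
bindingIntensity <- function(ed) {
  if (!"binding" %in% assayNames(ed))
    stop("no binding assay; run normalizeBinding() first")
  assay(ed, "binding")
}

#' @describeIn normalizeBinding edited-count assay accessor
#' @param x a [SiteExperiment-class] or [Editome-class]
#' @export
editedCounts <- function(x) assay(x, "edited")
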