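#' Four-part significance filter for edited sites
#'
#' Retains sites satisfying, simultaneously: (1) FDR below `fdrMax`;
#' (2) editing frequency within `freqRange`; (3) edited count strictly
#' greater than `minEdited`; (4) coverage strictly greater than
#' `minCoverage`. With `perReplicate = TRUE` criteria 2-4 must hold in every
#' column (replicate) separately, the bulk convention; otherwise they are
#' evaluated on counts pooled across columns, the single-cell pseudobulk
#' convention. Per-criterion pass flags are recorded in `rowData`.
#'
#' @param se a tested [SiteExperiment-class] (see [testSites()])
#' @param fdrMax FDR threshold (default 0.01)
#' @param freqRange inclusive editing-frequency window (default 0.05-0.95)
#' @param minEdited edited count must exceed this (default 2)
#' @param minCoverage coverage must exceed this (default 10)
#' @param perReplicate apply criteria 2-4 per column; defaults to `TRUE`
#'   for read-level (bulk) counting and `FALSE` for UMI-level counting
#' @param keepAll return all sites with flags instead of the surviving set
#' @return the filtered `SiteExperiment` with logical `passFdr`, `passFreq`,
#'   `passEdited`, `passCoverage`, and `significant` columns in `rowData`.
#' @export
applySiteFilters <- function(se, fdrMax = 0.01, freqRange = c(0.05, 0.95),
                             minEdited = 2, minCoverage = 10,
                             perReplicate = NULL, keepAll = FALSE) {
  if (is.null(perReplicate)) perReplicate <- countingMode(se) == "reads"
  rd <- rowData(se)
  if (is.null(rd$fdr)) stop("run testSites() before filtering")

  if (perReplicate && ncol(se) > 1) {
    k <- as.matrix(assay(se, "edited"))
    n <- as.matrix(assay(se, "coverage"))
    f <- ifelse(n > 0, k / n, NA_real_)
    passFreq <- rowAlls(f >= freqRange[1] & f <= freqRange[2])
    passEdited <- rowAlls(k > minEdited)
    passCoverage <- rowAlls(n > minCoverage)
  } else {
    k <- rd$k %||% as.vector(Matrix::rowSums(assay(se, "edited")))
    n <- rd$n %||% as.vector(Matrix::rowSums(assay(se, "coverage")))
    f <- ifelse(n > 0, k / n, NA_real_)
    passFreq <- !is.na(f) & f >= freqRange[1] & f <= freqRange[2]
    passEdited <- k > minEdited
    passCoverage <- n > minCoverage
  }
  passFdr <- rd$fdr < fdrMax

  rowData(se)$passFdr <- passFdr
  rowData(se)$passFreq <- passFreq
  rowData(se)$passEdited <- passEdited
  rowData(se)$passCoverage <- passCoverage
  rowData(se)$significant <- passFdr & passFreq & passEdited & passCoverage
  if (keepAll) se else se[rowData(se)$significant, ]
}

rowAlls <- function(m) {
  m[is.na(m)] <- FALSE
  rowSums(m) == ncol(m)
}

#' Export an edit-site table
#'
#' Writes tested sites as TSV, or as a minimal VCF whose INFO field carries
#' the per-site counts and statistics (K, N, F, P, FDR, GENE).
#'
#' @param se a tested [SiteExperiment-class]
#' @param path output file
#' @param format `"tsv"` or `"vcf"`
#' @return `path`, invisibly
#' @export
writeSites <- function(se, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  rd <- as.data.frame(rowData(se))
  df <- data.frame(chrom = as.character(seqnames(rowRanges(se))),
                   pos = start(rowRanges(se)), rd,
                   stringsAsFactors = FALSE)
  if (format == "tsv") {
    writeTsv(df, path)
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=K,Number=1,Type=Integer,Description=\"Edited count\">",
             "##INFO=<ID=N,Number=1,Type=Integer,Description=\"Coverage\">",
             "##INFO=<ID=F,Number=1,Type=Float,Description=\"Editing frequency\">",
             "##INFO=<ID=P,Number=1,Type=Float,Description=\"One-sided p-value\">",
             "##INFO=<ID=FDR,Number=1,Type=Float,Description=\"BH FDR\">",
             "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- sprintf("K=%d;N=%d;F=%.6g;P=%.6g;FDR=%.6g;GENE=%s",
                    df$k, df$n, df$f, df$p, df$fdr,
                    df$gene_id %||% rep(".", nrow(df)))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    df$chrom, df$pos, rownames(df), df$ref, df$alt, info)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
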