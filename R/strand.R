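#' Calibrate candidate sites against transcript strand and mask variants
#'
#' ADAR deposits A-to-I edits on the transcript, which sequencing reads as
#' A-to-G in transcript space. On the genome this appears as A-to-G on
#' plus-strand genes and T-to-C on minus-strand genes; every other
#' substitution class is noise and is dropped. Sites overlapping genes on
#' both strands cannot be assigned a transcript-space class and are dropped.
#' Sites matching the known-variant mask (dbSNP-style) are removed.
#'
#' @param se a [SiteExperiment-class] from [pileupCounts()]
#' @param annotation gene models (list from [readGeneModels()], GTF path, or
#'   a `GRanges` of genes with `gene_id`)
#' @param variantMask optional `GRanges` of known variants or a VCF path
#' @return the calibrated `SiteExperiment`: only retained sites, with
#'   `gene_id`, `tx_strand`, and transcript-space `refTx`/`altTx` (always
#'   "A"/"G") added to `rowData`.
#' @export
calibrateStrand <- function(se, annotation, variantMask = NULL) {
  ann <- if (is.list(annotation)) annotation else
    if (is(annotation, "GRanges") && is.null(annotation$type))
      list(genes = annotation) else readGeneModels(annotation)
  genes <- ann$genes
  if (!nrow(se)) return(se)

  hits <- GenomicRanges::findOverlaps(rowRanges(se), genes,
                                      ignore.strand = TRUE)
  strandsBySite <- split(as.character(strand(genes))[
    S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
  genesBySite <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))

  n <- nrow(se)
  txStrand <- rep(NA_character_, n)
  geneId <- rep(NA_character_, n)
  idx <- as.integer(names(strandsBySite))
  for (i in seq_along(idx)) {
    st <- unique(strandsBySite[[i]])
    if (length(st) != 1L) next   # ambiguous: genes on both strands
    txStrand[idx[i]] <- st
    geneId[idx[i]] <- genesBySite[[i]][1]
  }

  ref <- rowData(se)$ref
  alt <- rowData(se)$alt
  keep <- !is.na(txStrand) &
    ((txStrand == "+" & ref == "A" & alt == "G") |
     (txStrand == "-" & ref == "T" & alt == "C"))

  if (!is.null(variantMask)) {
    mask <- readVariantMask(variantMask)
    keep <- keep & !IRanges::overlapsAny(rowRanges(se), mask,
                                         ignore.strand = TRUE)
  }

  out <- se[keep, ]
  rowData(out)$gene_id <- geneId[keep]
  rowData(out)$tx_strand <- txStrand[keep]
  rowData(out)$refTx <- "A"
  rowData(out)$altTx <- "G"
  out
}
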