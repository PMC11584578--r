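#' Read gene models from a GTF file
#'
#' Imports gene and exon records and returns plain `GRanges` keyed by
#' `gene_id`, the representation the calling and aggregation steps consume.
#' When the GTF has no explicit `gene` rows, gene extents are derived as the
#' range of each gene's exons.
#'
#' @param path GTF file path, or an already-imported `GRanges` with `type`
#'   and `gene_id` columns.
#' @return list with elements `genes` and `exons` (both `GRanges` with a
#'   `gene_id` metadata column).
#' @export
readGeneModels <- function(path) {
  gr <- if (is(path, "GRanges")) path else rtracklayer::import(path)
  if (is.null(gr$gene_id)) stop("annotation lacks gene_id attributes")
  exons <- gr[gr$type == "exon"]
  genes <- gr[gr$type == "gene"]
  if (!length(genes)) {
    sp <- split(exons, exons$gene_id)
    rng <- unlist(range(sp))
    genes <- GRanges(rng, gene_id = names(rng))
  }
  S4Vectors::mcols(exons) <- DataFrame(gene_id = exons$gene_id)
  S4Vectors::mcols(genes) <- DataFrame(gene_id = genes$gene_id)
  list(genes = genes, exons = exons)
}

#' Read a known-variant mask
#'
#' Loads variant positions (dbSNP-style VCF) to exclude from edit calling.
#'
#' @param path VCF file path, or a `GRanges` of positions (returned as is).
#' @return `GRanges` of variant positions.
#' @export
readVariantMask <- function(path) {
  if (is(path, "GRanges")) return(path)
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  S4Vectors::mcols(gr) <- NULL
  gr
}

readGenomeSeq <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  Biostrings::readDNAStringSet(genome)
}

# genome FASTA headers may carry descriptions; keep the first word
cleanSeqNames <- function(x) {
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  x
}
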