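# Hand-built toy alignment fixture: one chromosome, one plus-strand gene,
# reads of length 20 starting at position 1. Returns paths plus the truth
# about what was written.
suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(GenomicRanges)
})

toyStack <- function(reads, genomeSeq = NULL, dir = tempfile("toy")) {
  dir.create(dir)
  if (is.null(genomeSeq))
    genomeSeq <- paste(rep("ACGTAACGTTACGTAACGTTACGTAACGTT", 2),
                       collapse = "")
  genome <- Biostrings::DNAStringSet(genomeSeq)
  names(genome) <- "chrT"
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fa)
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:chrT\tLN:%d", nchar(genomeSeq)))
  writeLines(c(hdr, reads), sam)
  genes <- GRanges("chrT", IRanges(1, nchar(genomeSeq)), strand = "+",
                   gene_id = "toygene")
  list(sam = sam, genome = genome, genes = genes, dir = dir)
}

toyRead <- function(id, pos, seq, cb = "BC1", umi = "U1", mapq = 60) {
  sprintf("%s\t0\tchrT\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tCB:Z:%s\tUB:Z:%s",
          id, pos, mapq, nchar(seq), seq, strrep("I", nchar(seq)), cb, umi)
}

# reference-derived read sequence with optional substitutions (named vector
# position -> base, positions in genome coordinates)
refRead <- function(genomeSeq, pos, len, subs = NULL) {
  s <- substr(genomeSeq, pos, pos + len - 1)
  if (!is.null(subs)) {
    ch <- strsplit(s, "")[[1]]
    for (p in names(subs)) ch[as.integer(p) - pos + 1] <- subs[[p]]
    s <- paste(ch, collapse = "")
  }
  s
}

# 4 genes x 3 cells toy editome input; gene gd has an intronic site
toyEditomeInputs <- function() {
  # 4 genes x 3 cells; gene gd's site is intronic; ge has two sites
  genes <- GRanges("chr1", IRanges(c(1, 101, 201, 301), width = 100),
                   strand = "+",
                   gene_id = c("ga", "gb", "gc", "gd"))
  exons <- GRanges("chr1",
                   IRanges(c(1, 101, 201, 301), c(100, 200, 300, 320)),
                   strand = "+",
                   gene_id = c("ga", "gb", "gc", "gd"))
  k <- rbind(c(2, 0, 1),   # ga site 1
             c(3, 1, 0),   # ga site 2
             c(0, 4, 2),   # gb
             c(1, 1, 1),   # gc
             c(5, 5, 5))   # gd, intronic (pos 350 outside exon end 320)
  n <- k + 2
  colnames(k) <- colnames(n) <- c("c1", "c2", "c3")
  se <- makeSiteExperiment(k, n, pos = c(10, 50, 150, 250, 350),
                           geneId = c("ga", "ga", "gb", "gc", "gd"))
  rowData(se)$significant <- TRUE
  list(se = se, ann = list(genes = genes, exons = exons))
}
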