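#' Simulate tagged alignments and companion files from a synthetic truth
#'
#' Emits one coordinate-sorted SAM file per sample (experimental / control)
#' with cell-barcode and UMI tags, plus the matching toy genome FASTA, GTF
#' gene models, SNP VCF, and a BED6 file of planted sites. Each transcript
#' molecule (UMI) picks one exon of its gene and a start position such that
#' the read fits inside the exon; its edit status at each covered planted
#' site is drawn once per molecule, so all PCR duplicates of a UMI share the
#' molecule's edits before per-read sequencing error. Reads per UMI follow
#' `1 + Poisson(lambda_cell)` with the cell's Gamma-distributed duplication
#' rate. Edited bases are written as G on plus-strand genes and C on
#' minus-strand genes; germline SNPs are heterozygous (each molecule carries
#' the alternative allele with probability 0.5).
#'
#' @param truth a [SyntheticTruth-class]
#' @param dir output directory
#' @param seed integer seed
#' @param readLength read length in bp (must not exceed the exon length)
#' @param cbTag,umiTag SAM tag names for cell barcode and UMI
#' @return named list of emitted file paths (`genome`, `gtf`, `vcf`, `bed`,
#'   `truth`, and one `sam.<sample>` entry per sample).
#' @export
simulateAlignments <- function(truth, dir, seed = 0, readLength = 80L,
                               cbTag = "CB", umiTag = "UB") {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- truth@params
  genes <- truth@genes
  cells <- truth@cells
  exonLen <- truth@exons$end - truth@exons$start + 1L
  if (readLength > min(exonLen))
    stop("readLength must not exceed the exon length")
  genomeChars <- strsplit(as.character(truth@genome[[1]]), "")[[1]]

  exonsByGene <- split(truth@exons, truth@exons$gene_id)
  sitesByGene <- split(truth@sites, truth@sites$gene_id)
  qual <- strrep("I", readLength)

  out <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    vcf = file.path(dir, "variants.vcf"),
    bed = file.path(dir, "sites.bed"),
    truth = file.path(dir, "truth"))
  Biostrings::writeXStringSet(truth@genome, out$genome)
  writeGtf(truth, out$gtf)
  writeSnpVcf(truth, out$vcf)
  writeSitesBed(truth, out$bed)
  saveTruth(truth, out$truth)

  for (smp in unique(cells$sample)) {
    idx <- which(cells$sample == smp)
    pos <- character(0); seqs <- character(0); tags <- character(0)
    starts <- integer(0)
    readCounter <- 0L
    for (ci in idx) {
      bc <- cells$barcode[ci]
      lam <- cells$dup_lambda[ci]
      t_g <- stats::rmultinom(1, round(cells$depth[ci]), genes$weight)[, 1]
      umiIdx <- 0L
      for (gi in which(t_g > 0)) {
        gid <- genes$gene_id[gi]
        ex <- exonsByGene[[gid]]
        st <- sitesByGene[[gid]]
        exW <- ex$end - ex$start + 1L - readLength + 1L
        editP <- moleculeEditProb(cells[ci, ], st, p)
        for (m in seq_len(t_g[gi])) {
          umiIdx <- umiIdx + 1L
          e <- sample.int(nrow(ex), 1L, prob = exW)
          s0 <- ex$start[e] + sample.int(exW[e], 1L) - 1L
          frag <- genomeChars[s0:(s0 + readLength - 1L)]
          if (nrow(st)) {
            cov <- which(st$pos >= s0 & st$pos <= s0 + readLength - 1L)
            for (j in cov) {
              if (stats::runif(1) < editP[j])
                frag[st$pos[j] - s0 + 1L] <-
                  if (st$strand[j] == "+") "G" else "C"
            }
          }
          if (nrow(truth@snps)) {
            sv <- which(truth@snps$pos >= s0 &
                        truth@snps$pos <= s0 + readLength - 1L)
            for (j in sv) {
              if (stats::runif(1) < 0.5)
                frag[truth@snps$pos[j] - s0 + 1L] <- truth@snps$alt[j]
            }
          }
          d <- 1L + stats::rpois(1, lam)
          for (r in seq_len(d)) {
            rd <- frag
            nerr <- stats::rbinom(1, readLength, p$error_rate)
            if (nerr > 0) {
              at <- sample.int(readLength, nerr)
              rd[at] <- vapply(rd[at], function(b)
                sample(setdiff(DNA_BASES, b), 1), character(1))
            }
            readCounter <- readCounter + 1L
            starts <- c(starts, s0)
            seqs <- c(seqs, paste(rd, collapse = ""))
            tags <- c(tags, sprintf("%s:Z:%s\t%s:Z:U%06d",
                                    cbTag, bc, umiTag, umiIdx))
          }
        }
      }
    }
    o <- order(starts)
    lines <- sprintf(
      "r%07d\t0\tchr1\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\t%s",
      seq_along(starts), starts[o], readLength, seqs[o], qual, tags[o])
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:chr1\tLN:%d", length(genomeChars)))
    path <- file.path(dir, paste0(smp, ".sam"))
    writeLines(c(header, lines), path)
    out[[paste0("sam.", smp)]] <- path
  }
  out
}

# per-site molecule editing probability for one cell
moleculeEditProb <- function(cell, sites, params) {
  if (!nrow(sites)) return(numeric(0))
  if (cell$sample == "control") return(rep(params$background_mu, nrow(sites)))
  f <- sites[[paste0("freq.", cell$state)]]
  if (isTRUE(cell$negative)) f <- f * params$negative_scale
  f
}

writeGtf <- function(truth, path) {
  g <- truth@genes
  e <- truth@exons
  attrs <- function(gid) sprintf('gene_id "%s"; transcript_id "%s.t1";',
                                 gid, gid)
  gl <- sprintf("%s\ttribetools\tgene\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, g$start, g$end, g$strand, attrs(g$gene_id))
  el <- sprintf("%s\ttribetools\texon\t%d\t%d\t.\t%s\t.\t%s",
                e$chrom, e$start, e$end, e$strand, attrs(e$gene_id))
  writeLines(c(gl, el), path)
  invisible(path)
}

writeSnpVcf <- function(truth, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(truth@genome)[1],
                   Biostrings::width(truth@genome)[1]),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  s <- truth@snps
  body <- if (nrow(s))
    sprintf("%s\t%d\tsnp%d\t%s\t%s\t.\tPASS\t.",
            s$chrom, s$pos, seq_len(nrow(s)), s$ref, s$alt)
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# BED6, 0-based half-open
writeSitesBed <- function(truth, path) {
  s <- truth@sites
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     s$chrom, s$pos - 1L, s$pos, s$site_id, s$strand), path)
  invisible(path)
}
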