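#' Pile up candidate edit-site counts from tagged alignments
#'
#' Enumerates every genomic position where at least one read (or UMI)
#' carries a base different from the reference, and counts, per sample
#' (`mode = "reads"`, bulk) or per cell (`mode = "umis"`, single-cell), the
#' edited units `k` and covering units `n` at each (position, alternative
#' base) pair. In `umis` mode, reads sharing (cell barcode, gene, UMI)
#' collapse to one molecule whose base at a site is the majority base among
#' its duplicate reads; ties discard the molecule at that site. Reads below
#' the mapping-quality cutoff are excluded; reads not overlapping any
#' annotated gene are dropped in `umis` mode (the gene is part of the
#' molecule key).
#'
#' @param files named character vector of SAM/BAM paths (names become sample
#'   labels; SAM input is converted on the fly).
#' @param genome reference sequences ([Biostrings::DNAStringSet] or FASTA
#'   path).
#' @param annotation gene models ([readGeneModels()] list, GTF path, or
#'   `GRanges` of genes with `gene_id`); required in `umis` mode.
#' @param mode `"reads"` (count reads per sample) or `"umis"` (collapse to
#'   molecules per cell).
#' @param mapqMin minimum mapping quality (reads below are excluded).
#' @param cbTag,umiTag SAM tags holding cell barcode and UMI.
#' @return a [SiteExperiment-class]; columns are samples (`reads`) or cells
#'   (`umis`, with `sample` and `barcode` in `colData`).
#' @export
pileupCounts <- function(files, genome, annotation = NULL,
                         mode = c("umis", "reads"), mapqMin = 10,
                         cbTag = "CB", umiTag = "UB") {
  mode <- match.arg(mode)
  genome <- cleanSeqNames(readGenomeSeq(genome))
  if (is.null(names(files)))
    names(files) <- sub("\\.(sam|bam)$", "", basename(files))
  geneRanges <- NULL
  if (!is.null(annotation)) {
    ann <- if (is.list(annotation)) annotation else
      if (is(annotation, "GRanges") && is.null(annotation$type))
        list(genes = annotation) else readGeneModels(annotation)
    geneRanges <- ann$genes
  }
  if (mode == "umis" && is.null(geneRanges))
    stop("umis mode requires gene annotation")

  samples <- lapply(names(files), function(smp)
    loadReadStack(files[[smp]], genome, mode, mapqMin, cbTag, umiTag,
                  geneRanges))
  names(samples) <- names(files)

  # union of mismatch sites over all samples
  mm <- unique(do.call(rbind, lapply(samples, function(s)
    s$mismatches[c("chrom", "pos", "ref", "alt")])))
  if (is.null(mm) || !nrow(mm))
    return(emptySiteExperiment(mode, names(files)))
  mm <- mm[order(mm$chrom, mm$pos, mm$alt), ]
  key <- siteKey(mm$chrom, mm$pos, mm$ref, mm$alt)
  sitePos <- GRanges(mm$chrom, IRanges(mm$pos, mm$pos))

  if (mode == "reads") {
    cols <- names(files)
    k <- n <- matrix(0L, nrow(mm), length(cols),
                     dimnames = list(key, cols))
    for (smp in cols) {
      bt <- baseTable(samples[[smp]], sitePos)
      if (!nrow(bt)) next
      n[, smp] <- tabulateAt(bt$site, nrow(mm))
      hitAlt <- bt[bt$base == mm$alt[bt$site], , drop = FALSE]
      k[, smp] <- tabulateAt(hitAlt$site, nrow(mm))
    }
    cd <- DataFrame(sample = cols, row.names = cols)
  } else {
    perCell <- list()
    for (smp in names(files)) {
      st <- samples[[smp]]
      bt <- baseTable(st, sitePos)
      if (!nrow(bt)) next
      bt$cell <- st$cb[bt$read]
      bt$mol <- paste(st$cb[bt$read], st$gene[bt$read], st$umi[bt$read],
                      sep = "|")
      cons <- umiConsensus(bt)
      cons$sample <- smp
      perCell[[smp]] <- cons
    }
    cons <- do.call(rbind, perCell)
    if (is.null(cons) || !nrow(cons))
      return(emptySiteExperiment(mode, character(0)))
    cellIds <- unique(cons[, c("sample", "cell")])
    cellIds$column <- paste(cellIds$sample, cellIds$cell, sep = ".")
    cons$col <- match(paste(cons$sample, cons$cell, sep = "."),
                      cellIds$column)
    dn <- list(key, cellIds$column)
    # coverage counts every consensus molecule at the site; edited counts
    # the molecules whose consensus equals the row's alternative base
    n <- Matrix::sparseMatrix(cons$site, cons$col, x = cons$n,
                              dims = c(nrow(mm), nrow(cellIds)),
                              dimnames = dn)
    isAlt <- cons$base == mm$alt[cons$site]
    k <- Matrix::sparseMatrix(cons$site[isAlt], cons$col[isAlt],
                              x = cons$n[isAlt],
                              dims = dim(n), dimnames = dn)
    cd <- DataFrame(sample = cellIds$sample, barcode = cellIds$cell,
                    row.names = cellIds$column)
  }

  rr <- sitePos
  names(rr) <- key
  se <- SummarizedExperiment(
    assays = list(edited = k, coverage = n),
    rowRanges = rr, colData = cd)
  rowData(se)$ref <- mm$ref
  rowData(se)$alt <- mm$alt
  new("SiteExperiment", se, counting = mode)
}

# read one alignment file, lay read sequences onto reference space, and
# record per-read mismatch positions vs the reference
loadReadStack <- function(file, genome, mode, mapqMin, cbTag, umiTag,
                          geneRanges = NULL) {
  if (grepl("\\.sam$", file)) {
    file <- Rsamtools::asBam(file,
      destination = tempfile(fileext = ""), overwrite = TRUE,
      indexDestination = TRUE)
  }
  tags <- if (mode == "umis") c(cbTag, umiTag) else character(0)
  param <- Rsamtools::ScanBamParam(what = c("mapq", "seq"), tag = tags)
  ga <- GenomicAlignments::readGAlignments(file, param = param)
  mq <- S4Vectors::mcols(ga)$mapq
  ga <- ga[is.na(mq) | mq >= mapqMin]
  if (mode == "umis") {
    cb <- S4Vectors::mcols(ga)[[cbTag]]
    umi <- S4Vectors::mcols(ga)[[umiTag]]
    if (is.null(cb) || is.null(umi) || anyNA(cb) || anyNA(umi))
      stop("umis mode requires ", cbTag, "/", umiTag,
           " tags on every read")
  }
  refSeqs <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(ga)$seq, GenomicAlignments::cigar(ga))
  gr <- GRanges(GenomicAlignments::seqnames(ga),
                IRanges(GenomicAlignments::start(ga),
                        width = Biostrings::width(refSeqs)))
  reads <- as.character(refSeqs)
  cb <- umi <- gene <- NULL
  if (mode == "umis") {
    cb <- S4Vectors::mcols(ga)[[cbTag]]
    umi <- S4Vectors::mcols(ga)[[umiTag]]
    # the molecule key includes the gene; reads outside genes are dropped
    hit <- GenomicRanges::findOverlaps(gr, geneRanges, ignore.strand = TRUE,
                                       select = "first")
    keep <- !is.na(hit)
    gr <- gr[keep]; reads <- reads[keep]
    cb <- cb[keep]; umi <- umi[keep]
    gene <- geneRanges$gene_id[hit[keep]]
  }
  chromStr <- stats::setNames(as.character(genome), names(genome))
  list(ranges = gr, reads = reads,
       mismatches = findMismatches(gr, reads, chromStr),
       cb = cb, umi = umi, gene = gene)
}

findMismatches <- function(gr, reads, chromStr) {
  res <- list()
  ch <- as.character(seqnames(gr))
  st <- start(gr)
  wd <- width(gr)
  for (grp in split(seq_along(gr), paste(ch, wd))) {
    w <- wd[grp[1]]
    rm_ <- do.call(rbind, strsplit(reads[grp], ""))
    refs <- substring(chromStr[[ch[grp[1]]]], st[grp], st[grp] + w - 1L)
    fm <- do.call(rbind, strsplit(refs, ""))
    diff <- which(rm_ != fm & rm_ %in% DNA_BASES & fm %in% DNA_BASES,
                  arr.ind = TRUE)
    if (!nrow(diff)) next
    res[[length(res) + 1L]] <- data.frame(
      chrom = ch[grp[1]],
      pos = st[grp][diff[, 1]] + diff[, 2] - 1L,
      ref = fm[diff], alt = rm_[diff],
      read = grp[diff[, 1]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      read = integer(0))
  out
}

# per-read base calls at each candidate site (read must cover the position)
baseTable <- function(stack, sitePos) {
  hits <- GenomicRanges::findOverlaps(sitePos, stack$ranges)
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  if (!length(si))
    return(data.frame(site = integer(0), read = integer(0),
                      base = character(0)))
  off <- start(sitePos)[si] - start(stack$ranges)[ri] + 1L
  base <- substring(stack$reads[ri], off, off)
  keep <- base %in% DNA_BASES
  data.frame(site = si[keep], read = ri[keep], base = base[keep],
             stringsAsFactors = FALSE)
}

# collapse duplicate reads of one molecule to a majority-vote consensus base
umiConsensus <- function(bt) {
  keyF <- interaction(bt$site, bt$mol, drop = TRUE)
  tab <- unclass(table(keyF, bt$base))
  top <- max.col(tab, ties.method = "first")
  mx <- tab[cbind(seq_len(nrow(tab)), top)]
  tie <- rowSums(tab == mx) > 1L
  idx <- match(levels(keyF), as.character(keyF))
  out <- data.frame(site = bt$site[idx], cell = bt$cell[idx],
                    base = colnames(tab)[top], n = 1L,
                    stringsAsFactors = FALSE)
  out[!tie, , drop = FALSE]
}

tabulateAt <- function(idx, n) as.integer(tabulate(idx, nbins = n))

emptySiteExperiment <- function(mode, cols) {
  m <- matrix(0L, 0, length(cols), dimnames = list(NULL, cols))
  se <- SummarizedExperiment(
    assays = list(edited = m, coverage = m),
    rowRanges = GRanges(),
    colData = DataFrame(sample = cols, row.names = cols))
  new("SiteExperiment", se, counting = mode)
}
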