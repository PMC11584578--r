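#' Editing-frequency profile around CLIP peak centers
#'
#' Assigns each edited site a signed distance to the nearest peak center
#' (interval midpoint, or the summit when a 7th BED column gives a 0-based
#' summit offset from the interval start), discards sites farther than
#' `window`, and accumulates sites and their editing frequencies in
#' equal-width bins over `[-window, +window]`. Both the per-bin and the
#' cumulative form are returned.
#'
#' @param sites a tested [SiteExperiment-class] (uses `rowData` `f`), or a
#'   `GRanges` with an `f` metadata column
#' @param peaks a `GRanges` of peak intervals (see [readPeaks()]), possibly
#'   with a `summit` column
#' @param window flank size in bp (default 500)
#' @param bins number of bins (default 50)
#' @return data.frame per bin: `binStart`, `binEnd`, `binMid`, `nSites`,
#'   `freqSum`, `freqMean`, `cumFraction` (cumulative share of the total
#'   editing frequency, non-decreasing).
#' @export
peakFlankProfile <- function(sites, peaks, window = 500, bins = 50) {
  if (!length(peaks)) stop("empty peak set")
  gr <- if (is(sites, "SiteExperiment")) {
    g <- rowRanges(sites)
    g$f <- rowData(sites)$f
    g
  } else sites
  if (is.null(gr$f)) stop("sites lack an editing-frequency column 'f'")

  center <- if (!is.null(peaks$summit)) start(peaks) + peaks$summit
            else (start(peaks) + end(peaks)) %/% 2
  centers <- GRanges(seqnames(peaks), IRanges(center, center))
  near <- GenomicRanges::nearest(gr, centers, ignore.strand = TRUE)
  ok <- !is.na(near)
  dist <- start(gr)[ok] - start(centers)[near[ok]]
  f <- gr$f[ok]
  keep <- abs(dist) <= window
  dist <- dist[keep]; f <- f[keep]

  edges <- seq(-window, window, length.out = bins + 1)
  bin <- cut(dist, edges, include.lowest = TRUE, labels = FALSE)
  nSites <- tabulate(bin, nbins = bins)
  freqSum <- vapply(seq_len(bins), function(b)
    sum(f[bin == b]), numeric(1))
  out <- data.frame(
    binStart = edges[-(bins + 1)], binEnd = edges[-1],
    binMid = (edges[-(bins + 1)] + edges[-1]) / 2,
    nSites = nSites, freqSum = freqSum,
    freqMean = ifelse(nSites > 0, freqSum / nSites, NA_real_))
  total <- sum(freqSum)
  out$cumFraction <- if (total > 0) cumsum(freqSum) / total else
    cumsum(nSites) / max(sum(nSites), 1)
  out
}

#' Read peak intervals from BED
#'
#' BED6 with an optional 7th column interpreted as the 0-based summit
#' offset from the interval start. Coordinates convert from 0-based
#' half-open to the 1-based inclusive `GRanges` convention.
#'
#' @param path BED file
#' @return `GRanges` with `name`, `score`, and optionally `summit`.
#' @export
readPeaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                strand = if (ncol(df) >= 6) df[[6]] else "*")
  if (ncol(df) >= 4) gr$name <- df[[4]]
  if (ncol(df) >= 5) gr$score <- df[[5]]
  if (ncol(df) >= 7) gr$summit <- df[[7]]
  gr
}

#' Decompose the overlap of two target gene sets with motif support
#'
#' Reports the intersection and the set differences of two target sets
#' (e.g. editing-derived targets vs CLIP-derived targets) and, within each
#' partition of set A, the fraction of genes carrying at least one
#' motif-positive flank window.
#'
#' @param targetsA,targetsB character vectors of gene ids
#' @param windows flank windows from [extractFlanks()] whose names (or a
#'   `gene_id` column) map windows to genes; optional
#' @param motif IUPAC consensus scanned with [motifHits()]; optional
#' @return list with `nIntersect`, `nOnlyA`, `nOnlyB`, `overlapFraction`
#'   (of A), the member vectors, and when windows and motif are given,
#'   `motifFractionOverlap` / `motifFractionNonOverlap` within A.
#' @export
overlapDecomposition <- function(targetsA, targetsB, windows = NULL,
                                 motif = NULL) {
  a <- unique(targetsA); b <- unique(targetsB)
  if (!length(a) || !length(b)) stop("both gene sets must be non-empty")
  inter <- intersect(a, b)
  onlyA <- setdiff(a, b)
  onlyB <- setdiff(b, a)
  out <- list(nIntersect = length(inter), nOnlyA = length(onlyA),
              nOnlyB = length(onlyB),
              overlapFraction = length(inter) / length(a),
              intersect = inter, onlyA = onlyA, onlyB = onlyB)
  if (!is.null(windows) && !is.null(motif)) {
    gene <- windows$gene_id %||% names(windows)
    if (is.null(gene)) stop("windows lack gene identifiers")
    hits <- motifHits(windowSeqs(windows), motif)
    posGenes <- unique(gene[hits])
    frac <- function(set) if (length(set)) mean(set %in% posGenes) else
      NA_real_
    out$motifFractionOverlap <- frac(inter)
    out$motifFractionNonOverlap <- frac(onlyA)
  }
  out
}
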