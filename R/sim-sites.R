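#' Assemble a SiteExperiment from count vectors
#'
#' Programmatic constructor for site-level workflows that start from count
#' tables rather than alignments (e.g. calibration studies on simulated
#' sites). Sites are placed on a nominal chromosome at consecutive
#' positions unless coordinates are given.
#'
#' @param edited,coverage matrices (sites by samples/cells) or vectors
#' @param counting `"reads"` or `"umis"`
#' @param chrom,pos,ref,alt optional site coordinates and bases
#' @param geneId optional gene assignment, stored in `rowData`
#' @param sample per-column sample labels
#' @return a [SiteExperiment-class]
#' @export
makeSiteExperiment <- function(edited, coverage, counting = "umis",
                               chrom = "chr1", pos = NULL,
                               ref = "A", alt = "G", geneId = NULL,
                               sample = NULL) {
  edited <- as.matrix(edited); coverage <- as.matrix(coverage)
  m <- nrow(edited)
  pos <- pos %||% seq_len(m)
  rr <- GRanges(rep(chrom, length.out = m), IRanges(pos, pos))
  ref <- rep(ref, length.out = m); alt <- rep(alt, length.out = m)
  names(rr) <- siteKey(as.character(seqnames(rr)), pos, ref, alt)
  cols <- colnames(edited) %||% paste0("s", seq_len(ncol(edited)))
  colnames(edited) <- colnames(coverage) <- cols
  se <- SummarizedExperiment(
    assays = list(edited = edited, coverage = coverage),
    rowRanges = rr,
    colData = DataFrame(sample = sample %||% cols, row.names = cols))
  rowData(se)$ref <- ref
  rowData(se)$alt <- alt
  rowData(se)$refTx <- "A"
  rowData(se)$altTx <- "G"
  if (!is.null(geneId)) rowData(se)$gene_id <- rep(geneId, length.out = m)
  new("SiteExperiment", se, counting = counting)
}

#' Simulate per-site edit counts for caller calibration studies
#'
#' Draws experimental and control counts at a set of sites: planted sites
#' edit at their own frequency, null sites and the control at the
#' beta-binomial background (`backgroundMu`, `backgroundRho`; `rho = 0`
#' gives binomial noise). Coverage is drawn uniformly within
#' `coverageRange` for the experiment and `controlCoverageRange` for the
#' control.
#'
#' @param nTrue,nNull numbers of planted and null sites
#' @param trueFreq editing frequency of planted sites (scalar, vector, or
#'   range to draw uniformly from)
#' @param coverageRange,controlCoverageRange inclusive coverage windows
#' @param backgroundMu,backgroundRho background model parameters
#' @param seed integer seed
#' @return list with `experimental` and `control`
#'   [SiteExperiment-class]s over the same sites and a logical `isTrue`
#'   vector.
#' @export
simulateSiteCounts <- function(nTrue = 500, nNull = 500,
                               trueFreq = c(0.1, 0.5),
                               coverageRange = c(30, 200),
                               controlCoverageRange = c(30, 200),
                               backgroundMu = 0.005, backgroundRho = 0.02,
                               seed = 0) {
  set.seed(seed)
  m <- nTrue + nNull
  isTrue <- c(rep(TRUE, nTrue), rep(FALSE, nNull))
  f <- if (length(trueFreq) == 2 && nTrue != 2)
    stats::runif(nTrue, trueFreq[1], trueFreq[2])
  else rep(trueFreq, length.out = nTrue)

  rcov <- function(n, rng) sample(seq(rng[1], rng[2]), n, replace = TRUE)
  rbg <- function(n, size) {
    p <- if (backgroundRho > 0) {
      ab <- muRhoToAlphaBeta(backgroundMu, backgroundRho)
      stats::rbeta(n, ab["alpha"], ab["beta"])
    } else rep(backgroundMu, n)
    stats::rbinom(n, size, p)
  }

  nExp <- rcov(m, coverageRange)
  kExp <- integer(m)
  kExp[isTrue] <- stats::rbinom(nTrue, nExp[isTrue], f)
  kExp[!isTrue] <- rbg(nNull, nExp[!isTrue])
  nCtl <- rcov(m, controlCoverageRange)
  kCtl <- rbg(m, nCtl)

  list(
    experimental = makeSiteExperiment(cbind(experimental = kExp),
                                      cbind(experimental = nExp)),
    control = makeSiteExperiment(cbind(control = kCtl),
                                 cbind(control = nCtl)),
    isTrue = isTrue, trueFreq = f)
}

#' Simulate edited counts along a pseudotime for dynamic-binding studies
#'
#' Draws per-cell pseudotime uniformly on [0, 1], log-normal cell depths,
#' and negative-binomial edited counts whose mean scales with cell depth.
#' Planted genes follow a sigmoidal binding trend along pseudotime (rate
#' rising from `baseRate` to `baseRate * foldChange` around a gene-specific
#' midpoint); null genes stay flat at `baseRate`.
#'
#' @param nGenes,nPlanted total and dynamically bound gene counts
#' @param nCells number of cells
#' @param baseRate expected edited UMIs per 10,000 total UMIs at baseline
#' @param foldChange sigmoid plateau fold-change for planted genes
#' @param steepness logistic slope of the trend
#' @param dispersion NB size parameter (larger = closer to Poisson)
#' @param medianDepth,sdLogDepth per-cell total-UMI model
#' @param seed integer seed
#' @return list: `counts` (genes by cells), `totals`, `pseudotime`
#'   (data.frame barcode/pseudotime), `planted` (gene ids).
#' @export
simulateDynamicCounts <- function(nGenes = 500, nPlanted = 50,
                                  nCells = 300, baseRate = 3,
                                  foldChange = 4, steepness = 10,
                                  dispersion = 10,
                                  medianDepth = 10000, sdLogDepth = 0.3,
                                  seed = 0) {
  set.seed(seed)
  barcode <- sprintf("cell%05d", seq_len(nCells))
  pt <- stats::runif(nCells)
  totals <- stats::setNames(
    round(stats::rlnorm(nCells, log(medianDepth), sdLogDepth)), barcode)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  planted <- genes[seq_len(nPlanted)]
  mid <- stats::runif(nPlanted, 0.25, 0.75)

  counts <- matrix(0L, nGenes, nCells, dimnames = list(genes, barcode))
  base <- baseRate * stats::rlnorm(nGenes, 0, 0.2)
  for (i in seq_len(nGenes)) {
    rate <- base[i]
    if (i <= nPlanted)
      rate <- rate * (1 + (foldChange - 1) *
                        stats::plogis(steepness * (pt - mid[i])))
    mu <- rate * totals / 1e4
    counts[i, ] <- stats::rnbinom(nCells, size = dispersion, mu = mu)
  }
  list(counts = counts, totals = totals,
       pseudotime = data.frame(barcode = barcode, pseudotime = pt,
                               stringsAsFactors = FALSE),
       planted = planted)
}
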