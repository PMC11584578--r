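#' Simulate the ground truth of a TRIBE experiment
#'
#' Draws a toy genome, non-overlapping multi-exon gene models, planted edit
#' sites with per-state editing frequencies, germline SNPs, and a cell
#' population with state labels, droplet depths, and per-cell PCR-duplication
#' rates. The defaults emulate a heterogeneous stem-cell culture: three
#' states at proportions 0.961 / 0.029 / 0.010 (a dominant pluripotent pool,
#' an intermediate population, and a rare totipotent-like state), log-normal
#' per-cell depth with median 10,000 UMIs, and a Gamma-distributed per-cell
#' PCR duplication rate.
#'
#' @param nGenes number of genes on the toy chromosome.
#' @param nCells number of cells (experimental + control).
#' @param states named numeric vector of state proportions (must sum to 1).
#' @param siteFreq editing frequency of planted sites in experimental cells:
#'   a scalar, a per-site vector, or a sites-by-states matrix for
#'   state-specific binding.
#' @param sitesPerGene planted edit sites per gene.
#' @param exonsPerGene,exonLength,intronLength,spacer gene geometry (bp).
#' @param negativeFraction fraction of experimental cells with near-zero
#'   fusion expression (their editing is scaled by `negativeScale`).
#' @param negativeScale editing-frequency multiplier in negative cells.
#' @param controlFraction fraction of cells assigned to the ADAR-only
#'   control sample.
#' @param backgroundMu background editing rate (control cells, all sites).
#' @param errorRate per-base sequencing error probability.
#' @param dupShape,dupRate Gamma(shape, rate) law of the per-cell PCR
#'   duplication intensity; reads per UMI are `1 + Poisson(lambda_cell)`.
#' @param medianDepth,sdLogDepth log-normal per-cell total-UMI model.
#' @param nSnps planted germline heterozygous variants.
#' @param stateWeights optional genes-by-states matrix of expression
#'   multipliers (columns named by state), for planting state-specific
#'   expression differences; default: expression identical across states.
#' @param seed integer seed; identical seeds give identical truths.
#' @return a [SyntheticTruth-class] object.
#' @examples
#' truth <- simulateTruth(nGenes = 10, nCells = 200, seed = 1)
#' table(truthCells(truth)$state)
#' @export
simulateTruth <- function(nGenes = 40, nCells = 1000,
    states = c(pluripotent = 0.961, intermediate = 0.029, twoCLC = 0.010),
    siteFreq = 0.3, sitesPerGene = 1,
    exonsPerGene = 2, exonLength = 300L, intronLength = 120L, spacer = 200L,
    negativeFraction = 0, negativeScale = 0.01,
    controlFraction = 0.25, backgroundMu = 0.005, errorRate = 1e-3,
    dupShape = 4, dupRate = 4,
    medianDepth = 10000, sdLogDepth = 0.4,
    nSnps = 5, stateWeights = NULL, seed = 0) {

  if (abs(sum(states) - 1) > 1e-8)
    stop("state proportions must sum to 1")
  if (any(states < 0)) stop("state proportions must be non-negative")
  nSites <- nGenes * sitesPerGene
  freq <- siteFreqMatrix(siteFreq, nSites, names(states))
  if (any(freq < 0 | freq > 1))
    stop("editing frequencies must lie in [0, 1]")
  if (negativeFraction < 0 || negativeFraction > 1)
    stop("negativeFraction must lie in [0, 1]")

  set.seed(seed)
  geneLength <- exonsPerGene * exonLength + (exonsPerGene - 1L) * intronLength
  chromLen <- nGenes * (geneLength + spacer) + spacer
  genomeChars <- sample(DNA_BASES, chromLen, replace = TRUE)

  geneIds <- sprintf("gene%03d", seq_len(nGenes))
  starts <- spacer + (seq_len(nGenes) - 1L) * (geneLength + spacer) + 1L
  strands <- rep(c("+", "-"), length.out = nGenes)
  genes <- data.frame(gene_id = geneIds, chrom = "chr1", strand = strands,
                      start = starts, end = starts + geneLength - 1L,
                      weight = NA_real_, stringsAsFactors = FALSE)
  w <- stats::rgamma(nGenes, shape = 1)
  genes$weight <- w / sum(w)
  if (!is.null(stateWeights)) {
    stopifnot(nrow(stateWeights) == nGenes,
              all(names(states) %in% colnames(stateWeights)),
              all(stateWeights >= 0))
    for (s in names(states))
      genes[[paste0("weight.", s)]] <- stateWeights[, s]
  }

  exons <- do.call(rbind, lapply(seq_len(nGenes), function(i) {
    es <- starts[i] + (seq_len(exonsPerGene) - 1L) * (exonLength + intronLength)
    data.frame(gene_id = geneIds[i], chrom = "chr1",
               start = es, end = es + exonLength - 1L,
               strand = strands[i], stringsAsFactors = FALSE)
  }))

  # plant sites inside exons; force the reference base so the edit is A-to-G
  # in transcript space (genomic A on plus-strand genes, T on minus-strand)
  sites <- do.call(rbind, lapply(seq_len(nGenes), function(i) {
    ex <- exons[exons$gene_id == geneIds[i], ]
    posPool <- unlist(mapply(seq, ex$start, ex$end, SIMPLIFY = FALSE))
    pos <- sort(sample(posPool, sitesPerGene))
    data.frame(gene_id = geneIds[i], chrom = "chr1", pos = pos,
               strand = strands[i], stringsAsFactors = FALSE)
  }))
  sites <- cbind(site_id = sprintf("site%04d", seq_len(nrow(sites))), sites,
                 stringsAsFactors = FALSE)
  genomeChars[sites$pos] <- ifelse(sites$strand == "+", "A", "T")
  for (s in names(states)) sites[[paste0("freq.", s)]] <- freq[, s]

  snps <- data.frame(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0))
  if (nSnps > 0) {
    pool <- setdiff(seq_len(chromLen), sites$pos)
    snpPos <- sort(sample(pool, nSnps))
    ref <- genomeChars[snpPos]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                  character(1))
    snps <- data.frame(chrom = "chr1", pos = snpPos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
  }

  barcodes <- sprintf("CELL%05d", seq_len(nCells))
  sampleLab <- ifelse(stats::runif(nCells) < controlFraction,
                      "control", "experimental")
  state <- sample(names(states), nCells, replace = TRUE, prob = states)
  negative <- sampleLab == "experimental" &
    stats::runif(nCells) < negativeFraction
  cells <- data.frame(
    barcode = barcodes, sample = sampleLab, state = state,
    negative = negative,
    depth = stats::rlnorm(nCells, log(medianDepth), sdLogDepth),
    dup_lambda = if (dupShape <= 0) rep(0, nCells) else
      stats::rgamma(nCells, shape = dupShape, rate = dupRate),
    stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(paste(genomeChars, collapse = ""))
  names(genome) <- "chr1"

  new("SyntheticTruth", genome = genome, genes = genes, exons = exons,
      sites = sites, snps = snps, cells = cells,
      params = list(
        proportions = as.list(states), negative_fraction = negativeFraction,
        negative_scale = negativeScale, control_fraction = controlFraction,
        background_mu = backgroundMu, error_rate = errorRate,
        dup_shape = dupShape, dup_rate = dupRate,
        median_depth = medianDepth, sd_log_depth = sdLogDepth,
        seed = seed))
}

siteFreqMatrix <- function(siteFreq, nSites, stateNames) {
  nStates <- length(stateNames)
  if (is.matrix(siteFreq)) {
    if (ncol(siteFreq) != nStates)
      stop("siteFreq matrix needs one column per state")
    m <- siteFreq[rep(seq_len(nrow(siteFreq)), length.out = nSites), ,
                  drop = FALSE]
  } else {
    m <- matrix(rep(siteFreq, length.out = nSites), nSites, nStates)
  }
  colnames(m) <- stateNames
  m
}

#' @describeIn SyntheticTruth per-cell table (barcode, sample, state,
#'   negative flag, depth, duplication rate)
#' @param truth a `SyntheticTruth`
#' @export
truthCells <- function(truth) truth@cells

#' @describeIn SyntheticTruth planted-site table with per-state frequencies
#' @export
truthSites <- function(truth) truth@sites

#' @describeIn SyntheticTruth per-gene table
#' @export
truthGenes <- function(truth) truth@genes

#' @describeIn SyntheticTruth per-exon table (1-based inclusive)
#' @export
truthExons <- function(truth) truth@exons

#' @describeIn SyntheticTruth generative parameter list
#' @export
truthParams <- function(truth) truth@params

#' Gene and exon models of a synthetic truth as GRanges
#' @param truth a [SyntheticTruth-class]
#' @return a `GRanges` of genes with a `gene_id` column
#' @export
truthGeneRanges <- function(truth) {
  g <- truth@genes
  GRanges(g$chrom, IRanges(g$start, g$end), strand = g$strand,
          gene_id = g$gene_id)
}

#' @rdname truthGeneRanges
#' @export
truthExonRanges <- function(truth) {
  e <- truth@exons
  GRanges(e$chrom, IRanges(e$start, e$end), strand = e$strand,
          gene_id = e$gene_id)
}

#' Serialize / restore a synthetic truth
#'
#' Writes the truth as plain-text files (FASTA genome, TSV tables, JSON
#' parameters) so a round trip through [loadTruth()] is lossless.
#'
#' @param truth a [SyntheticTruth-class]
#' @param dir output directory (created if missing)
#' @return `saveTruth` the directory, invisibly; `loadTruth` the restored
#'   [SyntheticTruth-class].
#' @export
saveTruth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(truth@genome, file.path(dir, "genome.fa"))
  writeTsv(truth@genes, file.path(dir, "genes.tsv"))
  writeTsv(truth@exons, file.path(dir, "exons.tsv"))
  writeTsv(truth@sites, file.path(dir, "sites.tsv"))
  writeTsv(truth@snps, file.path(dir, "snps.tsv"))
  writeTsv(truth@cells, file.path(dir, "cells.tsv"))
  jsonlite::write_json(truth@params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveTruth
#' @export
loadTruth <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  params$proportions <- as.list(params$proportions)
  new("SyntheticTruth",
      genome = Biostrings::readDNAStringSet(file.path(dir, "genome.fa")),
      genes = readTsv(file.path(dir, "genes.tsv")),
      exons = readTsv(file.path(dir, "exons.tsv")),
      sites = readTsv(file.path(dir, "sites.tsv")),
      snps = readTsv(file.path(dir, "snps.tsv")),
      cells = readTsv(file.path(dir, "cells.tsv")),
      params = params)
}
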