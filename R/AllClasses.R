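#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment rowData rowData<-
#'   colData colData<- assay assays assayNames rowRanges rowRanges<-
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#' @importFrom IRanges IRanges
NULL

#' Per-site edit counts across samples or cells
#'
#' A `SiteExperiment` holds candidate RNA-edit sites as rows (a [GRanges] of
#' single-base positions with `ref` and `alt` base annotations) and samples
#' (bulk, read-level counts) or cells (single-cell, UMI-level counts) as
#' columns. Two integer assays are required: `edited` (reads or UMIs carrying
#' the alternative base) and `coverage` (reads or UMIs covering the site with
#' a usable base call). Downstream steps attach per-site statistics
#' (`gene_id`, `tx_strand`, `p`, `fdr`, filter flags) to `rowData`.
#'
#' @slot counting either `"reads"` or `"umis"`, recorded by [pileupCounts()].
#' @export
setClass("SiteExperiment",
  contains = "RangedSummarizedExperiment",
  representation(counting = "character"),
  prototype(counting = "reads")
)

setValidity("SiteExperiment", function(object) {
  msg <- NULL
  if (!all(c("edited", "coverage") %in% assayNames(object)))
    msg <- c(msg, "assays 'edited' and 'coverage' are required")
  else {
    k <- assay(object, "edited")
    n <- assay(object, "coverage")
    if (min(k) < 0 || min(n) < 0)
      msg <- c(msg, "counts must be non-negative")
    if (any(as.vector(k > n)))
      msg <- c(msg, "edited counts must not exceed coverage")
  }
  if (!length(object@counting) == 1L ||
      !object@counting %in% c("reads", "umis"))
    msg <- c(msg, "counting must be 'reads' or 'umis'")
  if (nrow(object) > 0 &&
      !all(c("ref", "alt") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must carry 'ref' and 'alt' bases")
  if (is.null(msg)) TRUE else msg
})

#' Beta-binomial background model of control editing
#'
#' Captures the editing-frequency distribution of the ADAR-only control:
#' a beta-binomial with mean `mu = alpha/(alpha+beta)` and overdispersion
#' `rho = 1/(alpha+beta+1)`. When the control shows no extra-binomial
#' dispersion the model degenerates to a binomial (`rho = 0`). A per-site
#' table (pooling `"per_site"`) stores site-specific means sharing the
#' global overdispersion; sites with sparse control coverage fall back to
#' the pooled model.
#'
#' @slot mu pooled mean editing rate, floored at `rateFloor`.
#' @slot rho overdispersion in `[0, 1)`; 0 means binomial.
#' @slot alpha,beta beta parameters (Inf allowed when `rho = 0`).
#' @slot method fitting method tag ("mom+ml", "mom", "binomial").
#' @slot rateFloor minimum admissible rate, guards zero-rate degeneracy.
#' @slot pooling `"global"` or `"per_site"`.
#' @slot perSite `DataFrame` keyed by `site` with per-site `mu` and control
#'   coverage `n`, empty for global pooling.
#' @export
setClass("BackgroundModel",
  representation(
    mu = "numeric", rho = "numeric",
    alpha = "numeric", beta = "numeric",
    method = "character", rateFloor = "numeric",
    pooling = "character", perSite = "DataFrame"
  ),
  prototype(pooling = "global", perSite = DataFrame())
)

setValidity("BackgroundModel", function(object) {
  msg <- NULL
  if (object@mu <= 0 || object@mu >= 1)
    msg <- c(msg, "mu must lie in (0, 1)")
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "rho must lie in [0, 1)")
  if (object@rho > 0 && (object@alpha <= 0 || object@beta <= 0))
    msg <- c(msg, "alpha and beta must be positive when rho > 0")
  if (is.null(msg)) TRUE else msg
})

#' Genes-by-cells edited-UMI matrix (the editome)
#'
#' An `Editome` extends [SingleCellExperiment] with a primary integer assay
#' `edited` counting, per gene and cell, the UMIs edited at significant
#' exonic sites. `colData` carries the per-cell totals the QC and
#' normalization steps need: `totalUMIs` (transcriptome depth),
#' `editedUMIs`, `editedTranscripts` (genes with >= 1 edited UMI),
#' `mitoFraction`, and `sample`. [normalizeBinding()] adds a `binding`
#' assay with log1p(edited / totalUMIs * 1e4) values.
#'
#' @export
setClass("Editome", contains = "SingleCellExperiment")

setValidity("Editome", function(object) {
  msg <- NULL
  if (!"edited" %in% assayNames(object))
    msg <- c(msg, "assay 'edited' is required")
  else if (min(assay(object, "edited")) < 0)
    msg <- c(msg, "edited counts must be non-negative")
  need <- c("totalUMIs", "editedUMIs", "editedTranscripts", "mitoFraction")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData lacks:", paste(miss, collapse = ", ")))
  if (is.null(msg) && ncol(object) > 0) {
    cs <- Matrix::colSums(assay(object, "edited"))
    if (!isTRUE(all.equal(unname(cs), unname(object$editedUMIs))))
      msg <- "editedUMIs must equal the column sums of 'edited'"
  }
  if (is.null(msg)) TRUE else msg
})

#' Ground truth of a synthetic TRIBE experiment
#'
#' Records everything the synthetic generator planted: the toy genome, gene
#' models, edit sites with per-state editing frequencies, per-cell state
#' assignments, and the generative parameters (depth model, PCR duplication,
#' sequencing error, background rate, germline SNPs). Downstream recovery
#' tests score calls against this object.
#'
#' @slot genome a [Biostrings::DNAStringSet] toy reference.
#' @slot genes per-gene table (gene_id, chrom, strand, weight).
#' @slot exons per-exon table (gene_id, chrom, start, end, strand), 1-based
#'   inclusive coordinates.
#' @slot sites planted edit sites (site_id, gene_id, chrom, pos, strand and
#'   one `freq.<state>` column per cell state).
#' @slot snps planted germline variants (chrom, pos, ref, alt).
#' @slot cells per-cell table (barcode, sample, state, negative, depth,
#'   dup_lambda).
#' @slot params list of generative parameters including `seed`.
#' @export
setClass("SyntheticTruth",
  representation(
    genome = "DNAStringSet", genes = "data.frame", exons = "data.frame",
    sites = "data.frame", snps = "data.frame", cells = "data.frame",
    params = "list"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- NULL
  fcols <- grep("^freq\\.", colnames(object@sites), value = TRUE)
  if (nrow(object@sites)) {
    fr <- as.matrix(object@sites[, fcols, drop = FALSE])
    if (any(fr < 0 | fr > 1))
      msg <- c(msg, "editing frequencies must lie in [0, 1]")
  }
  pr <- unlist(object@params$proportions)
  if (!is.null(pr) && abs(sum(pr) - 1) > 1e-8)
    msg <- c(msg, "state proportions must sum to 1")
  if (nrow(object@sites)) {
    ex <- object@exons
    ok <- vapply(seq_len(nrow(object@sites)), function(i) {
      s <- object@sites[i, ]
      any(ex$gene_id == s$gene_id & ex$start <= s$pos & ex$end >= s$pos)
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "every planted site must lie within an exon of its gene")
  }
  if (nrow(object@exons)) {
    gr <- GRanges(object@exons$chrom,
                  IRanges(object@exons$start, object@exons$end))
    hit <- GenomicRanges::findOverlaps(gr, gr)
    off <- hit[object@exons$gene_id[S4Vectors::queryHits(hit)] !=
               object@exons$gene_id[S4Vectors::subjectHits(hit)]]
    if (length(off))
      msg <- c(msg, "gene models overlap on the genome")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SiteExperiment counting mode ("reads" or "umis")
#' @param x a `SiteExperiment`
#' @export
countingMode <- function(x) x@counting

setMethod("show", "SiteExperiment", function(object) {
  callNextMethod()
  cat("counting:", object@counting, "\n")
  if ("significant" %in% colnames(rowData(object)))
    cat("significant sites:", sum(rowData(object)$significant), "\n")
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel (", object@method, ", pooling=", object@pooling,
      ")\n  mu=", signif(object@mu, 4), " rho=", signif(object@rho, 4),
      " floor=", object@rateFloor, "\n", sep = "")
  if (nrow(object@perSite))
    cat("  per-site entries:", nrow(object@perSite), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@genes), "genes,",
      nrow(object@sites), "planted sites,",
      nrow(object@cells), "cells,",
      length(object@params$proportions), "states\n")
})
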