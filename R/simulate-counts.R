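#' Simulate editome and expression counts directly (alignment-free fast path)
#'
#' Bypasses read simulation and draws, per cell and gene, total UMIs from a
#' multinomial over gene weights at the cell's log-normal depth, and edited
#' UMIs from a binomial at the cell state's gene-level editing probability
#' (one molecule is edited if it is edited at any planted site of the gene,
#' so the gene-level probability is `1 - prod(1 - f_site)`). Control-sample
#' cells edit at the background rate; negative experimental cells at the
#' state frequency scaled by `negative_scale`. Edited read counts are also
#' drawn (`k + Poisson(k * lambda_cell)`) so UMI-vs-read variability is
#' testable without alignments.
#'
#' @param truth a [SyntheticTruth-class]
#' @param seed integer seed
#' @return an [Editome-class] with assays `edited`, `editedReads`, and
#'   `total` (per-gene total UMIs); `colData` carries sample, state,
#'   negative flag and QC totals.
#' @examples
#' truth <- simulateTruth(nGenes = 20, nCells = 100, seed = 1)
#' ed <- simulateEditomeCounts(truth, seed = 1)
#' ed
#' @export
simulateEditomeCounts <- function(truth, seed = 0) {
  set.seed(seed)
  genes <- truth@genes
  cells <- truth@cells
  p <- truth@params
  states <- names(p$proportions)
  nG <- nrow(genes); nC <- nrow(cells)

  # gene-level editing probability per state
  fcols <- paste0("freq.", states)
  probState <- sapply(states, function(s) {
    f <- truth@sites[[paste0("freq.", s)]]
    1 - vapply(genes$gene_id, function(g)
      prod(1 - f[truth@sites$gene_id == g]), numeric(1))
  })
  probState <- matrix(probState, nrow = nG,
                      dimnames = list(genes$gene_id, states))
  nSitesPerGene <- as.vector(table(
    factor(truth@sites$gene_id, levels = genes$gene_id)))
  probBg <- 1 - (1 - p$background_mu)^nSitesPerGene

  total <- matrix(0L, nG, nC, dimnames = list(genes$gene_id, cells$barcode))
  edited <- total
  editedReads <- total
  depth <- round(cells$depth)
  for (c in seq_len(nC)) {
    wc <- genes$weight
    swCol <- paste0("weight.", cells$state[c])
    if (swCol %in% colnames(genes)) wc <- wc * genes[[swCol]]
    t_g <- stats::rmultinom(1, depth[c], wc)[, 1]
    pr <- if (cells$sample[c] == "control") probBg
          else probState[, cells$state[c]] *
               (if (cells$negative[c]) p$negative_scale else 1)
    k <- stats::rbinom(nG, t_g, pr)
    total[, c] <- t_g
    edited[, c] <- k
    editedReads[, c] <- k + stats::rpois(nG, k * cells$dup_lambda[c])
  }

  makeEditome(
    edited = Matrix::Matrix(edited, sparse = TRUE),
    totalUMIs = colSums(total),
    extraAssays = list(
      editedReads = Matrix::Matrix(editedReads, sparse = TRUE),
      total = Matrix::Matrix(total, sparse = TRUE)),
    colData = DataFrame(sample = cells$sample, state = cells$state,
                        negative = cells$negative,
                        row.names = cells$barcode))
}

# assemble an Editome with consistent per-cell totals
makeEditome <- function(edited, totalUMIs, colData = NULL,
                        mitoFraction = NULL, sample = NULL,
                        extraAssays = list()) {
  cd <- colData %||% DataFrame(row.names = colnames(edited))
  cd$totalUMIs <- unname(totalUMIs)
  cd$editedUMIs <- unname(Matrix::colSums(edited))
  cd$editedTranscripts <- unname(Matrix::colSums(edited > 0))
  cd$mitoFraction <- if (is.null(mitoFraction)) 0 else unname(mitoFraction)
  if (!is.null(sample)) cd$sample <- sample
  if (is.null(cd$sample)) cd$sample <- "sample1"
  assays <- c(list(edited = edited), extraAssays)
  new("Editome", SingleCellExperiment::SingleCellExperiment(
    assays = assays, colData = cd))
}
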