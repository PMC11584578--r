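#' Cluster cells by their editome
#'
#' Standard single-cell community detection run on binding intensities:
#' the top `nHvg` highly variable genes (by variance of binding intensity)
#' are z-scaled (values capped at +/-10), reduced by PCA to `nPcs`
#' components, a shared-nearest-neighbor graph is built (Jaccard weights
#' over `kNN` Euclidean neighbors), and Louvain modularity optimization at
#' `resolution` assigns cluster labels. Deterministic for a fixed `seed`.
#'
#' @param ed an [Editome-class] carrying a `binding` assay
#'   (see [normalizeBinding()])
#' @param nHvg number of highly variable genes (all genes, with a warning,
#'   when fewer are available)
#' @param nPcs number of principal components
#' @param resolution Louvain resolution parameter
#' @param kNN neighbors for the SNN graph
#' @param prune minimum Jaccard weight for an SNN edge
#' @param seed RNG seed for the community search
#' @return factor of cluster labels named by cell.
#' @export
clusterEditome <- function(ed, nHvg = 600, nPcs = 8, resolution = 0.1,
                           kNN = 20, prune = 1 / 15, seed = 0) {
  b <- as.matrix(bindingIntensity(ed))
  v <- apply(b, 1, stats::var)
  if (nrow(b) < nHvg) {
    warning("fewer genes than nHvg; using all ", nrow(b), " genes")
    nHvg <- nrow(b)
  }
  hvg <- order(v, decreasing = TRUE)[seq_len(nHvg)]
  x <- b[hvg, , drop = FALSE]
  x <- x[apply(x, 1, stats::sd) > 0, , drop = FALSE]
  if (nrow(x) == 0)   # no variable gene at all: a single population
    return(stats::setNames(factor(rep(1L, ncol(ed))), colnames(ed)))
  z <- t(scale(t(x)))
  z[z > 10] <- 10; z[z < -10] <- -10

  nPcs <- min(nPcs, nrow(z) - 1L, ncol(z) - 1L)
  pcs <- stats::prcomp(t(z), center = TRUE, scale. = FALSE,
                       rank. = nPcs)$x

  g <- snnGraph(pcs, k = min(kNN, ncol(ed) - 1L), prune = prune)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- factor(igraph::membership(cl))
  names(labels) <- colnames(ed)
  labels
}

# shared-nearest-neighbor graph with Jaccard edge weights
snnGraph <- function(pcs, k, prune) {
  n <- nrow(pcs)
  d <- as.matrix(stats::dist(pcs))
  nbr <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k),
    j = as.vector(apply(d, 1, function(r) order(r)[2:(k + 1)])),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(nbr)
  jac <- shared / (2 * k - shared)
  jac[jac < prune] <- 0
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
}

#' Select the positive (sufficiently edited) cell population
#'
#' Cells cluster into populations of distinct editing depth; clusters whose
#' median edited-UMI total falls below `fraction` of the largest cluster
#' median are flagged as the negative population (cells without substantial
#' editing, e.g. with insufficient fusion expression) and excluded.
#'
#' @param labels cluster labels from [clusterEditome()]
#' @param ed the matching [Editome-class]
#' @param fraction negative threshold as a fraction of the maximum cluster
#'   median edited-UMI total
#' @return named logical vector, `TRUE` for positive cells.
#' @export
selectPositiveCells <- function(labels, ed, fraction = 0.25) {
  stopifnot(length(labels) == ncol(ed))
  med <- tapply(colData(ed)$editedUMIs, labels, stats::median)
  if (length(med) == 1L) {
    warning("single cluster; all cells taken as positive")
    return(stats::setNames(rep(TRUE, ncol(ed)), colnames(ed)))
  }
  negative <- med < fraction * max(med)
  mask <- !negative[as.character(labels)]
  stats::setNames(as.vector(mask), colnames(ed))
}
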