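#' Differentially bound transcripts between cell groups
#'
#' One-vs-rest marker analysis on binding intensities: for each group and
#' gene, a two-sided Wilcoxon rank-sum test compares the group's cells with
#' all other cells, and the fold-change is computed on expm1 of the mean
#' log-normalized values with a small pseudocount. A record is significant
#' when the absolute log2 fold-change exceeds `log2(fcMin)` and the raw
#' p-value is below `pMax` (raw p, no multiple-testing correction, mirroring
#' the standard marker-gene convention). Groups with fewer than `minCells`
#' cells are skipped with a warning.
#'
#' @param binding genes-by-cells matrix of binding intensities (natural-log
#'   scale, see [normalizeBinding()]), or an [Editome-class] with a
#'   `binding` assay
#' @param groups per-cell group labels (factor or character)
#' @param fcMin fold-change gate on the ratio scale (default 1.2, i.e.
#'   log2FC > 0.263)
#' @param pMax raw p-value gate
#' @param minCells minimum group size
#' @param pseudocount added to both expm1-means before the ratio (default
#'   1, the marker-analysis convention of the single-cell toolkit whose
#'   0.263 log2 gate is mirrored here; it stabilizes fold changes of weakly
#'   edited genes)
#' @param comparison `"one_vs_rest"` (the marker-analysis default) or
#'   `"pairwise"` (every ordered group pair; the `group` column then reads
#'   `"A_vs_B"`)
#' @return data.frame with one row per (gene, group): `log2FC`, `p`,
#'   `significant`, and the direction (`up` = higher binding in the group).
#' @export
findDbts <- function(binding, groups, fcMin = 1.2, pMax = 0.01,
                     minCells = 3, pseudocount = 1,
                     comparison = c("one_vs_rest", "pairwise")) {
  comparison <- match.arg(comparison)
  b <- if (is(binding, "Editome")) as.matrix(bindingIntensity(binding))
       else as.matrix(binding)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(b))
  if (nlevels(groups) < 2) stop("need at least two groups")
  small <- levels(groups)[table(groups)[levels(groups)] < minCells]
  for (g in small)
    warning("group '", g, "' has fewer than ", minCells, " cells; skipped")
  usable <- setdiff(levels(groups), small)

  res <- list()
  if (comparison == "one_vs_rest") {
    for (g in usable) {
      stats <- groupVsRest(b, groups == g, pseudocount)
      stats$group <- g
      res[[g]] <- stats
    }
  } else {
    for (g1 in usable) for (g2 in setdiff(usable, g1)) {
      sel <- groups %in% c(g1, g2)
      stats <- groupVsRest(b[, sel, drop = FALSE],
                           groups[sel] == g1, pseudocount)
      stats$group <- paste0(g1, "_vs_", g2)
      res[[stats$group[1]]] <- stats
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$significant <- abs(out$log2FC) > log2(fcMin) & out$p < pMax
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  out[c("gene", "group", "log2FC", "p", "significant", "direction")]
}

groupVsRest <- function(b, inG, pseudocount) {
  mIn <- rowMeans(expm1(b[, inG, drop = FALSE]))
  mOut <- rowMeans(expm1(b[, !inG, drop = FALSE]))
  log2FC <- log2((mIn + pseudocount) / (mOut + pseudocount))
  p <- vapply(seq_len(nrow(b)), function(i) {
    x <- b[i, inG]; y <- b[i, !inG]
    if (all(x == x[1]) && all(y == x[1])) return(1)
    # ties fall back to the normal approximation with tie correction
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  data.frame(gene = rownames(b) %||% as.character(seq_len(nrow(b))),
             log2FC = log2FC, p = p, stringsAsFactors = FALSE)
}

#' Classify significant DBTs as expression-dependent or -independent
#'
#' A binding difference may simply track transcript abundance. A
#' significant DBT is expression-dependent when the same gene also shows
#' higher expression in the same group (fold-change above `fcMin` with
#' p below `pMax` by the same one-vs-rest Wilcoxon test on normalized
#' expression); otherwise it is expression-independent. Genes missing from
#' the expression matrix get `NA` with a flag.
#'
#' @param dbts output of [findDbts()]
#' @param expression genes-by-cells normalized (log-scale) expression matrix
#' @param groups the same per-cell labels used for [findDbts()]
#' @param fcMin,pMax,pseudocount gates, as in [findDbts()]
#' @return `dbts` with `exprLog2FC`, `exprP`, and `dependence`
#'   ("expression_dependent" / "expression_independent", `NA` when the gene
#'   is absent from the expression matrix) for significant records.
#' @export
classifyDependence <- function(dbts, expression, groups, fcMin = 1.2,
                               pMax = 0.01, pseudocount = 1) {
  expression <- as.matrix(expression)
  groups <- as.factor(groups)
  dbts$exprLog2FC <- NA_real_
  dbts$exprP <- NA_real_
  dbts$dependence <- NA_character_
  sig <- which(dbts$significant)
  for (i in sig) {
    gene <- dbts$gene[i]
    if (!gene %in% rownames(expression)) next
    inG <- groups == dbts$group[i]
    x <- expression[gene, inG]; y <- expression[gene, !inG]
    mIn <- mean(expm1(x)); mOut <- mean(expm1(y))
    lfc <- log2((mIn + pseudocount) / (mOut + pseudocount))
    p <- if (all(c(x, y) == x[1])) 1 else
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    dbts$exprLog2FC[i] <- lfc
    dbts$exprP[i] <- p
    dbts$dependence[i] <- if (lfc > log2(fcMin) && p < pMax)
      "expression_dependent" else "expression_independent"
  }
  dbts
}

#' Relative binding intensity per group
#'
#' Separates binding changes from abundance changes: for each gene, the
#' group's relative editing level (group mean divided by the across-group
#' mean of group means) is divided by its relative expression level
#' (same construction, plus `epsilon`).
#'
#' @param editingMeans,expressionMeans genes-by-groups matrices of mean
#'   editing and mean expression levels (same genes and groups)
#' @param epsilon guard against zero relative expression
#' @return genes-by-groups matrix of relative binding intensities; rows
#'   with all-zero expression are `NA` (flagged undefined).
#' @export
relativeBindingIntensity <- function(editingMeans, expressionMeans,
                                     epsilon = 1e-9) {
  editingMeans <- as.matrix(editingMeans)
  expressionMeans <- as.matrix(expressionMeans)
  stopifnot(all(dim(editingMeans) == dim(expressionMeans)))
  relEdit <- editingMeans / rowMeans(editingMeans)
  relExpr <- expressionMeans / rowMeans(expressionMeans)
  out <- relEdit / (relExpr + epsilon)
  out[rowSums(expressionMeans) == 0, ] <- NA_real_
  out
}

#' Per-group mean levels of selected genes
#' @param mat genes-by-cells matrix (binding or expression)
#' @param groups per-cell labels
#' @param genes optional gene subset
#' @return genes-by-groups matrix of means
#' @export
groupMeans <- function(mat, groups, genes = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  groups <- as.factor(groups)
  sapply(levels(groups), function(g)
    rowMeans(mat[, groups == g, drop = FALSE]))
}
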