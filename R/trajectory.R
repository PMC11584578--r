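#' Read a per-cell pseudotime table
#'
#' Pseudotime is consumed, not computed: trajectory learning happens in an
#' external tool and its output (barcode, pseudotime, optional branch
#' label) is supplied as TSV.
#'
#' @param path TSV with columns `barcode`, `pseudotime`, and optionally
#'   `branch`
#' @return data.frame with those columns
#' @export
readPseudotime <- function(path) {
  pt <- readTsv(path)
  stopifnot(all(c("barcode", "pseudotime") %in% colnames(pt)))
  if (anyDuplicated(pt$barcode)) stop("duplicated barcodes in pseudotime")
  if (any(!is.finite(pt$pseudotime))) stop("non-finite pseudotime values")
  pt
}

#' Test for binding dynamics along pseudotime (dynamic DBTs)
#'
#' Per gene, fits two negative-binomial regressions of the edited-UMI
#' counts with a log total-UMI offset (so the modeled quantity is binding
#' intensity, not raw depth): a full model with a natural cubic spline of
#' pseudotime (`splineDf` degrees of freedom) and an intercept-only null.
#' The likelihood-ratio statistic is referred to a chi-square on the
#' degree-of-freedom difference; q-values are Benjamini-Hochberg across
#' converged genes. Genes with fewer than `minNonzero` nonzero cells are
#' skipped; non-converged fits are reported `NA` and excluded from the BH
#' correction. Branch comparisons are realized by subsetting `cells` to the
#' union of the two branch paths before calling this function.
#'
#' @param counts genes-by-cells edited-UMI counts
#' @param totals per-cell total UMIs (named or in column order)
#' @param pseudotime data.frame from [readPseudotime()] (or with the same
#'   columns); only cells present in both inputs are used, and at least 30
#'   are required
#' @param splineDf spline degrees of freedom (default 3)
#' @param minNonzero minimum nonzero cells per gene
#' @return data.frame per gene: `lrt`, `df`, `p`, `q`, `nNonzero`.
#' @export
dynamicDbtTest <- function(counts, totals, pseudotime, splineDf = 3,
                           minNonzero = 5) {
  prep <- alignPseudotime(counts, totals, pseudotime)
  if (ncol(prep$counts) < 30)
    stop("need at least 30 cells with pseudotime")
  ct <- prep$counts; off <- log(prep$totals); pt <- prep$pt

  basis <- splines::ns(pt, df = splineDf)
  res <- data.frame(gene = rownames(ct), lrt = NA_real_,
                    df = splineDf, p = NA_real_, q = NA_real_,
                    nNonzero = as.vector(rowSums(ct > 0)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ct))) {
    if (res$nNonzero[i] < minNonzero) next
    y <- ct[i, ]
    fit <- fitNbPair(y, basis, off)
    if (is.null(fit)) next
    res$lrt[i] <- fit$lrt
    res$p[i] <- stats::pchisq(fit$lrt, df = splineDf, lower.tail = FALSE)
  }
  ok <- !is.na(res$p)
  res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res
}

# full (spline) and null (intercept) NB fits. The gene-wise dispersion is
# ML-estimated and floored at 1e-6 (theta capped at 1e6): equidispersed
# counts push theta to infinity, where glm.nb's likelihood evaluation
# loses precision, so such fits are redone at the cap with a fixed-theta
# NB family. Both models share the constraint, keeping the pair nested.
THETA_MAX <- 1e6

fitNbPair <- function(y, basis, off) {
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  nbFit <- function(fml) {
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(fml, control = ctl)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$theta < THETA_MAX) return(fit)
    tryCatch(suppressWarnings(
      stats::glm(fml, family = MASS::negative.binomial(THETA_MAX),
                 control = ctl)),
      error = function(e) NULL)
  }
  full <- nbFit(y ~ basis + offset(off))
  null <- nbFit(y ~ 1 + offset(off))
  if (is.null(full) || is.null(null)) return(NULL)
  lrt <- max(0, 2 * (stats::logLik(full) - stats::logLik(null)))
  list(lrt = as.numeric(lrt), full = full, null = null)
}

alignPseudotime <- function(counts, totals, pseudotime) {
  counts <- as.matrix(counts)
  if (!is.null(names(totals)) && !is.null(colnames(counts)))
    totals <- totals[colnames(counts)]
  stopifnot(length(totals) == ncol(counts))
  common <- intersect(colnames(counts) %||%
                        as.character(seq_len(ncol(counts))),
                      pseudotime$barcode)
  if (!is.null(colnames(counts))) {
    idx <- match(common, colnames(counts))
    counts <- counts[, idx, drop = FALSE]
    totals <- totals[idx]
    pt <- pseudotime$pseudotime[match(common, pseudotime$barcode)]
  } else {
    pt <- pseudotime$pseudotime
  }
  list(counts = counts, totals = as.numeric(totals), pt = pt)
}

#' Smoothed binding profiles over a pseudotime grid
#'
#' Fits the full spline model per gene and evaluates its mean on an evenly
#' spaced grid spanning the observed pseudotime range (at the median cell
#' depth, so profiles are comparable across genes), then row-standardizes
#' for pattern grouping.
#'
#' @inheritParams dynamicDbtTest
#' @param genes optional gene subset (e.g. dynamic DBTs at `q < 0.01`)
#' @param gridSize number of grid points
#' @param standardize row-standardize (z-score) the fitted profiles
#' @return genes-by-grid matrix; `attr(, "grid")` holds the pseudotime grid.
#' @export
smoothProfiles <- function(counts, totals, pseudotime, genes = NULL,
                           splineDf = 3, gridSize = 100,
                           standardize = TRUE) {
  prep <- alignPseudotime(counts, totals, pseudotime)
  ct <- prep$counts
  if (!is.null(genes)) ct <- ct[genes, , drop = FALSE]
  off <- log(prep$totals); pt <- prep$pt
  grid <- seq(min(pt), max(pt), length.out = gridSize)
  basis <- splines::ns(pt, df = splineDf)
  newBasis <- stats::predict(basis, grid)
  offRef <- log(stats::median(prep$totals))

  prof <- matrix(NA_real_, nrow(ct), gridSize,
                 dimnames = list(rownames(ct), NULL))
  for (i in seq_len(nrow(ct))) {
    fit <- fitNbPair(ct[i, ], basis, off)
    if (is.null(fit)) next
    beta <- stats::coef(fit$full)
    eta <- cbind(1, newBasis) %*% beta + offRef
    prof[i, ] <- exp(eta)
  }
  prof <- prof[stats::complete.cases(prof), , drop = FALSE]
  if (standardize) {
    s <- apply(prof, 1, stats::sd)
    prof <- (prof - rowMeans(prof)) / ifelse(s > 0, s, 1)
  }
  attr(prof, "grid") <- grid
  prof
}

#' Group smoothed binding profiles into patterns
#'
#' Hierarchical clustering of standardized profiles (correlation distance,
#' complete linkage) cut at `k` groups; genes are ordered by group and,
#' within a group, by the position of the profile peak along pseudotime.
#'
#' @param smoothed standardized profile matrix from [smoothProfiles()]
#' @param k number of pattern groups
#' @return data.frame (gene, group, peak, order) in display order.
#' @export
groupPatterns <- function(smoothed, k) {
  if (k > nrow(smoothed)) stop("k exceeds the number of genes")
  peak <- apply(smoothed, 1, which.max)
  if (k == 1L) {
    grp <- rep(1L, nrow(smoothed))
  } else {
    cc <- stats::cor(t(smoothed))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
    grp <- stats::cutree(hc, k = k)
  }
  ord <- order(grp, peak)
  data.frame(gene = rownames(smoothed)[ord], group = grp[ord],
             peak = peak[ord], order = seq_along(ord),
             stringsAsFactors = FALSE)
}
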