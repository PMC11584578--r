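#' Compare read-level and UMI-level count variability across cells
#'
#' For every edited transcript, computes the coefficient of variation
#' (CV% = 100 * sd / mean) of its read counts and of its UMI counts across
#' cells. Transcripts are tiered by quartiles of their average edited UMI
#' count (low: below Q1; median: Q1-Q3; high: above Q3) and a paired
#' two-sided Wilcoxon test contrasts the two CVs within each tier. UMI
#' collapsing removes cell-to-cell PCR-amplification noise, so UMI CVs are
#' expected below read CVs.
#'
#' @param readCounts,umiCounts transcripts-by-cells count matrices on the
#'   same transcripts and cells
#' @return list with `records` (transcript, tier, meanUmi, cvRead, cvUmi)
#'   and `tests` (tier, n, p from the paired Wilcoxon test).
#' @export
cvComparison <- function(readCounts, umiCounts) {
  stopifnot(all(dim(readCounts) == dim(umiCounts)))
  readCounts <- as.matrix(readCounts)
  umiCounts <- as.matrix(umiCounts)
  meanUmi <- rowMeans(umiCounts)
  meanRead <- rowMeans(readCounts)
  keep <- meanUmi > 0 & meanRead > 0
  cvp <- function(m, mu) 100 * apply(m, 1, stats::sd) / mu
  rec <- data.frame(
    transcript = rownames(umiCounts) %||%
      as.character(seq_len(nrow(umiCounts))),
    meanUmi = meanUmi,
    cvRead = cvp(readCounts, meanRead),
    cvUmi = cvp(umiCounts, meanUmi),
    stringsAsFactors = FALSE)[keep, ]

  q <- stats::quantile(rec$meanUmi, c(0.25, 0.75))
  rec$tier <- cut(rec$meanUmi, c(-Inf, q[1], q[2], Inf),
                  labels = c("low", "median", "high"), right = FALSE)
  rec$tier[rec$meanUmi == q[2]] <- "median"  # Q3 itself is mid-tier

  tests <- do.call(rbind, lapply(levels(rec$tier), function(tier) {
    sub <- rec[rec$tier == tier, ]
    p <- if (nrow(sub) >= 2 && any(sub$cvRead != sub$cvUmi))
      stats::wilcox.test(sub$cvRead, sub$cvUmi, paired = TRUE,
                         exact = FALSE)$p.value
    else 1
    data.frame(tier = tier, n = nrow(sub), p = p)
  }))
  list(records = rec, tests = tests)
}
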