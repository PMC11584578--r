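test_that("state labels are drawn at the configured proportions", {
  states <- c(pluripotent = 0.961, intermediate = 0.029, twoCLC = 0.010)
  truth <- simulateTruth(nGenes = 5, nCells = 10000, states = states,
                         seed = 123)
  obs <- table(factor(truthCells(truth)$state, levels = names(states)))
  gof <- chisq.test(obs, p = states)
  expect_gt(gof$p.value, 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(simulateTruth(states = c(a = 0.6, b = 0.5)), "sum to 1")
  expect_error(simulateTruth(siteFreq = 1.5), "\\[0, 1\\]")
  expect_error(simulateTruth(negativeFraction = 2), "negativeFraction")
})

test_that("planted sites lie in exons and carry the editable ref base", {
  truth <- simulateTruth(nGenes = 8, nCells = 20, sitesPerGene = 3,
                         seed = 2)
  s <- truthSites(truth)
  ex <- truthExons(truth)
  g <- as.character(truth@genome[[1]])
  for (i in seq_len(nrow(s))) {
    expect_true(any(ex$gene_id == s$gene_id[i] & ex$start <= s$pos[i] &
                      ex$end >= s$pos[i]))
    expect_identical(substr(g, s$pos[i], s$pos[i]),
                     if (s$strand[i] == "+") "A" else "T")
  }
})

test_that("serialization round trip is lossless and seed-reproducible", {
  truth <- simulateTruth(nGenes = 6, nCells = 50, seed = 9)
  d1 <- file.path(tempdir(), "truth-a")
  d2 <- file.path(tempdir(), "truth-b")
  saveTruth(truth, d1)
  back <- loadTruth(d1)
  expect_equal(truthCells(back), truthCells(truth))
  expect_equal(truthSites(back), truthSites(truth))
  expect_equal(truthGenes(back), truthGenes(truth))
  expect_equal(truthParams(back), truthParams(truth))
  expect_identical(as.character(back@genome), as.character(truth@genome))

  saveTruth(simulateTruth(nGenes = 6, nCells = 50, seed = 9), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("editome counts follow the law of total expectation", {
  truth <- simulateTruth(nGenes = 30, nCells = 2000, states = c(S = 1),
                         siteFreq = 0.3, controlFraction = 0,
                         medianDepth = 5000, seed = 5)
  ed <- simulateEditomeCounts(truth, seed = 5)
  k <- as.matrix(SummarizedExperiment::assay(ed, "edited"))
  t_ <- as.matrix(SummarizedExperiment::assay(ed, "total"))
  # E[k] = f * E[t]; compare pooled per-gene means within 3 SE
  f <- 0.3
  km <- rowMeans(k); tm <- rowMeans(t_)
  se <- sqrt(rowMeans(t_) * f * (1 - f) / ncol(k)) +
    f * apply(t_, 1, sd) / sqrt(ncol(k))
  expect_true(all(abs(km - f * tm) < 3 * se + 1e-8))
})

test_that("zero-frequency genes yield all-zero edited columns", {
  freq <- matrix(c(0, 0.4), nrow = 10, ncol = 2, byrow = TRUE,
                 dimnames = list(NULL, c("off", "on")))
  truth <- simulateTruth(nGenes = 10, nCells = 200,
                         states = c(off = 0.5, on = 0.5), siteFreq = freq,
                         controlFraction = 0, seed = 3)
  ed <- simulateEditomeCounts(truth, seed = 3)
  offCells <- ed$state == "off"
  expect_true(all(SummarizedExperiment::assay(ed, "edited")[, offCells] == 0))
  expect_gt(sum(SummarizedExperiment::assay(ed, "edited")[, !offCells]), 0)
})

test_that("negative cells appear at the configured fraction with low editing", {
  truth <- simulateTruth(nGenes = 20, nCells = 3000, states = c(S = 1),
                         siteFreq = 0.3, negativeFraction = 0.2,
                         controlFraction = 0, seed = 7)
  cells <- truthCells(truth)
  expect_lt(abs(mean(cells$negative) - 0.2), 0.03)
  ed <- simulateEditomeCounts(truth, seed = 7)
  expect_lt(median(ed$editedUMIs[ed$negative]),
            0.05 * median(ed$editedUMIs[!ed$negative]))
})

test_that("empirical frequency converges to the planted frequency", {
  # pooled over ~10,000 molecules per gene, within 3 binomial SEs
  truth <- simulateTruth(nGenes = 5, nCells = 1000, states = c(S = 1),
                         siteFreq = 0.25, controlFraction = 0,
                         medianDepth = 10000, seed = 11)
  ed <- simulateEditomeCounts(truth, seed = 11)
  k <- Matrix::rowSums(SummarizedExperiment::assay(ed, "edited"))
  n <- Matrix::rowSums(SummarizedExperiment::assay(ed, "total"))
  expect_true(all(n > 10000))
  se <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(k / n - 0.25) < 3 * se))
})

test_that("read counts dominate UMI counts, with equality iff no duplication", {
  truth <- simulateTruth(nGenes = 15, nCells = 100, states = c(S = 1),
                         siteFreq = 0.4, controlFraction = 0,
                         dupShape = 4, dupRate = 2, seed = 13)
  ed <- simulateEditomeCounts(truth, seed = 13)
  k <- as.matrix(SummarizedExperiment::assay(ed, "edited"))
  r <- as.matrix(SummarizedExperiment::assay(ed, "editedReads"))
  expect_true(all(r >= k))
  expect_gt(sum(r), sum(k))

  truth0 <- simulateTruth(nGenes = 15, nCells = 100, states = c(S = 1),
                          siteFreq = 0.4, controlFraction = 0,
                          dupShape = 0, seed = 13)
  ed0 <- simulateEditomeCounts(truth0, seed = 13)
  expect_identical(
    as.matrix(SummarizedExperiment::assay(ed0, "editedReads")),
    as.matrix(SummarizedExperiment::assay(ed0, "edited")))
})

test_that("state-specific expression weights shift the totals", {
  sw <- matrix(1, 10, 2, dimnames = list(NULL, c("A", "B")))
  sw[1, "A"] <- 4
  truth <- simulateTruth(nGenes = 10, nCells = 400,
                         states = c(A = 0.5, B = 0.5), siteFreq = 0.2,
                         stateWeights = sw, controlFraction = 0, seed = 17)
  ed <- simulateEditomeCounts(truth, seed = 17)
  t_ <- as.matrix(SummarizedExperiment::assay(ed, "total"))
  mA <- mean(t_[1, ed$state == "A"]); mB <- mean(t_[1, ed$state == "B"])
  expect_gt(mA / mB, 2)
})
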