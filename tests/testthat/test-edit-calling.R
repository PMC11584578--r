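makeCalSites <- function() {
  # sites across substitution classes and strands, plus one inside
  # overlapping genes on both strands and one matching the variant mask
  genes <- GRanges("chr1", IRanges(c(1, 201, 401), c(100, 300, 500)),
                   strand = c("+", "-", "-"),
                   gene_id = c("gp", "gm", "gm2"))
  both <- GRanges("chr1", IRanges(450, 520), strand = "+",
                  gene_id = "gp2")
  genes <- c(genes, both)
  se <- makeSiteExperiment(
    edited = cbind(x = c(5, 5, 5, 5, 5)),
    coverage = cbind(x = c(20, 20, 20, 20, 20)),
    pos = c(10, 250, 50, 460, 90),
    ref = c("A", "T", "C", "T", "A"),
    alt = c("G", "C", "T", "C", "G"))
  list(se = se, genes = genes)
}

test_that("strand calibration keeps A-to-G in transcript space only", {
  fx <- makeCalSites()
  cal <- calibrateStrand(fx$se, fx$genes)
  # +A>G kept; -T>C kept (reported A>G in transcript space); +C>T dropped;
  # both-strand site dropped as ambiguous
  expect_setequal(rownames(cal), c("chr1:10:A:G", "chr1:250:T:C",
                                   "chr1:90:A:G"))
  expect_true(all(rowData(cal)$refTx == "A" & rowData(cal)$altTx == "G"))
  expect_identical(
    rowData(cal)$tx_strand[match("chr1:250:T:C", rownames(cal))], "-")

  mask <- GRanges("chr1", IRanges(10, 10))
  cal2 <- calibrateStrand(fx$se, fx$genes, variantMask = mask)
  expect_false("chr1:10:A:G" %in% rownames(cal2))
})

test_that("beta-binomial parameters are recovered from control draws", {
  set.seed(31)
  alpha <- 2; beta <- 198
  n <- rep(50, 5000)
  k <- rbinom(5000, n, rbeta(5000, alpha, beta))
  bg <- fitBackground(data.frame(k = k, n = n))
  muTrue <- alpha / (alpha + beta)             # 0.01
  rhoTrue <- 1 / (alpha + beta + 1)            # ~0.005
  expect_equal(bg@method, "mom+ml")
  expect_lt(abs(bg@mu - muTrue) / muTrue, 0.2)
  expect_lt(abs(bg@rho - rhoTrue) / rhoTrue, 0.5)
})

test_that("binomial control triggers the zero-dispersion fallback", {
  set.seed(32)
  n <- rep(80, 2000)
  k <- rbinom(2000, n, 0.01)
  bg <- fitBackground(data.frame(k = k, n = n))
  expect_equal(bg@method, "binomial")
  expect_equal(bg@rho, 0)
  expect_equal(bg@mu, sum(k) / sum(n))
})

test_that("degenerate controls hit the rate floor or fail loudly", {
  expect_warning(bg <- fitBackground(data.frame(k = 0, n = 100)),
                 "rate floor")
  expect_equal(bg@mu, 1e-4)
  expect_error(fitBackground(data.frame(k = numeric(0), n = numeric(0))),
               "empty")
})

test_that("tail probabilities match an independent integration oracle", {
  ab <- tribetools:::muRhoToAlphaBeta(0.02, 0.05)
  for (n in c(15, 40, 120)) {
    for (k in c(1, 2, 5, round(n / 3))) {
      expect_equal(pbetabinomUpper(k, n, ab["alpha"], ab["beta"]),
                   bbTailIntegrate(k, n, ab["alpha"], ab["beta"]),
                   tolerance = 1e-7,
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
  expect_equal(pbetabinomUpper(0, 30, 2, 198), 1)
})

test_that("site test separates saturated sites from null-centered ones", {
  bg <- new("BackgroundModel", mu = 0.01, rho = 0.02,
            alpha = unname(tribetools:::muRhoToAlphaBeta(0.01, 0.02)[1]),
            beta = unname(tribetools:::muRhoToAlphaBeta(0.01, 0.02)[2]),
            method = "mom+ml", rateFloor = 1e-4, pooling = "global")
  se <- makeSiteExperiment(edited = cbind(x = c(30, 0)),
                           coverage = cbind(x = c(30, 50)))
  tested <- testSites(se, bg)
  expect_lt(rowData(tested)$p[1], 1e-20)
  # frequency equal to the background mean: p around 0.5 or larger
  # (binomial model: the tail at the mean carries at least half the mass)
  bgBin <- new("BackgroundModel", mu = 0.01, rho = 0, alpha = Inf,
               beta = Inf, method = "binomial", rateFloor = 1e-4,
               pooling = "global")
  se2 <- makeSiteExperiment(edited = cbind(x = 10),
                            coverage = cbind(x = 1000))
  expect_gte(rowData(testSites(se2, bgBin))$p[1], 0.5)
})

test_that("per-site pooling uses site means where covered, global elsewhere", {
  set.seed(33)
  kc <- c(rbinom(50, 200, 0.02), 0)
  nc <- c(rep(200, 50), 5)     # last site under-covered in the control
  ctl <- data.frame(k = kc, n = nc,
                    row.names = paste0("chr1:", 1:51, ":A:G"))
  bg <- fitBackground(ctl, pooling = "per_site")
  expect_equal(bg@pooling, "per_site")
  expect_true(all(bg@perSite$n > 10))
  expect_false("chr1:51:A:G" %in% bg@perSite$site)
  se <- makeSiteExperiment(edited = cbind(x = c(10, 10)),
                           coverage = cbind(x = c(100, 100)),
                           pos = c(1, 51))
  tested <- testSites(se, bg)
  expect_true(all(rowData(tested)$p >= 0 & rowData(tested)$p <= 1))
})

test_that("null sites simulated from the fitted model stay below the FDR gate", {
  sim <- simulateSiteCounts(nTrue = 0, nNull = 1000, trueFreq = numeric(0),
                            coverageRange = c(50, 50), backgroundMu = 0.01,
                            backgroundRho = 0.05, seed = 41)
  bg <- fitBackground(sim$control)
  tested <- testSites(sim$experimental, bg)
  expect_lte(mean(rowData(tested)$fdr < 0.01), 0.02)
})

test_that("the four-part filter applies the documented gates", {
  # two replicates; thresholds quoted from the calling convention:
  # FDR < 0.01, 0.05 <= f <= 0.95, k > 2, n > 10 in each replicate
  se <- makeSiteExperiment(
    edited = cbind(r1 = c(3, 48, 2, 6), r2 = c(3, 48, 2, 6)),
    coverage = cbind(r1 = c(11, 50, 20, 40), r2 = c(11, 50, 20, 40)),
    counting = "reads")
  rowData(se)$k <- rowSums(assay(se, "edited"))
  rowData(se)$n <- rowSums(assay(se, "coverage"))
  rowData(se)$f <- rowData(se)$k / rowData(se)$n
  rowData(se)$p <- c(1e-5, 1e-9, 1e-9, 1e-9)
  rowData(se)$fdr <- c(0.005, 1e-8, 1e-8, 1e-8)
  out <- applySiteFilters(se, perReplicate = TRUE, keepAll = TRUE)
  sig <- rowData(out)$significant
  expect_true(sig[1])          # f=0.27, k=3, n=11: kept
  expect_false(sig[2])         # f=0.96: frequency gate
  expect_false(sig[3])         # k=2: strict inequality
  expect_true(sig[4])
  expect_false(rowData(out)$passFreq[2])
  expect_false(rowData(out)$passEdited[3])
})

test_that("filter survivors match a brute-force implementation", {
  set.seed(42)
  m <- 300
  n <- sample(5:60, m, replace = TRUE)
  k <- rbinom(m, n, runif(m, 0, 1))
  fdr <- runif(m, 0, 0.05)
  se <- makeSiteExperiment(edited = cbind(x = k), coverage = cbind(x = n))
  rowData(se)$k <- k; rowData(se)$n <- n; rowData(se)$f <- k / n
  rowData(se)$p <- fdr; rowData(se)$fdr <- fdr
  got <- rowData(applySiteFilters(se, keepAll = TRUE))$significant
  expect_identical(got, bruteFilter(fdr, k, n))
})

test_that("filtering is monotone under threshold tightening", {
  set.seed(43)
  m <- 200
  n <- sample(5:80, m, replace = TRUE)
  k <- rbinom(m, n, runif(m))
  se <- makeSiteExperiment(edited = cbind(x = k), coverage = cbind(x = n))
  rowData(se)$k <- k; rowData(se)$n <- n; rowData(se)$f <- k / n
  rowData(se)$fdr <- runif(m, 0, 0.05)
  rowData(se)$p <- rowData(se)$fdr
  base <- rownames(applySiteFilters(se))
  tighter <- list(
    applySiteFilters(se, fdrMax = 0.005),
    applySiteFilters(se, freqRange = c(0.1, 0.9)),
    applySiteFilters(se, minEdited = 5),
    applySiteFilters(se, minCoverage = 30))
  for (t in tighter) expect_true(all(rownames(t) %in% base))
})

test_that("BH correction agrees with the brute-force definition", {
  set.seed(44)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bruteBH(p))
  }
})

test_that("significant calls on simulated alignments recover the truth", {
  truth <- simulateTruth(nGenes = 6, nCells = 40, sitesPerGene = 2,
                         siteFreq = 0.4, medianDepth = 300,
                         sdLogDepth = 0.3, nSnps = 3,
                         controlFraction = 0.3, seed = 42)
  files <- simulateAlignments(truth, tempfile("e2e"), seed = 1)
  ann <- readGeneModels(files$gtf)
  se <- pileupCounts(c(experimental = files$sam.experimental,
                       control = files$sam.control),
                     files$genome, ann, mode = "umis")
  cal <- calibrateStrand(se, ann, variantMask = files$vcf)
  ctrl <- cal[, colData(cal)$sample == "control"]
  expt <- cal[, colData(cal)$sample == "experimental"]
  sig <- applySiteFilters(testSites(expt, fitBackground(ctrl)))
  planted <- truthSites(truth)
  keys <- ifelse(planted$strand == "+",
                 paste0(planted$chrom, ":", planted$pos, ":A:G"),
                 paste0(planted$chrom, ":", planted$pos, ":T:C"))
  tp <- sum(rownames(sig) %in% keys)
  expect_gte(tp / nrow(sig), 0.9)            # precision
  expect_gte(tp / length(keys), 0.9)         # recall
  # transcript-space report: every retained site is A-to-G
  expect_true(all(rowData(sig)$refTx == "A" & rowData(sig)$altTx == "G"))
})
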