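test_that("a planted two-fold binding difference is recovered", {
  set.seed(71)
  n <- 50
  b <- rbind(hit = c(log1p(rpois(n, 8)), log1p(rpois(n, 4))),
             null = log1p(rpois(2 * n, 5)))
  colnames(b) <- paste0("c", seq_len(2 * n))
  groups <- rep(c("A", "B"), each = n)
  dbts <- findDbts(b, groups)
  hitA <- dbts[dbts$gene == "hit" & dbts$group == "A", ]
  expect_true(hitA$significant)
  expect_lt(hitA$p, 0.01)
  expect_gt(hitA$log2FC, log2(1.2))
})

test_that("a 1.1-fold difference is excluded by the fold-change gate", {
  set.seed(72)
  n <- 4000   # plenty of power so p is tiny, only the FC gate blocks
  b <- rbind(g = c(log1p(rpois(n, 110)), log1p(rpois(n, 100))))
  colnames(b) <- paste0("c", seq_len(2 * n))
  dbts <- findDbts(b, rep(c("A", "B"), each = n))
  a <- dbts[dbts$group == "A", ]
  expect_lt(a$p, 0.01)
  expect_lt(abs(a$log2FC), log2(1.2))
  expect_false(a$significant)
})

test_that("identical groups produce no significant records", {
  set.seed(73)
  b <- matrix(log1p(rpois(100 * 120, 10)), 100, 120,
              dimnames = list(paste0("g", 1:100), paste0("c", 1:120)))
  dbts <- findDbts(b, rep(c("A", "B"), each = 60))
  expect_equal(sum(dbts$significant), 0)
  expect_gt(mean(dbts$p), 0.3)   # roughly uniform p-values
})

test_that("two-group fold-changes are reciprocal on the ratio scale", {
  set.seed(74)
  b <- matrix(log1p(rpois(20 * 40, 6)), 20, 40,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:40)))
  dbts <- findDbts(b, rep(c("A", "B"), each = 20))
  fa <- dbts$log2FC[dbts$group == "A"][order(dbts$gene[dbts$group == "A"])]
  fb <- dbts$log2FC[dbts$group == "B"][order(dbts$gene[dbts$group == "B"])]
  expect_equal(fa, -fb, tolerance = 1e-9)
})

test_that("small groups are skipped with a warning", {
  b <- matrix(log1p(rpois(5 * 12, 4)), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:12)))
  expect_warning(dbts <- findDbts(b, c(rep("A", 10), rep("B", 2))),
                 "fewer than")
  expect_false("B" %in% dbts$group)
})

test_that("rank-sum p-values match exact enumeration for small groups", {
  set.seed(75)
  for (i in 1:8) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)   # continuous: no ties
    b <- matrix(c(x, y), 1, dimnames = list("g", NULL))
    dbts <- findDbts(b, c(rep("A", nx), rep("B", ny)), minCells = 3)
    expect_equal(dbts$p[dbts$group == "A"], exactWilcoxP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("label permutation keeps the false-positive rate at the nominal level", {
  set.seed(76)
  # three groups of 50 cells at typical edited-UMI depth
  b <- matrix(log1p(rpois(400 * 150, 8)), 400, 150,
              dimnames = list(paste0("g", 1:400), paste0("c", 1:150)))
  groups <- rep(c("A", "B", "C"), each = 50)
  rates <- replicate(5, {
    d <- findDbts(b, sample(groups))
    length(unique(d$gene[d$significant])) / 400
  })
  expect_lte(mean(rates), 0.02)
})

test_that("dependence classification contrasts binding with expression", {
  set.seed(77)
  n <- 60
  groups <- rep(c("A", "B"), each = n)
  b <- rbind(dep = c(log1p(rpois(n, 8)), log1p(rpois(n, 4))),
             indep = c(log1p(rpois(n, 8)), log1p(rpois(n, 4))))
  colnames(b) <- paste0("c", seq_len(2 * n))
  expr <- rbind(dep = c(log1p(rpois(n, 20)), log1p(rpois(n, 10))),
                indep = log1p(rpois(2 * n, 15)))
  colnames(expr) <- colnames(b)
  dbts <- classifyDependence(findDbts(b, groups), expr, groups)
  a <- dbts[dbts$group == "A" & dbts$significant, ]
  expect_identical(a$dependence[a$gene == "dep"], "expression_dependent")
  expect_identical(a$dependence[a$gene == "indep"],
                   "expression_independent")
  # classes partition the significant set
  expect_false(anyNA(a$dependence))
  # a gene absent from the expression matrix stays flagged NA
  dbts2 <- classifyDependence(findDbts(b, groups),
                              expr["dep", , drop = FALSE], groups)
  a2 <- dbts2[dbts2$group == "A" & dbts2$significant, ]
  expect_true(is.na(a2$dependence[a2$gene == "indep"]))
})

test_that("no significant DBTs yields an empty classification", {
  set.seed(78)
  b <- matrix(log1p(rpois(10 * 40, 3)), 10, 40,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:40)))
  expr <- b
  dbts <- classifyDependence(findDbts(b, rep(c("A", "B"), each = 20)),
                             expr, rep(c("A", "B"), each = 20))
  expect_true(all(is.na(dbts$dependence)))
})

test_that("relative binding intensity divides relative editing by expression", {
  edit <- rbind(g1 = c(2, 1, 0) * 2, g2 = c(1, 1, 1))
  expr <- rbind(g1 = c(1, 1, 1), g2 = c(2, 1, 3))
  colnames(edit) <- colnames(expr) <- c("s1", "s2", "s3")
  rbi <- relativeBindingIntensity(edit, expr, epsilon = 0)
  # hand computation: relEdit g1 = (4,2,0)/2; relExpr g1 = 1 everywhere
  expect_equal(unname(rbi["g1", ]), c(2, 1, 0))
  # relEdit g2 = 1; relExpr g2 = (2,1,3)/2
  expect_equal(unname(rbi["g2", ]), c(1, 2, 2 / 3))
  # editing and expression equal across groups -> 1 everywhere
  same <- rbind(g = c(3, 3, 3))
  expect_equal(unname(relativeBindingIntensity(same, same,
                                               epsilon = 0)["g", ]),
               c(1, 1, 1))
  # all-zero expression row is flagged undefined
  z <- relativeBindingIntensity(rbind(g = c(1, 2, 3)),
                                rbind(g = c(0, 0, 0)))
  expect_true(all(is.na(z)))
})

test_that("fold-change equals the expm1-mean ratio on a worked example", {
  # group A cells hold binding log1p(3) and log1p(5); group B log1p(1)
  # and log1p(3): FC = (mean(3,5)+1)/(mean(1,3)+1) = 5/3
  b <- matrix(log1p(c(3, 5, 1, 3)), 1, 4,
              dimnames = list("g", paste0("c", 1:4)))
  dbts <- findDbts(b, c("A", "A", "B", "B"), minCells = 2)
  expect_equal(dbts$log2FC[dbts$group == "A"], log2(5 / 3),
               tolerance = 1e-12)
})

test_that("pairwise comparisons cover every ordered group pair", {
  set.seed(80)
  b <- matrix(log1p(rpois(10 * 45, 6)), 10, 45,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:45)))
  b[1, 1:15] <- log1p(rpois(15, 24))
  groups <- rep(c("A", "B", "C"), each = 15)
  dbts <- findDbts(b, groups, comparison = "pairwise")
  expect_setequal(unique(dbts$group),
                  c("A_vs_B", "A_vs_C", "B_vs_A", "B_vs_C",
                    "C_vs_A", "C_vs_B"))
  ab <- dbts[dbts$gene == "g1" & dbts$group == "A_vs_B", ]
  expect_true(ab$significant && ab$direction == "up")
  # pairwise log2FCs are antisymmetric
  ba <- dbts[dbts$gene == "g1" & dbts$group == "B_vs_A", ]
  expect_equal(ab$log2FC, -ba$log2FC)
})
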