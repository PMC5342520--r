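test_that("Fisher-Z positive-correlation p-values match the closed form", {
  expect_equal(fisherZPositiveP(0, 30), 0.5)
  # frozen from a 30-digit normal-CDF oracle: z = atanh(0.5) * 5
  expect_equal(fisherZPositiveP(0.5, 28), 0.00301146224294170,
               tolerance = 1e-12)
  expect_gt(fisherZPositiveP(-0.9, 100), 0.999)
  expect_error(fisherZPositiveP(0.5, 3), "more than 3")
  expect_warning(p1 <- fisherZPositiveP(1, 30), "clamped")
  expect_lt(p1, 1e-15)
})

test_that("Fisher-Z p is strictly decreasing in r and in n (for r > 0)", {
  rGrid <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(fisherZPositiveP(rGrid, 20)) < 0))
  nGrid <- seq(5, 100, by = 5)
  expect_true(all(diff(fisherZPositiveP(0.4, nGrid)) < 0))
})

test_that("Fisher-Z agrees with a permutation test within Monte-Carlo error", {
  set.seed(301)
  nPerm <- 10000
  for (case in list(list(n = 15, r = 0.35), list(n = 30, r = 0.3),
                    list(n = 60, r = 0.2))) {
    n <- case$n
    # draw one dataset with roughly the requested correlation
    repeat {
      f <- rnorm(n)
      x <- sqrt(case$r) * f + sqrt(1 - case$r) * rnorm(n)
      y <- sqrt(case$r) * f + sqrt(1 - case$r) * rnorm(n)
      r <- cor(x, y)
      if (r > 0.05 && abs(r) <= 0.8) break
    }
    perms <- replicate(nPerm, cor(x, sample(y)))
    pPerm <- (1 + sum(perms >= r)) / (nPerm + 1)
    pZ <- fisherZPositiveP(r, n)
    se <- sqrt(pPerm * (1 - pPerm) / nPerm)
    expect_lt(abs(pZ - pPerm), 3 * se + 1e-4,
              label = sprintf("n=%d r=%.2f", n, r))
  }
})

test_that("co-expression filter keeps positive significant pairs only", {
  set.seed(302)
  n <- 28
  base <- rnorm(n)
  X <- rbind(
    g1 = base + rnorm(n, sd = 1.2),     # positively correlated with L1
    g2 = -base + rnorm(n, sd = 0.2),    # strongly negative with L1
    g3 = rnorm(n),                      # independent
    gflat = rep(2, n),                  # zero variance
    L1 = base + rnorm(n, sd = 1.2),
    L2 = rnorm(n))
  se <- makeExpr(X, c(rep("mRNA", 4), "lncRNA", "lncRNA"))
  pairs <- data.frame(
    lncrna = c("L1", "L1", "L2", "L1", "L1"),
    mrna = c("g1", "g2", "g3", "gflat", "gmissing"),
    shared = 2L, K = 4L, M = 4L, N = 10L, hypergP = 0.01, jaccard = 0.5,
    passedHyperg = TRUE, passedJaccard = TRUE, stringsAsFactors = FALSE)
  net <- new("CeRNANetwork", candidates = pairs, pairs = pairs,
             jaccardCutoff = 0.5)
  expect_warning(
    expect_message(edges <- filterByCoexpression(net, se, alpha = 0.05),
                   "absent"),
    "zero-variance")
  expect_equal(attr(edges, "nMissing"), 1L)
  expect_equal(attr(edges, "nZeroVar"), 1L)
  expect_true(all(edges$r > 0))
  expect_true(all(edges$p < 0.05))
  expect_true("g1" %in% edges$mrna)       # planted positive pair kept
  expect_false("g2" %in% edges$mrna)      # negative correlation never kept

  # identical profiles give r clamped to 1 and are retained
  X2 <- rbind(gA = seq_len(10), LA = seq_len(10))
  se2 <- makeExpr(X2 + 0, c("mRNA", "lncRNA"))
  pairs2 <- pairs[1, ]
  pairs2$lncrna <- "LA"; pairs2$mrna <- "gA"
  net2 <- new("CeRNANetwork", candidates = pairs2, pairs = pairs2,
              jaccardCutoff = 0.5)
  edges2 <- suppressWarnings(filterByCoexpression(net2, se2))
  expect_equal(nrow(edges2), 1L)
  expect_equal(edges2$r, 1)
})

test_that("lncRNA embedding adds nodes and regulation edges correctly", {
  pg <- pathwayGraph("path:p", edges = cbind("A", "B"))
  re <- data.frame(lncrna = c("L1", "L1", "L2"),
                   mrna = c("A", "B", "X"),
                   r = 0.5, nSamples = 30L, p = 0.01,
                   stringsAsFactors = FALSE)
  lrsp <- buildLRSP(pg, re)
  expect_setequal(pathwayNodes(lrsp), c("A", "B", "L1"))  # L2 -> X dropped
  expect_equal(lncrnaNodes(lrsp), "L1")                   # single node, 2 edges
  expect_equal(nrow(regulationEdges(lrsp)), 2L)
  # base gene-gene edges untouched
  expect_equal(pathwayEdges(lrsp@base), pathwayEdges(pg))
  # no embedding: pathway still returned
  lrsp0 <- buildLRSP(pg, re[re$mrna == "X", ])
  expect_length(lncrnaNodes(lrsp0), 0L)
  expect_setequal(pathwayNodes(lrsp0), c("A", "B"))
})

test_that("t-test stage flags strong shifts and controls false discoveries", {
  # one feature with a 5-sigma group shift among noise: always called
  set.seed(303)
  hits <- 0L
  for (i in 1:200) {
    X <- rbind(gshift = c(rnorm(10, 5), rnorm(10, 0)),
               gnull = rnorm(20),
               L1 = rnorm(20))
    se <- makeExpr(X, c("mRNA", "mRNA", "lncRNA"), nCase = 10)
    sel <- computeInterestingGenes(se, fdrThreshold = 0.1)
    if ("gshift" %in% sel) hits <- hits + 1L
  }
  expect_gte(hits, 198L)  # detection probability ~ 1 at this effect size

  # identical values in both groups can never be significant
  Xflat <- rbind(gflat = rep(3, 12), gnoise = rnorm(12), L1 = rnorm(12))
  seFlat <- makeExpr(Xflat, c("mRNA", "mRNA", "lncRNA"), nCase = 6)
  expect_false("gflat" %in% computeInterestingGenes(seFlat))
  tab <- attr(computeInterestingGenes(seFlat), "table")
  expect_equal(tab$t[tab$gene == "gflat"], 0)

  # BH under the global null: average false-positive count stays small
  set.seed(304)
  fp <- vapply(1:200, function(i) {
    X <- matrix(rnorm(100 * 12), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
    se <- makeExpr(X, rep("mRNA", 100), nCase = 6)
    length(computeInterestingGenes(se, fdrThreshold = 0.1))
  }, numeric(1))
  # under the complete null BH makes any rejection with prob <= 0.1
  expect_lte(mean(fp > 0), 0.1 + 3 * sqrt(0.1 * 0.9 / 200))

  seFlat2 <- makeExpr(rbind(g = rnorm(4)), "mRNA", nCase = 1)
  expect_error(computeInterestingGenes(seFlat2), "at least 2")
})
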