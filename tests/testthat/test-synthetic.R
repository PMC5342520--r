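test_that("catalog simulation plants the requested overlap structure", {
  ct <- simulateCatalog(nLnc = 6, nMrna = 10, nMirna = 30,
                        baselineTargets = 5, plantedPairs = 2,
                        plantedOverlap = 10, seed = 501)
  cat1 <- ct$catalog
  expect_s4_class(cat1, "InteractionCatalog")
  expect_equal(nrow(ct$truth$plantedPairs), 2L)
  for (i in 1:2) {
    l <- ct$truth$plantedPairs$lncrna[i]
    m <- ct$truth$plantedPairs$mrna[i]
    ov <- length(intersect(cat1@lncTargets[[l]], cat1@mrnaTargets[[m]]))
    expect_gte(ov, 10L)
  }
  # full-universe overlap with no baseline: planted Jaccard is exactly 1
  ct2 <- simulateCatalog(nLnc = 2, nMrna = 2, nMirna = 8,
                         baselineTargets = 0, plantedPairs = 1,
                         plantedOverlap = 8, seed = 502)
  l <- ct2$truth$plantedPairs$lncrna[1]
  m <- ct2$truth$plantedPairs$mrna[1]
  expect_setequal(ct2$catalog@lncTargets[[l]], ct2$catalog@mrnaTargets[[m]])
  expect_error(simulateCatalog(nMirna = 10, baselineTargets = 8,
                               plantedOverlap = 5), "infeasible")
  # determinism
  ctA <- simulateCatalog(seed = 503)
  ctB <- simulateCatalog(seed = 503)
  expect_identical(ctA, ctB)
})

test_that("simulated pathways are connected with the expected edge counts", {
  ps <- simulatePathways(nPathways = 5, nodesPerPathway = 12,
                         edgeProb = 0, seed = 504)
  for (p in ps) {
    expect_true(igraph::is_connected(p@graph))
    expect_equal(igraph::gsize(p@graph), 11L)  # pure tree
  }
  # disjoint gene spaces at shared fraction 0
  nodeSets <- lapply(ps, pathwayNodes)
  expect_equal(anyDuplicated(unlist(nodeSets)), 0L)
  expect_length(simulatePathways(nPathways = 0, seed = 1), 0L)
  psDense <- simulatePathways(nPathways = 2, nodesPerPathway = 10,
                              edgeProb = 0.5, seed = 505)
  expect_true(all(vapply(psDense, function(p)
    igraph::gsize(p@graph) > 9, logical(1))))
})

test_that("planted pairs reach the target correlation", {
  # sampling distribution of r at rho = 0.9, 100 samples: the empirical
  # correlation of the planted pair stays in [0.8, 0.96] almost surely
  pw <- simulatePathways(nPathways = 1, nodesPerPathway = 4, edgeProb = 0.3,
                         seed = 506)
  inside <- 0L
  set.seed(507)
  for (i in 1:200) {
    ct <- simulateCatalog(nLnc = 2, nMrna = 4, nMirna = 20,
                          baselineTargets = 4, plantedPairs = 1,
                          plantedOverlap = 6, seed = NULL,
                          mrnaIds = sort(pathwayNodes(pw[[1]])))
    ex <- simulateExpression(ct, pw, nCase = 50, nControl = 50,
                             rhoPlanted = 0.9, deEffect = 0, seed = NULL)
    pp <- ex$truth$plantedPairs
    X <- SummarizedExperiment::assay(ex$expr, "expr")
    r <- cor(X[pp$lncrna[1], ], X[pp$mrna[1], ])
    if (r >= 0.8 && r <= 0.96) inside <- inside + 1L
  }
  expect_gte(inside, 190L)
})

test_that("without a planted shift the subpathway genes are not enriched", {
  # de_effect = 0: planted-region genes should be called DE no more often
  # than the BH false-positive expectation
  set.seed(508)
  calls <- 0L
  trials <- 0L
  for (i in 1:100) {
    sc <- simulateScenario(nLnc = 10, nMrna = 40, nMirna = 40,
                           nPathways = 2, nodesPerPathway = 20,
                           edgeProb = 0.1, baselineTargets = 6,
                           plantedPairs = 2, plantedOverlap = 10,
                           nCase = 10, nControl = 10, deEffect = 0,
                           subpathwaySize = 6, seed = 5080 + i)
    sel <- computeInterestingGenes(sc$expr, fdrThreshold = 0.1)
    region <- sc$truth$plantedSubpathway$nodes
    calls <- calls + length(intersect(sel, region))
    trials <- trials + length(region)
  }
  # under the null each gene is rejected with probability well below the
  # nominal FDR level; allow Monte-Carlo slack around 0.1
  expect_lte(calls / trials, 0.1 + 3 * sqrt(0.1 * 0.9 / trials))
})

test_that("expression simulation is reproducible under a fixed seed", {
  pw <- simulatePathways(nPathways = 2, nodesPerPathway = 6, edgeProb = 0.2,
                         seed = 509)
  ct <- simulateCatalog(nLnc = 3, nMrna = 12, nMirna = 20,
                        baselineTargets = 4, plantedPairs = 1,
                        plantedOverlap = 6, seed = 510,
                        mrnaIds = sort(unlist(lapply(pw, pathwayNodes))))
  e1 <- simulateExpression(ct, pw, nCase = 5, nControl = 5, seed = 511)
  e2 <- simulateExpression(ct, pw, nCase = 5, nControl = 5, seed = 511)
  expect_identical(SummarizedExperiment::assay(e1$expr),
                   SummarizedExperiment::assay(e2$expr))
  # generated objects pass the pipeline's own validator
  expect_silent(validateExpression(e1$expr))
})

test_that("robustness perturbation deletes the stated fraction, untouched input", {
  sc <- smallScenario(512)
  expr <- sc$expr
  p0 <- perturbForRobustness(expr, 0, "deleteFeatures", seed = 1)
  expect_identical(SummarizedExperiment::assay(p0),
                   SummarizedExperiment::assay(expr))
  p5 <- perturbForRobustness(expr, 0.5, "deleteFeatures", seed = 1)
  expect_equal(nrow(p5), nrow(expr) - floor(0.5 * nrow(expr)))
  expect_equal(nrow(expr), 80L)  # original untouched
  pA <- perturbForRobustness(expr, 0.3, "deleteFeatures", seed = 2)
  pB <- perturbForRobustness(expr, 0.3, "deleteFeatures", seed = 3)
  expect_false(identical(rownames(pA), rownames(pB)))

  # edge deletion across LRSPs preserves class invariants
  net <- buildCandidateNetwork(sc$catalog)
  edges <- filterByCoexpression(net, expr)
  lrsps <- lapply(sc$pathways, buildLRSP, retainedEdges = edges)
  tot <- sum(vapply(lrsps, function(l) igraph::gsize(l@graph), numeric(1)))
  pe <- perturbForRobustness(lrsps, 0.25, "deleteEdges", seed = 4)
  totP <- sum(vapply(pe, function(l) igraph::gsize(l@graph), numeric(1)))
  expect_equal(totP, tot - floor(0.25 * tot))
  for (l in pe) expect_true(validObject(l, test = TRUE))
})
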