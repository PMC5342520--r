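test_that("signature nodes are embedded lncRNAs plus mapped interesting genes", {
  lrsp <- makeLRSP("path:p", cbind("A", "B"), cbind("L1", "A"))
  expect_setequal(signatureNodesOf(lrsp, c("A", "Z")), c("A", "L1"))
  lrsp0 <- makeLRSP("path:p", cbind("A", "B"))
  expect_length(signatureNodesOf(lrsp0, "Z"), 0L)
  expect_length(signatureNodesOf(lrsp0, character()), 0L)
})

test_that("lenient-distance merging recovers the five-node chain", {
  # chain g1 - g2 - L - g4 - g5 with the lncRNA in the middle: merging at
  # n = 1 links (g1, L) and (L, g5), and the shortest-path intermediates
  # g2, g4 are pulled into the region
  lrsp <- makeLRSP("path:c", rbind(c("g1", "g2"), c("g4", "g5")),
                   rbind(c("L", "g2"), c("L", "g4")))
  sps <- locateSubpathways(lrsp, interestingGenes = c("g1", "g5"),
                           n = 1, s = 5)
  expect_length(sps, 1L)
  expect_setequal(subpathwayNodes(sps[[1]]), c("g1", "g2", "L", "g4", "g5"))
  expect_setequal(signatureNodes(sps[[1]]), c("g1", "L", "g5"))
  expect_equal(subpathwayLncrnas(sps[[1]]), "L")
  expect_equal(subpathwayId(sps[[1]]), "path:c_1")

  # signature spread too thin: three intermediates exceed n = 1, singleton
  # components fall below s
  chain <- rbind(c("g1", "g2"), c("g2", "g3"), c("g3", "g4"), c("g4", "g5"))
  lrspGene <- makeLRSP("path:c", chain, cbind("L", "g3"))
  expect_length(locateSubpathways(lrspGene, c("g1", "g5"), n = 1, s = 5), 0L)

  # disconnected signature nodes are never merged
  lrspDis <- makeLRSP("path:d", rbind(c("a1", "a2"), c("b1", "b2")),
                      cbind("L", "a1"))
  sps2 <- locateSubpathways(lrspDis, c("a2", "b1", "b2"), n = 5, s = 2)
  expect_true(all(vapply(sps2, function(sp)
    all(subpathwayNodes(sp) %in% c("a1", "a2", "L")), logical(1))))
})

test_that("regions without any lncRNA are discarded", {
  chain <- rbind(c("g1", "g2"), c("g2", "g3"))
  lrsp <- makeLRSP("path:g", chain, cbind("L", "g9"), genes = "g9")
  # g1..g3 merge into a 3-node pure-gene region; it must not be reported
  sps <- locateSubpathways(lrsp, c("g1", "g2", "g3"), n = 1, s = 2)
  expect_length(sps, 0L)
})

test_that("merging partitions the signature set", {
  set.seed(401)
  for (i in 1:20) {
    lrsp <- randomLRSPCase(nGenes = 15, extraEdgeProb = 0.08, nLnc = 3)
    genes <- igraph::V(lrsp@base@graph)$name
    sig <- signatureNodesOf(lrsp, sample(genes, 5))
    sps <- locateSubpathways(lrsp, sig, n = 1, s = 1)
    sigSets <- lapply(sps, signatureNodes)
    # disjoint ...
    expect_equal(anyDuplicated(unlist(sigSets)), 0L)
    # ... and, with s = 1 and no-lncRNA regions removed, the reported
    # signature nodes are a subset of sig that covers every lncRNA
    expect_true(all(unlist(sigSets) %in% sig))
    expect_true(all(lncrnaNodes(lrsp) %in% unlist(sigSets)))
  }
})

test_that("locator agrees with the BFS + union-find + path-enumeration oracle", {
  set.seed(402)
  nCases <- 100
  for (i in seq_len(nCases)) {
    nGenes <- sample(8:26, 1)
    lrsp <- randomLRSPCase(nGenes, extraEdgeProb = 0.06,
                           nLnc = sample(1:4, 1))
    genes <- igraph::V(lrsp@base@graph)$name
    interesting <- sample(genes, sample.int(min(6, nGenes), 1))
    sig <- signatureNodesOf(lrsp, interesting)
    nodes <- pathwayNodes(lrsp)
    el <- as.matrix(pathwayEdges(lrsp))
    isLnc <- setNames(nodes %in% lncrnaNodes(lrsp), nodes)
    s <- sample(2:6, 1)
    for (n in 0:2) {
      sps <- locateSubpathways(lrsp, interesting, n = n, s = s)
      got <- regionKey(lapply(sps, function(sp)
        list(nodes = sort(subpathwayNodes(sp)),
             sig = sort(signatureNodes(sp)))))
      want <- regionKey(locatorOracle(nodes, el, isLnc, sig, n, s))
      expect_equal(got, want,
                   label = sprintf("case %d n=%d s=%d", i, n, s))
    }
  }
})

test_that("output is invariant under node relabeling and raising n grows regions", {
  set.seed(403)
  lrsp <- randomLRSPCase(nGenes = 18, extraEdgeProb = 0.08, nLnc = 3)
  genes <- igraph::V(lrsp@base@graph)$name
  interesting <- sample(genes, 5)

  # relabel nodes with a prefix, locate, then unrelabel: same regions
  el <- pathwayEdges(lrsp@base)
  re <- regulationEdges(lrsp)
  tag <- function(x) paste0("zz", x)
  lrsp2 <- makeLRSP("path:test",
                    cbind(tag(el$from), tag(el$to)),
                    cbind(tag(re$lncrna), tag(re$mrna)),
                    genes = tag(genes))
  key1 <- regionKey(lapply(locateSubpathways(lrsp, interesting, 1, 3),
                           function(sp) list(nodes = subpathwayNodes(sp),
                                             sig = signatureNodes(sp))))
  key2 <- regionKey(lapply(locateSubpathways(lrsp2, tag(interesting), 1, 3),
                           function(sp)
                             list(nodes = sort(sub("^zz", "",
                                                   subpathwayNodes(sp))),
                                  sig = sort(sub("^zz", "",
                                                 signatureNodes(sp))))))
  expect_equal(key1, key2)

  # monotonicity: the component containing a fixed signature node never
  # shrinks as n grows
  sig <- signatureNodesOf(lrsp, interesting)
  anchor <- sig[1]
  prevSize <- 0L
  for (n in 0:4) {
    sps <- locateSubpathways(lrsp, interesting, n = n, s = 1)
    holder <- Filter(function(sp) anchor %in% signatureNodes(sp), sps)
    size <- if (length(holder)) length(signatureNodes(holder[[1]])) else 0L
    if (length(holder)) {
      expect_gte(size, prevSize)
      prevSize <- size
    }
  }
})
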