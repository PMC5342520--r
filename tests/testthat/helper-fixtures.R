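# Small in-code fixtures shared across test files.

# an LRSP over a gene chain/graph with lncRNAs attached by regulation edges
makeLRSP <- function(pathwayId, geneEdges, regPairs = NULL,
                     genes = character()) {
  pg <- pathwayGraph(pathwayId, edges = geneEdges, nodes = genes)
  re <- if (is.null(regPairs)) {
    data.frame(lncrna = character(), mrna = character(), r = numeric(),
               nSamples = integer(), p = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(lncrna = regPairs[, 1], mrna = regPairs[, 2], r = 0.6,
               nSamples = 30L, p = 1e-3, stringsAsFactors = FALSE)
  }
  buildLRSP(pg, re)
}

# a random connected gene graph with lncRNAs regulating random genes,
# returned as the pieces the locator oracle needs plus the LRSP itself
randomLRSPCase <- function(nGenes, extraEdgeProb, nLnc, maxRegPerLnc = 3) {
  genes <- sprintf("g%02d", seq_len(nGenes))
  order <- sample(genes)
  edges <- NULL
  if (nGenes > 1) {
    parent <- vapply(2:nGenes, function(i) order[sample.int(i - 1, 1)],
                     character(1))
    edges <- cbind(parent, order[-1])
    pairs <- utils::combn(genes, 2)
    pick <- stats::runif(ncol(pairs)) < extraEdgeProb
    if (any(pick)) edges <- rbind(edges, t(pairs[, pick, drop = FALSE]))
  }
  regPairs <- NULL
  if (nLnc > 0) {
    lnc <- sprintf("L%02d", seq_len(nLnc))
    regPairs <- do.call(rbind, lapply(lnc, function(l)
      cbind(l, sample(genes, sample.int(maxRegPerLnc, 1)))))
  }
  lrsp <- makeLRSP("path:test", edges, regPairs, genes = genes)
  lrsp
}

# minimal 2-group expression SummarizedExperiment from a values matrix
makeExpr <- function(values, classes, nCase = NULL) {
  if (is.null(nCase)) nCase <- ceiling(ncol(values) / 2)
  grp <- c(rep("case", nCase), rep("control", ncol(values) - nCase))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    rowData = S4Vectors::DataFrame(featureClass = classes),
    colData = S4Vectors::DataFrame(group = grp,
                                   row.names = colnames(values)))
}

# tiny deterministic planted scenario for pipeline-level tests (seconds, not
# minutes): 4 pathways x 15 genes, 30+30 samples
smallScenario <- function(seed) {
  simulateScenario(nLnc = 20, nMrna = 60, nMirna = 60, nPathways = 4,
                   nodesPerPathway = 15, edgeProb = 0.15,
                   baselineTargets = 8, plantedPairs = 4,
                   plantedOverlap = 12, nCase = 30, nControl = 30,
                   rhoPlanted = 0.8, deEffect = 2, noiseSd = 1,
                   subpathwaySize = 8, seed = seed)
}
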