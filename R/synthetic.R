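#' @importFrom stats rnorm runif rbinom
NULL

.simSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Simulate an RNA-to-miRNA interaction catalog with planted competing pairs
#'
#' Background RNAs receive uniformly random miRNA partner sets of size
#' \code{baselineTargets}; each planted (lncRNA, mRNA) pair additionally
#' shares \code{plantedOverlap} common miRNAs, making it strongly enriched
#' under the shared-miRNA filter.
#'
#' @param nLnc,nMrna,nMirna numbers of lncRNAs, mRNAs and miRNAs.
#' @param baselineTargets miRNA partners per background RNA.
#' @param plantedPairs number of planted competing pairs.
#' @param plantedOverlap shared miRNAs added to each planted pair; requires
#'   \code{baselineTargets + plantedOverlap <= nMirna}.
#' @param seed integer RNG seed (NULL leaves the RNG stream untouched, for
#'   callers that seed once).
#' @param mrnaIds optional mRNA ID vector (length \code{nMrna}); defaults to
#'   \code{g001...}. Planted pairs use the first IDs unless
#'   \code{plantedMrnaIds} is given.
#' @param plantedMrnaIds optional mRNA IDs to plant the pairs on (length
#'   \code{plantedPairs}).
#' @return list with elements \code{catalog} (an
#'   [InteractionCatalog-class]) and \code{truth} (list with
#'   \code{plantedPairs} data.frame and \code{seed}).
#' @export
simulateCatalog <- function(nLnc = 40, nMrna = 200, nMirna = 100,
                            baselineTargets = 10, plantedPairs = 5,
                            plantedOverlap = 15, seed = NULL,
                            mrnaIds = NULL, plantedMrnaIds = NULL) {
  if (baselineTargets + plantedOverlap > nMirna)
    stop("infeasible sizes: baselineTargets + plantedOverlap > nMirna")
  if (plantedPairs > nLnc || plantedPairs > nMrna)
    stop("more planted pairs than available RNAs")
  .simSeed(seed)
  lncIds <- sprintf("lnc%03d", seq_len(nLnc))
  if (is.null(mrnaIds)) mrnaIds <- sprintf("g%03d", seq_len(nMrna))
  if (length(mrnaIds) != nMrna) stop("mrnaIds must have length nMrna")
  mirIds <- sprintf("mir%03d", seq_len(nMirna))
  lncT <- lapply(lncIds, function(i) sample(mirIds, baselineTargets))
  names(lncT) <- lncIds
  mrnaT <- lapply(mrnaIds, function(i) sample(mirIds, baselineTargets))
  names(mrnaT) <- mrnaIds
  if (is.null(plantedMrnaIds)) plantedMrnaIds <- mrnaIds[seq_len(plantedPairs)]
  if (length(plantedMrnaIds) != plantedPairs)
    stop("plantedMrnaIds must have length plantedPairs")
  plantedLnc <- lncIds[seq_len(plantedPairs)]
  for (i in seq_len(plantedPairs)) {
    sharedSet <- sample(mirIds, plantedOverlap)
    lncT[[plantedLnc[i]]] <- unique(c(lncT[[plantedLnc[i]]], sharedSet))
    mrnaT[[plantedMrnaIds[i]]] <- unique(c(mrnaT[[plantedMrnaIds[i]]],
                                           sharedSet))
  }
  truth <- list(
    plantedPairs = data.frame(lncrna = plantedLnc,
                              mrna = as.character(plantedMrnaIds),
                              stringsAsFactors = FALSE),
    seed = seed)
  # an RNA with no interaction does not appear in a catalog
  lncT <- lncT[lengths(lncT) > 0]
  mrnaT <- mrnaT[lengths(mrnaT) > 0]
  list(catalog = interactionCatalog(lncT, mrnaT, mirnaUniverse = mirIds),
       truth = truth)
}

#' Simulate connected pathway graphs
#'
#' Each pathway is a uniformly random labelled tree (guaranteeing
#' connectivity) plus independent Bernoulli(\code{edgeProb}) extra edges.
#' Gene ID spaces are disjoint across pathways except for a configurable
#' shared fraction drawn from the previous pathways' genes.
#'
#' @param nPathways number of pathways.
#' @param nodesPerPathway genes per pathway.
#' @param edgeProb probability of each extra (non-tree) edge.
#' @param seed integer RNG seed (NULL: do not reseed).
#' @param sharedFraction fraction of each pathway's genes reused from earlier
#'   pathways (0 gives pairwise-disjoint node sets).
#' @return list of [PathwayGraph-class] objects.
#' @export
simulatePathways <- function(nPathways = 8, nodesPerPathway = 25,
                             edgeProb = 0.15, seed = NULL,
                             sharedFraction = 0) {
  .simSeed(seed)
  if (nPathways == 0) return(list())
  out <- vector("list", nPathways)
  prevGenes <- character()
  nextId <- 1L
  for (p in seq_len(nPathways)) {
    nShared <- min(floor(sharedFraction * nodesPerPathway),
                   length(prevGenes))
    shared <- if (nShared > 0) sample(prevGenes, nShared) else character()
    nNew <- nodesPerPathway - length(shared)
    fresh <- sprintf("g%03d", seq.int(nextId, length.out = nNew))
    nextId <- nextId + nNew
    nodes <- sample(c(shared, fresh))  # random attachment order
    edges <- NULL
    if (nodesPerPathway > 1) {
      parent <- vapply(2:nodesPerPathway, function(i)
        nodes[sample.int(i - 1L, 1L)], character(1))
      edges <- cbind(parent, nodes[-1L])
      if (edgeProb > 0) {
        extra <- utils::combn(nodesPerPathway, 2)
        inTree <- paste(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2]))
        a <- nodes[extra[1, ]]; b <- nodes[extra[2, ]]
        keyAll <- paste(pmin(a, b), pmax(a, b))
        candidate <- !(keyAll %in% inTree)
        pick <- candidate & stats::rbinom(length(a), 1, edgeProb) == 1
        if (any(pick)) edges <- rbind(edges, cbind(a[pick], b[pick]))
      }
    }
    out[[p]] <- pathwayGraph(sprintf("path:sim%02d", p), edges = edges,
                             nodes = nodes,
                             name = sprintf("simulated pathway %d", p))
    prevGenes <- unique(c(prevGenes, nodes))
  }
  out
}

#' Simulate a matched lncRNA/mRNA expression matrix with planted structure
#'
#' Background features are i.i.d. Normal(5, \code{noiseSd}). Each planted
#' competing pair is generated from a shared latent factor so its expected
#' Pearson correlation is \code{rhoPlanted}. Genes of the planted subpathway
#' receive a \code{+deEffect} mean shift in case samples.
#'
#' @param catalogTruth the list returned by [simulateCatalog()] (catalog plus
#'   truth), or an [InteractionCatalog-class] with no planted pairs.
#' @param pathways list of [PathwayGraph-class] objects; their genes define
#'   the mRNA features together with the catalog's mRNAs.
#' @param nCase,nControl sample sizes; \code{nCase + nControl > 3}.
#' @param rhoPlanted target correlation of planted pairs, in (0, 1).
#' @param deEffect case-group mean shift of planted-subpathway genes.
#' @param noiseSd residual standard deviation.
#' @param seed integer RNG seed (NULL: do not reseed).
#' @param plantedSubpathway optional list(pathwayId=, nodes=) naming the gene
#'   set that carries the differential signal.
#' @return list with \code{expr} (a \linkS4class{SummarizedExperiment}) and
#'   \code{truth} (planted pairs, planted subpathway, seed).
#' @export
simulateExpression <- function(catalogTruth, pathways, nCase = 100,
                               nControl = 100, rhoPlanted = 0.8,
                               deEffect = 2, noiseSd = 1, seed = NULL,
                               plantedSubpathway = NULL) {
  if (nCase + nControl <= 3) stop("need more than 3 samples in total")
  if (rhoPlanted <= 0 || rhoPlanted >= 1)
    stop("rhoPlanted must lie in (0, 1)")
  .simSeed(seed)
  if (is(catalogTruth, "InteractionCatalog")) {
    catalog <- catalogTruth
    planted <- data.frame(lncrna = character(), mrna = character())
  } else {
    catalog <- catalogTruth$catalog
    planted <- catalogTruth$truth$plantedPairs
  }
  mrnaIds <- sort(unique(c(names(catalog@mrnaTargets),
                           unlist(lapply(pathways, pathwayNodes),
                                  use.names = FALSE))))
  lncIds <- names(catalog@lncTargets)
  feats <- c(mrnaIds, lncIds)
  nS <- nCase + nControl
  X <- matrix(stats::rnorm(length(feats) * nS, mean = 5, sd = noiseSd),
              nrow = length(feats), dimnames = list(feats, NULL))
  # planted pairs: x = 5 + sd*(sqrt(rho) f + sqrt(1-rho) e), corr = rho
  a <- sqrt(rhoPlanted); b <- sqrt(1 - rhoPlanted)
  for (i in seq_len(nrow(planted))) {
    f <- stats::rnorm(nS)
    for (id in c(planted$lncrna[i], planted$mrna[i]))
      X[id, ] <- 5 + noiseSd * (a * f + b * stats::rnorm(nS))
  }
  grp <- c(rep("case", nCase), rep("control", nControl))
  if (!is.null(plantedSubpathway)) {
    pg <- intersect(plantedSubpathway$nodes, mrnaIds)
    X[pg, grp == "case"] <- X[pg, grp == "case", drop = FALSE] + deEffect
  }
  colnames(X) <- sprintf("s%03d", seq_len(nS))
  se <- SummarizedExperiment(
    assays = list(expr = X),
    rowData = S4Vectors::DataFrame(
      featureClass = c(rep("mRNA", length(mrnaIds)),
                       rep("lncRNA", length(lncIds)))),
    colData = S4Vectors::DataFrame(group = grp, row.names = colnames(X)))
  validateExpression(se)
  list(expr = se,
       truth = list(plantedPairs = planted,
                    plantedSubpathway = plantedSubpathway, seed = seed))
}

#' Simulate a complete planted scenario
#'
#' Wires the three generators into one coherent study: pathways are simulated
#' first and partition the mRNA pool; a connected region of the first pathway
#' is chosen as the planted subpathway; the planted competing pairs regulate
#' genes of that region; the expression matrix plants both the pair
#' correlations and the case-group shift of the region's genes. All
#' randomness flows from one \code{set.seed(seed)} call, so equal seeds give
#' identical scenarios.
#'
#' @param nLnc,nMrna,nMirna catalog sizes.
#' @param nPathways,nodesPerPathway,edgeProb pathway simulation parameters;
#'   \code{nPathways * nodesPerPathway} must equal \code{nMrna} (the pathway
#'   genes are the mRNA pool).
#' @param baselineTargets,plantedPairs,plantedOverlap catalog parameters.
#' @param nCase,nControl,rhoPlanted,deEffect,noiseSd expression parameters.
#' @param subpathwaySize planted-region size in genes.
#' @param seed integer RNG seed.
#' @return list with \code{catalog}, \code{pathways}, \code{expr} and
#'   \code{truth} (planted pairs, planted subpathway, seed).
#' @export
simulateScenario <- function(nLnc = 40, nMrna = 200, nMirna = 100,
                             nPathways = 8, nodesPerPathway = 25,
                             edgeProb = 0.15, baselineTargets = 10,
                             plantedPairs = 5, plantedOverlap = 15,
                             nCase = 100, nControl = 100, rhoPlanted = 0.8,
                             deEffect = 2, noiseSd = 1, subpathwaySize = 10,
                             seed = 1) {
  if (nPathways * nodesPerPathway != nMrna)
    stop("nPathways * nodesPerPathway must equal nMrna")
  set.seed(as.integer(seed))
  pathways <- simulatePathways(nPathways, nodesPerPathway, edgeProb,
                               seed = NULL, sharedFraction = 0)
  target <- pathways[[1]]
  # planted region: breadth-first ball around a random seed gene
  g <- target@graph
  start <- sample(igraph::V(g)$name, 1)
  bfs <- igraph::bfs(g, root = start, order = TRUE)
  region <- igraph::V(g)$name[as.integer(bfs$order)[
    seq_len(min(subpathwaySize, igraph::gorder(g)))]]
  plantedMrna <- region[seq_len(min(plantedPairs, length(region)))]
  allGenes <- unlist(lapply(pathways, pathwayNodes), use.names = FALSE)
  ct <- simulateCatalog(nLnc, nMrna, nMirna, baselineTargets, plantedPairs,
                        plantedOverlap, seed = NULL, mrnaIds = sort(allGenes),
                        plantedMrnaIds = plantedMrna)
  plantedSub <- list(pathwayId = target@pathwayId, nodes = region)
  ex <- simulateExpression(ct, pathways, nCase, nControl, rhoPlanted,
                           deEffect, noiseSd, seed = NULL,
                           plantedSubpathway = plantedSub)
  list(catalog = ct$catalog, pathways = pathways, expr = ex$expr,
       truth = list(plantedPairs = ct$truth$plantedPairs,
                    plantedSubpathway = plantedSub, seed = seed))
}

#' Randomly perturb inputs for the robustness harness
#'
#' Either deletes a uniformly random fraction of expression features (both
#' RNA classes pooled) or a uniformly random fraction of LRSP edges (gene-gene
#' and regulation edges pooled across all supplied LRSPs). Deletion counts use
#' \code{floor(fraction * size)}; the input object is never modified.
#'
#' @param x a \linkS4class{SummarizedExperiment} (mode
#'   \code{"deleteFeatures"}) or a list of [LRSPGraph-class] objects (mode
#'   \code{"deleteEdges"}).
#' @param fraction fraction to delete, in [0, 1).
#' @param mode \code{"deleteFeatures"} or \code{"deleteEdges"}.
#' @param seed integer RNG seed (NULL: do not reseed).
#' @return a perturbed copy of \code{x}, same type.
#' @export
perturbForRobustness <- function(x, fraction,
                                 mode = c("deleteFeatures", "deleteEdges"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  .simSeed(seed)
  if (mode == "deleteFeatures") {
    if (!methods::is(x, "SummarizedExperiment"))
      stop("deleteFeatures mode expects a SummarizedExperiment")
    k <- floor(fraction * nrow(x))
    if (k == 0) return(x)
    drop <- sample.int(nrow(x), k)
    return(x[-drop, ])
  }
  if (!is.list(x) || !all(vapply(x, is, logical(1), "LRSPGraph")))
    stop("deleteEdges mode expects a list of LRSPGraph objects")
  counts <- vapply(x, function(l) as.integer(igraph::gsize(l@graph)),
                   integer(1))
  total <- sum(counts)
  k <- floor(fraction * total)
  if (k == 0) return(x)
  drop <- sample.int(total, k)
  offsets <- cumsum(c(0L, counts))
  lapply(seq_along(x), function(i) {
    lr <- x[[i]]
    local <- drop[drop > offsets[i] & drop <= offsets[i + 1]] - offsets[i]
    if (!length(local)) return(lr)
    el <- igraph::as_edgelist(lr@graph, names = TRUE)
    delEdges <- el[local, , drop = FALSE]
    # split deletions into base gene-gene edges and regulation edges, then
    # rebuild so the LRSP invariants (lncRNA nodes = regulation lncRNAs) hold
    lnc <- lncrnaNodes(lr)
    isReg <- delEdges[, 1] %in% lnc | delEdges[, 2] %in% lnc
    baseEl <- pathwayEdges(lr@base)
    if (any(!isReg)) {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      kill <- key(delEdges[!isReg, 1], delEdges[!isReg, 2])
      keep <- !(key(baseEl$from, baseEl$to) %in% kill)
      baseEl <- baseEl[keep, , drop = FALSE]
    }
    newBase <- pathwayGraph(lr@base@pathwayId,
                            edges = as.matrix(baseEl),
                            nodes = pathwayNodes(lr@base),
                            name = lr@base@name)
    re <- regulationEdges(lr)
    if (any(isReg)) {
      dl <- delEdges[isReg, , drop = FALSE]
      regLnc <- ifelse(dl[, 1] %in% lnc, dl[, 1], dl[, 2])
      regMrna <- ifelse(dl[, 1] %in% lnc, dl[, 2], dl[, 1])
      keep <- !(paste(re$lncrna, re$mrna) %in% paste(regLnc, regMrna))
      re <- re[keep, , drop = FALSE]
    }
    buildLRSP(newBase, re)
  })
}
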