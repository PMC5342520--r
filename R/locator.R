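NULL

#' Signature nodes of an LRSP
#'
#' The nodes that seed subpathway location: every lncRNA embedded in the LRSP
#' (it is involved in the competing regulation by construction) plus each
#' interesting gene that is a node of this pathway.
#'
#' @param lrsp an [LRSPGraph-class].
#' @param interestingGenes character vector of interesting (e.g.
#'   differentially expressed or user-supplied) gene IDs.
#' @return character vector of signature node IDs (possibly empty).
#' @export
signatureNodesOf <- function(lrsp, interestingGenes) {
  stopifnot(is(lrsp, "LRSPGraph"))
  genes <- igraph::V(lrsp@base@graph)$name
  sort(unique(c(intersect(as.character(interestingGenes), genes),
                lncrnaNodes(lrsp))))
}

#' Locate candidate subpathways by lenient-distance merging
#'
#' Signature nodes are merged when the number of molecules between them on a
#' shortest path of the LRSP is at most \code{n}, i.e. when their unweighted
#' shortest-path distance is at most \code{n + 1}; merging is transitive
#' (connected components of the linkage relation). Distances are taken on the
#' full LRSP, so gene-gene edges and lncRNA regulation edges count alike and
#' two genes can be merged through a shared lncRNA regulator. Each merged
#' region's node set is its signature nodes plus every node lying on at least
#' one shortest path between a linked signature pair of the region. Regions
#' with at least \code{s} molecules (genes and lncRNAs both count) and at
#' least one lncRNA are reported as candidate subpathways.
#'
#' Subpathways are named \code{"<pathwayId>_<k>"} with \code{k} assigned in
#' order of decreasing node count, ties broken by the lexicographically
#' smallest member ID.
#'
#' @param lrsp an [LRSPGraph-class].
#' @param interestingGenes character vector of interesting gene IDs.
#' @param n maximum number of intermediate molecules allowed between merged
#'   signature nodes (default 1).
#' @param s minimum subpathway size in molecules (default 8).
#' @return list of [Subpathway-class] objects (possibly empty).
#' @export
locateSubpathways <- function(lrsp, interestingGenes, n = 1L, s = 8L) {
  stopifnot(is(lrsp, "LRSPGraph"), n >= 0, s >= 1)
  sig <- signatureNodesOf(lrsp, interestingGenes)
  if (!length(sig)) return(list())
  g <- lrsp@graph
  allNames <- igraph::V(g)$name
  D <- igraph::distances(g, v = sig, to = igraph::V(g))
  colnames(D) <- allNames
  Dsig <- D[, sig, drop = FALSE]

  # linkage: distinct signature pairs with <= n intermediates
  linked <- is.finite(Dsig) & Dsig >= 1 & Dsig <= n + 1
  lg <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(lg)
  memb <- split(sig, comp$membership)

  nodeType <- setNames(igraph::vertex_attr(g, "nodeType"), allNames)
  regions <- lapply(memb, function(cs) {
    if (length(cs) == 1L) return(list(nodes = cs, sig = cs))
    sub <- Dsig[cs, cs, drop = FALSE]
    pairIdx <- which(is.finite(sub) & sub >= 1 & sub <= n + 1,
                     arr.ind = TRUE)
    pairIdx <- pairIdx[pairIdx[, 1] < pairIdx[, 2], , drop = FALSE]
    onPath <- rep(FALSE, length(allNames))
    for (i in seq_len(nrow(pairIdx))) {
      u <- cs[pairIdx[i, 1]]; v <- cs[pairIdx[i, 2]]
      onPath <- onPath | (D[u, ] + D[v, ] == D[u, v][[1]])
    }
    list(nodes = sort(unique(c(cs, allNames[onPath]))), sig = cs)
  })

  keep <- vapply(regions, function(rg) {
    length(rg$nodes) >= s && any(nodeType[rg$nodes] == "lncRNA")
  }, logical(1))
  regions <- regions[keep]
  if (!length(regions)) return(list())

  sizes <- vapply(regions, function(rg) length(rg$nodes), integer(1))
  firstMember <- vapply(regions, function(rg) min(rg$nodes), character(1))
  ord <- order(-sizes, firstMember)
  regions <- regions[ord]
  lapply(seq_along(regions), function(k) {
    rg <- regions[[k]]
    isLnc <- nodeType[rg$nodes] == "lncRNA"
    new("Subpathway",
        subpathwayId = sprintf("%s_%d", lrsp@pathwayId, k),
        pathwayId = lrsp@pathwayId,
        nodes = rg$nodes,
        genes = rg$nodes[!isLnc],
        lncrnas = rg$nodes[isLnc],
        signatureNodes = sort(rg$sig))
  })
}

#' Write located subpathways as TSV
#'
#' @param subpathways list of [Subpathway-class] objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSubpathways <- function(subpathways, path) {
  df <- data.frame(
    subpathway_id = vapply(subpathways, subpathwayId, character(1)),
    pathway_id = vapply(subpathways, pathwayId, character(1)),
    node_count = vapply(subpathways, function(sp)
      length(subpathwayNodes(sp)), integer(1)),
    members = vapply(subpathways, function(sp)
      paste(subpathwayNodes(sp), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
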