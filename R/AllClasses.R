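#' @import methods
#' @importFrom igraph is_igraph gorder gsize V vcount ecount is_directed
#'   any_loop any_multiple vertex_attr
NULL

#' Catalog of RNA-to-miRNA interactions
#'
#' Holds, for each lncRNA and each mRNA, the set of miRNAs it interacts with,
#' together with the miRNA universe used as the background of the shared-miRNA
#' hypergeometric test. Interaction catalogs are taken as given (e.g. predicted
#' lncRNA-miRNA sites and experimentally validated mRNA-miRNA pairs); the
#' package does not predict miRNA targets.
#'
#' @slot lncTargets named list; each element a character vector of miRNA IDs
#'   for one lncRNA.
#' @slot mrnaTargets named list; each element a character vector of miRNA IDs
#'   for one mRNA.
#' @slot mirnaUniverse character vector of all miRNA IDs forming the background
#'   \code{N} of the hypergeometric test. Must contain every miRNA occurring in
#'   either target map.
#'
#' @seealso [interactionCatalog()], [buildCandidateNetwork()]
#' @export
setClass("InteractionCatalog",
  representation(
    lncTargets = "list",
    mrnaTargets = "list",
    mirnaUniverse = "character"
  )
)

setValidity("InteractionCatalog", function(object) {
  msg <- character()
  chkmap <- function(m, what) {
    if (length(m)) {
      if (is.null(names(m)) || anyNA(names(m)) || any(names(m) == ""))
        msg <<- c(msg, sprintf("all %s entries must be named", what))
      if (anyDuplicated(names(m)))
        msg <<- c(msg, sprintf("duplicate RNA IDs in %s", what))
      if (any(lengths(m) == 0L))
        msg <<- c(msg, sprintf("empty miRNA set in %s", what))
      if (!all(vapply(m, is.character, logical(1))))
        msg <<- c(msg, sprintf("%s elements must be character vectors", what))
    }
  }
  chkmap(object@lncTargets, "lncTargets")
  chkmap(object@mrnaTargets, "mrnaTargets")
  seen <- unique(unlist(c(object@lncTargets, object@mrnaTargets),
                        use.names = FALSE))
  if (!all(seen %in% object@mirnaUniverse))
    msg <- c(msg, "mirnaUniverse must contain every miRNA in the target maps")
  if (anyDuplicated(object@mirnaUniverse))
    msg <- c(msg, "mirnaUniverse contains duplicates")
  if (length(msg)) msg else TRUE
})

#' Candidate lncRNA-mRNA competing network
#'
#' The result of the dual shared-miRNA filter: all candidate pairs (those
#' sharing at least one miRNA) with their statistics, and the subset retained
#' by both the hypergeometric test and the top-quantile Jaccard rule.
#'
#' @slot candidates data.frame of every scored candidate pair, with columns
#'   \code{lncrna}, \code{mrna}, \code{shared}, \code{K}, \code{M}, \code{N},
#'   \code{hypergP}, \code{jaccard}, \code{passedHyperg}, \code{passedJaccard}.
#' @slot pairs data.frame, the rows of \code{candidates} passing both filters.
#' @slot jaccardCutoff numeric(1), the Jaccard value at the retained quantile
#'   (NA when there are no candidates).
#'
#' @seealso [buildCandidateNetwork()], [filterByCoexpression()]
#' @export
setClass("CeRNANetwork",
  representation(
    candidates = "data.frame",
    pairs = "data.frame",
    jaccardCutoff = "numeric"
  )
)

.PAIR_COLS <- c("lncrna", "mrna", "shared", "K", "M", "N",
                "hypergP", "jaccard", "passedHyperg", "passedJaccard")

setValidity("CeRNANetwork", function(object) {
  msg <- character()
  for (slotname in c("candidates", "pairs")) {
    df <- slot(object, slotname)
    if (!all(.PAIR_COLS %in% names(df)))
      msg <- c(msg, sprintf("%s must have columns: %s", slotname,
                            paste(.PAIR_COLS, collapse = ", ")))
  }
  if (nrow(object@pairs) &&
      !all(object@pairs$passedHyperg & object@pairs$passedJaccard))
    msg <- c(msg, "all retained pairs must pass both filters")
  if (length(msg)) msg else TRUE
})

#' Undirected pathway graph
#'
#' A signal pathway converted to a simple undirected graph with genes as nodes
#' and regulation relations as edges (direction and relation subtype
#' discarded, self-loops dropped, duplicate edges collapsed).
#'
#' @slot pathwayId character(1), e.g. \code{"path:04020"}.
#' @slot name character(1) human-readable pathway name (may be "").
#' @slot graph an undirected simple \pkg{igraph} object whose vertex names are
#'   gene IDs.
#'
#' @seealso [pathwayGraph()], [readPathwayEdgelist()], [readKGML()]
#' @export
setClass("PathwayGraph",
  representation(
    pathwayId = "character",
    name = "character",
    graph = "ANY"
  )
)

setValidity("PathwayGraph", function(object) {
  msg <- character()
  if (length(object@pathwayId) != 1L || is.na(object@pathwayId) ||
      !nzchar(object@pathwayId))
    msg <- c(msg, "pathwayId must be a single non-empty string")
  g <- object@graph
  if (!igraph::is_igraph(g)) {
    msg <- c(msg, "graph must be an igraph object")
  } else {
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (igraph::any_loop(g)) msg <- c(msg, "graph must not contain self-loops")
    if (igraph::any_multiple(g)) msg <- c(msg, "graph must be simple")
    nm <- igraph::vertex_attr(g, "name")
    if (igraph::vcount(g) > 0 && (is.null(nm) || anyDuplicated(nm)))
      msg <- c(msg, "vertices must carry unique names")
  }
  if (length(msg)) msg else TRUE
})

#' lncRNA-regulated signal pathway (LRSP)
#'
#' A pathway graph augmented with the lncRNA nodes that competitively regulate
#' member mRNAs under the studied condition, each linked by an undirected
#' regulation edge to its regulated mRNA.
#'
#' @slot pathwayId character(1).
#' @slot base the underlying [PathwayGraph-class].
#' @slot graph undirected \pkg{igraph} over genes plus embedded lncRNAs;
#'   vertex attribute \code{nodeType} is \code{"gene"} or \code{"lncRNA"}.
#' @slot regulationEdges data.frame with columns \code{lncrna}, \code{mrna},
#'   \code{r}, \code{nSamples}, \code{p} (the retained co-expression edges
#'   embedded into this pathway).
#'
#' @seealso [buildLRSP()], [locateSubpathways()]
#' @export
setClass("LRSPGraph",
  representation(
    pathwayId = "character",
    base = "PathwayGraph",
    graph = "ANY",
    regulationEdges = "data.frame"
  )
)

setValidity("LRSPGraph", function(object) {
  msg <- character()
  re <- object@regulationEdges
  need <- c("lncrna", "mrna", "r", "nSamples", "p")
  if (!all(need %in% names(re)))
    msg <- c(msg, sprintf("regulationEdges must have columns: %s",
                          paste(need, collapse = ", ")))
  g <- object@graph
  if (!igraph::is_igraph(g) || igraph::is_directed(g)) {
    msg <- c(msg, "graph must be an undirected igraph")
  } else if (all(need %in% names(re))) {
    baseNodes <- igraph::V(object@base@graph)$name
    if (nrow(re) && !all(re$mrna %in% baseNodes))
      msg <- c(msg, "every regulation edge must target a base-graph gene")
    tp <- igraph::vertex_attr(g, "nodeType")
    if (igraph::vcount(g) > 0 &&
        (is.null(tp) || !all(tp %in% c("gene", "lncRNA"))))
      msg <- c(msg, "vertex attribute nodeType must be gene/lncRNA")
    lnc <- igraph::V(g)$name[which(tp == "lncRNA")]
    if (!setequal(lnc, unique(re$lncrna)))
      msg <- c(msg, "lncRNA nodes must be exactly the regulation-edge lncRNAs")
  }
  if (length(msg)) msg else TRUE
})

#' A located subpathway
#'
#' A candidate subpathway: a merged region of one LRSP seeded by signature
#' nodes, containing at least one embedded lncRNA.
#'
#' @slot subpathwayId character(1), \code{"<pathwayId>_<k>"}.
#' @slot pathwayId character(1).
#' @slot nodes character, all member node IDs (genes and lncRNAs).
#' @slot genes character, the mRNA members.
#' @slot lncrnas character, the lncRNA members.
#' @slot signatureNodes character, the signature nodes that seeded the region.
#'
#' @seealso [locateSubpathways()], [evaluateSubpathways()]
#' @export
setClass("Subpathway",
  representation(
    subpathwayId = "character",
    pathwayId = "character",
    nodes = "character",
    genes = "character",
    lncrnas = "character",
    signatureNodes = "character"
  )
)

setValidity("Subpathway", function(object) {
  msg <- character()
  if (!setequal(object@nodes, c(object@genes, object@lncrnas)))
    msg <- c(msg, "genes and lncrnas must partition nodes")
  if (length(intersect(object@genes, object@lncrnas)))
    msg <- c(msg, "genes and lncrnas must be disjoint")
  if (length(object@lncrnas) < 1L)
    msg <- c(msg, "a subpathway must contain at least one lncRNA")
  if (!all(object@signatureNodes %in% object@nodes))
    msg <- c(msg, "signature nodes must be members")
  if (length(msg)) msg else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "InteractionCatalog", function(object) {
  cat("InteractionCatalog\n",
      "  lncRNAs: ", length(object@lncTargets),
      "  mRNAs: ", length(object@mrnaTargets),
      "  miRNA universe: ", length(object@mirnaUniverse), "\n", sep = "")
})

setMethod("show", "CeRNANetwork", function(object) {
  cat("CeRNANetwork\n",
      "  candidate pairs: ", nrow(object@candidates), "\n",
      "  retained pairs:  ", nrow(object@pairs),
      " (", length(unique(object@pairs$lncrna)), " lncRNAs, ",
      length(unique(object@pairs$mrna)), " mRNAs)\n",
      "  Jaccard cutoff:  ",
      format(object@jaccardCutoff, digits = 4), "\n", sep = "")
})

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph ", object@pathwayId,
      if (nzchar(object@name)) paste0(" (", object@name, ")") else "",
      ": ", igraph::gorder(object@graph), " genes, ",
      igraph::gsize(object@graph), " edges\n", sep = "")
})

setMethod("show", "LRSPGraph", function(object) {
  cat("LRSPGraph ", object@pathwayId, ": ",
      igraph::gorder(object@base@graph), " genes + ",
      length(lncrnaNodes(object)), " lncRNAs, ",
      nrow(object@regulationEdges), " regulation edges\n", sep = "")
})

setMethod("show", "Subpathway", function(object) {
  cat("Subpathway ", object@subpathwayId, ": ",
      length(object@nodes), " nodes (",
      length(object@genes), " genes, ",
      length(object@lncrnas), " lncRNAs)\n", sep = "")
})
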