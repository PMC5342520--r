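#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{retainedPairs()} returns the retained competing pairs of a
#' [CeRNANetwork-class] (or all candidates with \code{all = TRUE});
#' \code{pathwayNodes()} / \code{pathwayEdges()} return the gene nodes and
#' edge list of a [PathwayGraph-class] or the full node/edge sets of an
#' [LRSPGraph-class]; \code{lncrnaNodes()} and \code{regulationEdges()} expose
#' the lncRNA embedding of an LRSP; \code{subpathwayNodes()},
#' \code{subpathwayGenes()} and \code{subpathwayLncrnas()} expose subpathway
#' membership.
#'
#' @param x object.
#' @param ... passed on to methods.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("retainedPairs", function(x, ...) standardGeneric("retainedPairs"))

#' @rdname accessors
#' @param all logical; return every scored candidate instead of only the
#'   retained pairs.
#' @export
setMethod("retainedPairs", "CeRNANetwork", function(x, all = FALSE) {
  if (all) x@candidates else x@pairs
})

#' @rdname accessors
#' @export
setGeneric("pathwayId", function(x) standardGeneric("pathwayId"))

#' @rdname accessors
#' @export
setMethod("pathwayId", "PathwayGraph", function(x) x@pathwayId)

#' @rdname accessors
#' @export
setMethod("pathwayId", "LRSPGraph", function(x) x@pathwayId)

#' @rdname accessors
#' @export
setMethod("pathwayId", "Subpathway", function(x) x@pathwayId)

#' @rdname accessors
#' @export
setGeneric("pathwayNodes", function(x) standardGeneric("pathwayNodes"))

#' @rdname accessors
#' @export
setMethod("pathwayNodes", "PathwayGraph", function(x) {
  igraph::V(x@graph)$name
})

#' @rdname accessors
#' @export
setMethod("pathwayNodes", "LRSPGraph", function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))

#' @rdname accessors
#' @export
setMethod("pathwayEdges", "PathwayGraph", function(x) {
  el <- igraph::as_edgelist(x@graph, names = TRUE)
  data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("pathwayEdges", "LRSPGraph", function(x) {
  el <- igraph::as_edgelist(x@graph, names = TRUE)
  data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("lncrnaNodes", function(x) standardGeneric("lncrnaNodes"))

#' @rdname accessors
#' @export
setMethod("lncrnaNodes", "LRSPGraph", function(x) {
  v <- igraph::V(x@graph)
  v$name[igraph::vertex_attr(x@graph, "nodeType") == "lncRNA"]
})

#' @rdname accessors
#' @export
setGeneric("regulationEdges", function(x) standardGeneric("regulationEdges"))

#' @rdname accessors
#' @export
setMethod("regulationEdges", "LRSPGraph", function(x) x@regulationEdges)

#' @rdname accessors
#' @export
setGeneric("subpathwayId", function(x) standardGeneric("subpathwayId"))

#' @rdname accessors
#' @export
setMethod("subpathwayId", "Subpathway", function(x) x@subpathwayId)

#' @rdname accessors
#' @export
setGeneric("subpathwayNodes", function(x) standardGeneric("subpathwayNodes"))

#' @rdname accessors
#' @export
setMethod("subpathwayNodes", "Subpathway", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("subpathwayGenes", function(x) standardGeneric("subpathwayGenes"))

#' @rdname accessors
#' @export
setMethod("subpathwayGenes", "Subpathway", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("subpathwayLncrnas",
           function(x) standardGeneric("subpathwayLncrnas"))

#' @rdname accessors
#' @export
setMethod("subpathwayLncrnas", "Subpathway", function(x) x@lncrnas)

#' @rdname accessors
#' @export
setGeneric("signatureNodes", function(x) standardGeneric("signatureNodes"))

#' @rdname accessors
#' @export
setMethod("signatureNodes", "Subpathway", function(x) x@signatureNodes)

# ---- constructors -----------------------------------------------------------

#' Construct an interaction catalog
#'
#' @param lncTargets named list mapping lncRNA IDs to character vectors of
#'   miRNA IDs.
#' @param mrnaTargets named list mapping mRNA IDs to character vectors of
#'   miRNA IDs.
#' @param mirnaUniverse optional character vector defining the hypergeometric
#'   background; defaults to the union of all miRNAs in both maps (the only
#'   background derivable from the inputs alone).
#' @return An [InteractionCatalog-class].
#' @examples
#' cat <- interactionCatalog(
#'   lncTargets = list(L1 = c("m1", "m2")),
#'   mrnaTargets = list(G1 = c("m2", "m3")))
#' cat
#' @export
interactionCatalog <- function(lncTargets, mrnaTargets,
                               mirnaUniverse = NULL) {
  lncTargets <- lapply(lncTargets, function(x) sort(unique(as.character(x))))
  mrnaTargets <- lapply(mrnaTargets, function(x) sort(unique(as.character(x))))
  if (is.null(mirnaUniverse))
    mirnaUniverse <- sort(unique(unlist(c(lncTargets, mrnaTargets),
                                        use.names = FALSE)))
  new("InteractionCatalog", lncTargets = lncTargets,
      mrnaTargets = mrnaTargets,
      mirnaUniverse = sort(unique(as.character(mirnaUniverse))))
}

#' Construct a pathway graph
#'
#' Builds an undirected simple [PathwayGraph-class] from an edge list,
#' dropping self-loops and collapsing duplicate/reversed edges.
#'
#' @param pathwayId pathway identifier, e.g. \code{"path:04020"}.
#' @param edges two-column matrix or data.frame of gene-ID pairs (may be
#'   empty).
#' @param nodes optional character vector of additional isolated nodes.
#' @param name human-readable pathway name.
#' @return A [PathwayGraph-class].
#' @examples
#' pathwayGraph("path:00001", edges = cbind(c("A", "B"), c("B", "A")))
#' @export
pathwayGraph <- function(pathwayId, edges = NULL, nodes = character(),
                         name = "") {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L)
      stop("'edges' must have exactly two columns")
    storage.mode(em) <- "character"
  }
  allNodes <- sort(unique(c(as.character(em), as.character(nodes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = FALSE, vertices = allNodes)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new("PathwayGraph", pathwayId = as.character(pathwayId),
      name = as.character(name), graph = g)
}
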