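#' @useDynLib ceRNAsubpath, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Competing-regulation weight of a subpathway
#'
#' The odds weight given to a subpathway's mRNAs in the biased-urn test,
#' \deqn{W = 1 + \beta\,(-\log_2(G_L / P_G)),}
#' where \eqn{P_G} is the number of mRNA members and \eqn{G_L} the number of
#' mRNA members competitively regulated by the subpathway's lncRNAs. The
#' weight grows as the regulated fraction shrinks, up-weighting subpathways
#' where few genes carry the competing-regulation signal; \eqn{W = 1} (no
#' bias) when every member gene is regulated.
#'
#' @param G_L number of lncRNA-regulated mRNA members; must be at least 1.
#' @param P_G number of mRNA members; \code{G_L <= P_G}.
#' @param beta non-negative control parameter (default 1).
#' @return weight \code{W >= 1} for \code{beta >= 0}. Vectorised.
#' @examples
#' subpathwayWeight(4, 16)        # 3
#' subpathwayWeight(8, 8)         # 1: every gene regulated
#' @export
subpathwayWeight <- function(G_L, P_G, beta = 1) {
  if (any(G_L < 1)) stop("G_L must be at least 1 (no regulated gene)")
  if (any(G_L > P_G)) stop("G_L cannot exceed P_G")
  1 + beta * (-log2(G_L / P_G))
}

#' Wallenius noncentral hypergeometric pmf
#'
#' Probability mass function of the number of weighted ("red") balls among
#' \code{x} sequential draws without replacement from an urn of \code{n}
#' balls, \code{m1} of which carry odds weight \code{w} against 1 for the
#' rest. Computed by an exact forward recursion over draw states (no
#' Monte-Carlo, no asymptotic approximation); with \code{w = 1} it reduces to
#' the central hypergeometric distribution.
#'
#' @param n urn size.
#' @param m1 number of weighted balls.
#' @param x number of draws.
#' @param w positive odds weight.
#' @return numeric vector of \code{P(X = k)} for \code{k = 0..x}.
#' @examples
#' walleniusPMF(10, 4, 5, 1)          # equals dhyper(0:5, 4, 6, 5)
#' sum(walleniusPMF(12, 5, 6, 2.5))   # 1
#' @export
walleniusPMF <- function(n, m1, x, w) {
  wallenius_pmf_cpp(as.integer(n), as.integer(m1), as.integer(x),
                    as.numeric(w))
}

#' Upper tail of the Wallenius noncentral hypergeometric distribution
#'
#' Returns \eqn{P(X \ge m2)} for the biased urn of [walleniusPMF()]:
#' \code{x} interesting mRNAs drawn from \code{n} background mRNAs of which
#' \code{m1} belong to the subpathway and carry odds weight \code{w}. The
#' tail is inclusive of the observed count; \code{m2 = 0} returns exactly 1.
#'
#' @param x number of draws (interesting mRNAs).
#' @param n urn size (background mRNAs).
#' @param m1 number of weighted balls (background mRNAs in the subpathway).
#' @param m2 observed count (interesting mRNAs in the subpathway).
#' @param w positive odds weight of the subpathway mRNAs.
#' @return upper-tail probability in (0, 1].
#' @examples
#' walleniusUpperTail(x = 5, n = 10, m1 = 4, m2 = 3, w = 1)  # 66/252
#' @export
walleniusUpperTail <- function(x, n, m1, m2, w) {
  if (m2 > min(x, m1))
    stop("infeasible urn: m2 must not exceed min(x, m1)")
  if (m2 < 0) stop("m2 must be non-negative")
  if (m2 == 0) return(1)
  pmf <- walleniusPMF(n, m1, x, w)
  min(1, sum(pmf[(m2 + 1):(x + 1)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (a validated front over
#' \code{stats::p.adjust(method = "BH")}), order-preserving with respect to
#' the input.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted values aligned to the input.
#' @export
bhFdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Default mRNA background for the enrichment urn
#'
#' The union of gene nodes over all supplied pathway graphs, optionally
#' intersected with the mRNAs present in the expression matrix (the default,
#' restricting the urn to genes that could have been observed).
#'
#' @param pathways list of [PathwayGraph-class] or [LRSPGraph-class] objects.
#' @param expr optional \linkS4class{SummarizedExperiment}; when supplied and
#'   \code{restrictToExpression} is TRUE, the background is intersected with
#'   its mRNA features.
#' @param restrictToExpression logical.
#' @return character vector of background mRNA IDs.
#' @export
backgroundMrnas <- function(pathways, expr = NULL,
                            restrictToExpression = TRUE) {
  nodes <- unique(unlist(lapply(pathways, function(p) {
    if (is(p, "LRSPGraph")) igraph::V(p@base@graph)$name else pathwayNodes(p)
  }), use.names = FALSE))
  if (!is.null(expr) && restrictToExpression) {
    isM <- SummarizedExperiment::rowData(expr)$featureClass == "mRNA"
    nodes <- intersect(nodes, rownames(expr)[isM])
  }
  sort(nodes)
}

#' Score candidate subpathways with the weighted biased-urn test
#'
#' For each candidate subpathway the urn is: \code{n} background mRNAs of
#' which \code{m1} are subpathway members carrying odds weight
#' \code{W = subpathwayWeight(G_L, P_G, beta)}; \code{x} interesting mRNAs
#' are drawn and \code{m2} of them fall in the subpathway. \code{P_G} counts
#' the subpathway's mRNA members and \code{G_L} those with at least one
#' regulation edge to a subpathway-member lncRNA in the LRSP. Significance is
#' the inclusive upper tail of the Wallenius noncentral hypergeometric
#' distribution; FDR is Benjamini-Hochberg over all scored subpathways. Only
#' mRNAs enter the urn; lncRNAs contribute through \code{G_L} and the weight.
#'
#' @param subpathways list of [Subpathway-class] objects.
#' @param lrsps list of [LRSPGraph-class] objects, named by pathway ID (an
#'   unnamed list is named from the objects).
#' @param interestingGenes character vector of interesting mRNA IDs; genes
#'   outside the background are dropped with a message.
#' @param background character vector of background mRNA IDs (see
#'   [backgroundMrnas()]).
#' @param beta weight control parameter; \code{beta = 0} reduces the test to
#'   the central hypergeometric.
#' @return data.frame with one row per scored subpathway (columns
#'   \code{subpathway_id}, \code{pathway_id}, \code{pathway_name},
#'   \code{node_count}, \code{gene_count}, \code{lncrna_count}, \code{x},
#'   \code{n}, \code{m1}, \code{m2}, \code{G_L}, \code{P_G}, \code{W},
#'   \code{pvalue}, \code{fdr}, \code{member_genes}, \code{member_lncrnas}),
#'   sorted by FDR then p-value ascending. Subpathways with no background
#'   member (\code{m1 = 0}) are skipped with a warning.
#' @export
evaluateSubpathways <- function(subpathways, lrsps, interestingGenes,
                                background, beta = 1) {
  if (!length(background)) stop("background mRNA set is empty")
  background <- unique(as.character(background))
  if (is.null(names(lrsps)) || !all(nzchar(names(lrsps))))
    names(lrsps) <- vapply(lrsps, pathwayId, character(1))
  interesting <- unique(as.character(interestingGenes))
  outside <- setdiff(interesting, background)
  if (length(outside))
    message(length(outside),
            " interesting gene(s) outside the background dropped")
  interesting <- intersect(interesting, background)
  x <- length(interesting)
  n <- length(background)

  rows <- lapply(subpathways, function(sp) {
    genes <- subpathwayGenes(sp)
    lrsp <- lrsps[[pathwayId(sp)]]
    if (is.null(lrsp))
      stop("no LRSP supplied for pathway ", pathwayId(sp))
    re <- regulationEdges(lrsp)
    regulated <- unique(re$mrna[re$lncrna %in% subpathwayLncrnas(sp)])
    G_L <- length(intersect(regulated, genes))
    P_G <- length(genes)
    m1 <- length(intersect(genes, background))
    m2 <- length(intersect(intersect(genes, interesting), background))
    if (m1 == 0L) {
      warning("subpathway ", subpathwayId(sp),
              " has no background mRNA member; skipped")
      return(NULL)
    }
    if (G_L == 0L) {
      warning("subpathway ", subpathwayId(sp),
              " has no lncRNA-regulated member gene; skipped")
      return(NULL)
    }
    W <- subpathwayWeight(G_L, P_G, beta)
    data.frame(
      subpathway_id = subpathwayId(sp),
      pathway_id = pathwayId(sp),
      pathway_name = lrsp@base@name,
      node_count = length(subpathwayNodes(sp)),
      gene_count = P_G,
      lncrna_count = length(subpathwayLncrnas(sp)),
      x = x, n = n, m1 = m1, m2 = m2, G_L = G_L, P_G = P_G, W = W,
      pvalue = walleniusUpperTail(x = x, n = n, m1 = m1, m2 = m2, w = W),
      member_genes = paste(genes, collapse = ","),
      member_lncrnas = paste(subpathwayLncrnas(sp), collapse = ","),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(subpathway_id = character(), pathway_id = character(),
                      pathway_name = character(), node_count = integer(),
                      gene_count = integer(), lncrna_count = integer(),
                      x = integer(), n = integer(), m1 = integer(),
                      m2 = integer(), G_L = integer(), P_G = integer(),
                      W = numeric(), pvalue = numeric(), fdr = numeric(),
                      member_genes = character(),
                      member_lncrnas = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$pvalue)
  out <- out[order(out$fdr, out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("subpathway_id", "pathway_id", "pathway_name", "node_count",
          "gene_count", "lncrna_count", "x", "n", "m1", "m2", "G_L", "P_G",
          "W", "pvalue", "fdr", "member_genes", "member_lncrnas")]
}
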