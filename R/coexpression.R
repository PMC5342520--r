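#' @importFrom stats pnorm pt p.adjust
NULL

#' One-sided p-value for positive correlation via Fisher's Z transform
#'
#' Transforms a Pearson correlation to \eqn{z = \mathrm{atanh}(r)\sqrt{n-3}},
#' approximately standard normal under the null of zero correlation, and
#' returns the upper-tail probability \eqn{1 - \Phi(z)} testing \eqn{r > 0}.
#' Negative correlations therefore give p > 0.5 and can never be retained at
#' conventional thresholds.
#'
#' @param r Pearson correlation(s); values with \code{|r| >= 1} are clamped to
#'   \code{1 - 1e-12} in magnitude with a warning.
#' @param nSamples number of samples the correlation was computed on; must
#'   exceed 3.
#' @return one-sided p-value(s) in (0, 1). Vectorised over \code{r}.
#' @examples
#' fisherZPositiveP(0.5, 28)  # about 0.003
#' @export
fisherZPositiveP <- function(r, nSamples) {
  if (any(nSamples <= 3)) stop("Fisher's Z requires more than 3 samples")
  if (any(abs(r) >= 1)) {
    warning("|r| >= 1 clamped for the Z transform")
    r <- sign(r) * pmin(abs(r), 1 - 1e-12)
  }
  z <- atanh(r) * sqrt(nSamples - 3)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Filter a competing network by positive co-expression
#'
#' Scores every retained candidate pair on the expression matrix with the
#' Pearson correlation over the selected samples and keeps pairs that reach a
#' significant positive threshold: \code{r > 0} with a two-sided Fisher-Z
#' \code{p < alpha} (so a null pair is retained with probability
#' \code{alpha / 2}). Pairs with either endpoint absent from the matrix, or
#' with a zero-variance profile, are dropped (counted in the attributes
#' \code{nMissing} / \code{nZeroVar} of the result).
#'
#' @param network a [CeRNANetwork-class].
#' @param expr a \linkS4class{SummarizedExperiment} from [readExpression()] /
#'   [simulateExpression()].
#' @param alpha one-sided significance threshold.
#' @param samples \code{"all"} pools both groups (default); \code{"case"}
#'   restricts to case samples.
#' @return data.frame of retained co-expression edges with columns
#'   \code{lncrna}, \code{mrna}, \code{r}, \code{nSamples}, \code{p}.
#' @export
filterByCoexpression <- function(network, expr, alpha = 0.05,
                                 samples = c("all", "case")) {
  stopifnot(is(network, "CeRNANetwork"))
  validateExpression(expr)
  samples <- match.arg(samples)
  pairs <- retainedPairs(network)
  keepCols <- if (samples == "case")
    SummarizedExperiment::colData(expr)$group == "case" else
    rep(TRUE, ncol(expr))
  X <- SummarizedExperiment::assay(expr, "expr")[, keepCols, drop = FALSE]
  n <- ncol(X)
  if (n <= 3) stop("need more than 3 samples for the co-expression test")

  empty <- data.frame(lncrna = character(), mrna = character(),
                      r = numeric(), nSamples = integer(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)

  present <- pairs$lncrna %in% rownames(X) & pairs$mrna %in% rownames(X)
  nMissing <- sum(!present)
  if (nMissing)
    message(nMissing, " pair(s) dropped: endpoint absent from the matrix")
  pairs <- pairs[present, , drop = FALSE]
  if (!nrow(pairs)) {
    attr(empty, "nMissing") <- nMissing
    attr(empty, "nZeroVar") <- 0L
    return(empty)
  }

  feats <- unique(c(pairs$lncrna, pairs$mrna))
  Z <- X[feats, , drop = FALSE]
  mu <- rowMeans(Z)
  Zc <- Z - mu
  ss <- sqrt(rowSums(Zc^2))
  zeroVar <- ss == 0
  Zs <- Zc / ifelse(ss == 0, 1, ss)  # unit-norm centered profiles
  okVar <- !(zeroVar[pairs$lncrna] | zeroVar[pairs$mrna])
  nZeroVar <- sum(!okVar)
  if (nZeroVar)
    warning(nZeroVar, " pair(s) dropped: zero-variance profile")
  pairs <- pairs[okVar, , drop = FALSE]
  if (!nrow(pairs)) {
    attr(empty, "nMissing") <- nMissing
    attr(empty, "nZeroVar") <- nZeroVar
    return(empty)
  }
  r <- rowSums(Zs[pairs$lncrna, , drop = FALSE] *
               Zs[pairs$mrna, , drop = FALSE])
  r <- pmin(pmax(r, -1), 1)
  # two-sided Fisher-Z p restricted to positive r: a null pair passes with
  # probability alpha/2, the calibration of the positive-only rule
  p <- 2 * fisherZPositiveP(abs(r), n)
  keep <- r > 0 & p < alpha
  out <- data.frame(lncrna = pairs$lncrna[keep], mrna = pairs$mrna[keep],
                    r = r[keep], nSamples = n, p = p[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "nMissing") <- nMissing
  attr(out, "nZeroVar") <- nZeroVar
  out
}

#' Embed co-expressed lncRNAs into a pathway graph
#'
#' For each retained co-expression edge whose mRNA is a node of this pathway,
#' the lncRNA is added as a node (once) and linked to the mRNA by an
#' undirected regulation edge, yielding the condition-specific
#' lncRNA-regulated signal pathway (LRSP). Pathways gaining no lncRNA are
#' still returned with an empty embedding; the base gene-gene edges are never
#' modified.
#'
#' @param pathway a [PathwayGraph-class].
#' @param retainedEdges data.frame from [filterByCoexpression()].
#' @return An [LRSPGraph-class].
#' @export
buildLRSP <- function(pathway, retainedEdges) {
  stopifnot(is(pathway, "PathwayGraph"))
  genes <- pathwayNodes(pathway)
  re <- retainedEdges[retainedEdges$mrna %in% genes, , drop = FALSE]
  re <- re[!duplicated(re[, c("lncrna", "mrna")]), , drop = FALSE]
  rownames(re) <- NULL
  g <- pathway@graph
  g <- igraph::set_vertex_attr(g, "nodeType", value = "gene")
  lnc <- unique(re$lncrna)
  if (length(lnc)) {
    if (length(intersect(lnc, genes)))
      stop("lncRNA ID collides with a pathway gene ID: ",
           paste(intersect(lnc, genes), collapse = ", "))
    g <- igraph::add_vertices(g, length(lnc), name = lnc,
                              nodeType = "lncRNA")
    g <- igraph::add_edges(g, rbind(re$lncrna, re$mrna))
  }
  new("LRSPGraph", pathwayId = pathway@pathwayId, base = pathway,
      graph = g,
      regulationEdges = re[, c("lncrna", "mrna", "r", "nSamples", "p"),
                           drop = FALSE])
}

#' Differentially expressed mRNAs by Student's t-test
#'
#' Convenience stage producing the "interesting gene" signature from the
#' expression matrix: a per-mRNA equal-variance two-sample t-test between
#' case and control samples, Benjamini-Hochberg correction, and selection at
#' \code{FDR < fdrThreshold}. A user-supplied gene list can be used instead of
#' this stage anywhere a signature is expected.
#'
#' @param expr a \linkS4class{SummarizedExperiment}.
#' @param fdrThreshold FDR selection threshold.
#' @return character vector of selected mRNA IDs, with the full per-gene
#'   table (\code{gene}, \code{t}, \code{pvalue}, \code{fdr}) in attribute
#'   \code{"table"}.
#' @export
computeInterestingGenes <- function(expr, fdrThreshold = 0.1) {
  validateExpression(expr)
  grp <- SummarizedExperiment::colData(expr)$group
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L)
    stop("both groups need at least 2 samples for the t-test")
  isM <- SummarizedExperiment::rowData(expr)$featureClass == "mRNA"
  X <- SummarizedExperiment::assay(expr, "expr")[isM, , drop = FALSE]
  x1 <- X[, grp == "case", drop = FALSE]
  x2 <- X[, grp == "control", drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se == 0, 0, (m1 - m2) / se)
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0] <- 1  # identical groups: no evidence
  fdr <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(X), t = tstat, pvalue = p, fdr = fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  sel <- tab$gene[tab$fdr < fdrThreshold]
  attr(sel, "table") <- tab
  sel
}
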