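#' @importFrom stats phyper quantile setNames
NULL

#' Upper-tail hypergeometric p-value for shared miRNAs
#'
#' Tests whether a lncRNA and an mRNA share more miRNA partners than expected
#' by chance. With a background universe of \code{N} miRNAs of which the mRNA
#' interacts with \code{K} and the lncRNA with \code{M}, the overlap under the
#' null is hypergeometric; the returned value is the inclusive upper tail
#' \eqn{P(X \ge shared)}. \code{shared = 0} always gives 1.
#'
#' @param shared observed number of shared miRNAs.
#' @param K number of miRNA partners of the mRNA.
#' @param M number of miRNA partners of the lncRNA.
#' @param N size of the miRNA universe.
#' @return p-value in (0, 1]. Vectorised over all arguments.
#' @examples
#' sharedMirnaHypergeomP(2, 4, 4, 10)   # 115/210
#' @export
sharedMirnaHypergeomP <- function(shared, K, M, N) {
  if (any(K > N | M > N))
    stop("K and M must not exceed the universe size N")
  if (any(shared > pmin(K, M)) || any(shared < 0))
    stop("'shared' must lie in [0, min(K, M)]")
  # P(X >= shared) with X ~ Hypergeometric(N, K, M)
  stats::phyper(shared - 1L, K, N - K, M, lower.tail = FALSE)
}

#' Jaccard coefficient of two partner sets from overlap counts
#'
#' @param shared size of the intersection.
#' @param K,M sizes of the two sets.
#' @return \code{shared / (K + M - shared)}, in [0, 1]. Vectorised.
#' @examples
#' jaccardCoefficient(2, 4, 4)  # 1/3
#' @export
jaccardCoefficient <- function(shared, K, M) {
  if (any(K + M - shared <= 0))
    stop("empty union: K + M - shared must be positive")
  if (any(shared > pmin(K, M)) || any(shared < 0))
    stop("'shared' must lie in [0, min(K, M)]")
  shared / (K + M - shared)
}

#' Build the candidate lncRNA-mRNA competing network
#'
#' Every (lncRNA, mRNA) pair sharing at least one miRNA is a candidate. A
#' candidate is retained when it satisfies both criteria: (i) the shared-miRNA
#' hypergeometric p-value is below \code{hypergAlpha} (strict), and (ii) its
#' Jaccard coefficient ranks in the top \code{jaccardTopFraction} of all
#' candidates (inclusive of ties at the cutoff quantile, so the result does
#' not depend on input order). The Jaccard ranking scope is global over all
#' candidate pairs by default; \code{jaccardScope = "perLncrna"} ranks within
#' each lncRNA's own candidates instead.
#'
#' @param catalog an [InteractionCatalog-class].
#' @param hypergAlpha significance threshold of the hypergeometric filter.
#' @param jaccardTopFraction fraction of top-ranking Jaccard coefficients
#'   retained.
#' @param jaccardScope \code{"global"} or \code{"perLncrna"}.
#' @return A [CeRNANetwork-class]. When no pair shares a miRNA an empty
#'   network is returned with a warning.
#' @export
buildCandidateNetwork <- function(catalog, hypergAlpha = 0.05,
                                  jaccardTopFraction = 0.20,
                                  jaccardScope = c("global", "perLncrna")) {
  stopifnot(is(catalog, "InteractionCatalog"))
  jaccardScope <- match.arg(jaccardScope)
  if (!length(catalog@lncTargets) || !length(catalog@mrnaTargets))
    stop("catalog must contain both lncRNA and mRNA target sets")
  N <- length(catalog@mirnaUniverse)

  # overlap counts via a sparse incidence product would be overkill at the
  # catalog sizes this method sees; a dense logical incidence works fine
  mir <- catalog@mirnaUniverse
  lncInc <- vapply(catalog@lncTargets, function(s) mir %in% s,
                   logical(length(mir)))
  mrnaInc <- vapply(catalog@mrnaTargets, function(s) mir %in% s,
                    logical(length(mir)))
  sharedMat <- crossprod(lncInc, mrnaInc)  # lnc x mrna overlap counts
  Mv <- colSums(lncInc)
  Kv <- colSums(mrnaInc)

  idx <- which(sharedMat >= 1L, arr.ind = TRUE)
  if (!nrow(idx)) {
    warning("no lncRNA-mRNA pair shares any miRNA; returning empty network")
    empty <- as.data.frame(setNames(
      list(character(), character(), integer(), integer(), integer(),
           integer(), numeric(), numeric(), logical(), logical()),
      .PAIR_COLS))
    return(new("CeRNANetwork", candidates = empty, pairs = empty,
               jaccardCutoff = NA_real_))
  }
  cand <- data.frame(
    lncrna = names(catalog@lncTargets)[idx[, 1]],
    mrna = names(catalog@mrnaTargets)[idx[, 2]],
    shared = as.integer(sharedMat[idx]),
    K = as.integer(Kv[idx[, 2]]),
    M = as.integer(Mv[idx[, 1]]),
    N = N,
    stringsAsFactors = FALSE)
  cand$hypergP <- sharedMirnaHypergeomP(cand$shared, cand$K, cand$M, cand$N)
  cand$jaccard <- jaccardCoefficient(cand$shared, cand$K, cand$M)
  cand$passedHyperg <- cand$hypergP < hypergAlpha
  # "rank at top f": cutoff is the ceiling(f * n)-th largest Jaccard value;
  # every pair at or above it is kept, so ties at the cutoff are inclusive
  # and the result cannot depend on input order
  topCut <- function(j, f) {
    k <- max(1L, as.integer(ceiling(f * length(j))))
    sort(j, decreasing = TRUE)[k]
  }
  if (jaccardScope == "global") {
    cutoff <- topCut(cand$jaccard, jaccardTopFraction)
    cand$passedJaccard <- cand$jaccard >= cutoff
  } else {
    cutoff <- NA_real_
    sp <- split(cand$jaccard, cand$lncrna)
    cuts <- vapply(sp, topCut, numeric(1), f = jaccardTopFraction)
    cand$passedJaccard <- cand$jaccard >= cuts[cand$lncrna]
  }
  ord <- order(cand$lncrna, cand$mrna)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  pairs <- cand[cand$passedHyperg & cand$passedJaccard, , drop = FALSE]
  rownames(pairs) <- NULL
  new("CeRNANetwork", candidates = cand, pairs = pairs,
      jaccardCutoff = unname(cutoff))
}

#' Write a competing network as TSV
#'
#' @param network a [CeRNANetwork-class].
#' @param path output path.
#' @param all write all scored candidates instead of only retained pairs.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path, all = FALSE) {
  df <- retainedPairs(network, all = all)
  out <- df[, c("lncrna", "mrna", "shared", "K", "M", "N", "hypergP",
                "jaccard")]
  names(out) <- c("lncrna_id", "mrna_id", "shared", "K", "M", "N",
                  "hyperg_p", "jaccard")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
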