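# Independent oracles used to validate the package's statistics and the
# subpathway locator. These deliberately avoid the code paths they check:
# brute-force enumeration instead of phyper / the urn recursion, hand-rolled
# BFS + union-find instead of igraph.

# Upper-tail shared-miRNA probability by exhaustive draw-set enumeration:
# the mRNA's K miRNAs are items 1..K of a universe 1..N; enumerate all
# C(N, M) possible lncRNA partner sets and count those overlapping 1..K in
# at least `shared` items.
hypergTailOracle <- function(shared, K, M, N) {
  if (shared == 0) return(1)
  sets <- utils::combn(N, M)
  mean(colSums(sets <= K) >= shared)
}

# Wallenius pmf by exhaustive enumeration of all ordered draw sequences:
# every sequence of x draws contributes the product of its per-step removal
# probabilities (weight of the drawn ball over total remaining weight),
# aggregated by the number of weighted ("red") balls drawn.
walleniusEnumOracle <- function(n, m1, x, w) {
  pmf <- numeric(x + 1)
  rec <- function(reds, whites, drawn, k, prob) {
    if (drawn == x) {
      pmf[k + 1] <<- pmf[k + 1] + prob
      return(invisible(NULL))
    }
    tot <- w * reds + whites
    if (reds > 0) rec(reds - 1, whites, drawn + 1, k + 1, prob * w * reds / tot)
    if (whites > 0) rec(reds, whites - 1, drawn + 1, k, prob * whites / tot)
  }
  rec(m1, n - m1, 0, 0, 1)
  pmf
}

# ---- locator oracle ---------------------------------------------------------

# adjacency list (integer indices) from a character edge matrix
.adjList <- function(nodes, edges) {
  adj <- vector("list", length(nodes))
  idx <- seq_along(nodes)
  names(idx) <- nodes
  for (i in seq_len(nrow(edges))) {
    a <- idx[[edges[i, 1]]]; b <- idx[[edges[i, 2]]]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

.bfsDist <- function(adj, src) {
  d <- rep(Inf, length(adj))
  d[src] <- 0
  queue <- src
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!is.finite(d[nb])) {
        d[nb] <- d[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  d
}

# all nodes on at least one shortest u-v path, by depth-first enumeration
.allShortestPathNodes <- function(adj, dmat, u, v) {
  acc <- integer(0)
  rec <- function(cur, path) {
    if (cur == v) {
      acc <<- union(acc, path)
      return(invisible(NULL))
    }
    for (nb in adj[[cur]])
      if (dmat[nb, v] == dmat[cur, v] - 1) rec(nb, c(path, nb))
  }
  rec(u, u)
  acc
}

.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Reference subpathway location: all-pairs BFS distances, union-find merging
# of signature pairs with <= n intermediates, exhaustive shortest-path
# enumeration for linker inclusion. Returns a list of regions, each a list
# with sorted member names and signature names; filtered by size s and the
# at-least-one-lncRNA rule, unordered.
locatorOracle <- function(nodes, edges, isLnc, sigNodes, n, s) {
  adj <- .adjList(nodes, edges)
  nn <- length(nodes)
  dmat <- vapply(seq_len(nn), function(src) .bfsDist(adj, src),
                 numeric(nn))  # dmat[dest, src], symmetric
  sig <- match(sigNodes, nodes)
  parent <- seq_len(nn)
  linkedPairs <- list()
  if (length(sig) > 1) {
    for (i in seq_len(length(sig) - 1)) {
      for (j in (i + 1):length(sig)) {
        u <- sig[i]; v <- sig[j]
        if (is.finite(dmat[u, v]) && dmat[u, v] - 1 <= n) {
          linkedPairs[[length(linkedPairs) + 1]] <- c(u, v)
          ru <- .ufFind(parent, u); rv <- .ufFind(parent, v)
          if (ru != rv) parent[ru] <- rv
        }
      }
    }
  }
  roots <- vapply(sig, function(i) .ufFind(parent, i), integer(1))
  regions <- lapply(unique(roots), function(rt) {
    cs <- sig[roots == rt]
    members <- cs
    for (pr in linkedPairs) {
      if (.ufFind(parent, pr[1]) == rt)
        members <- union(members,
                         .allShortestPathNodes(adj, dmat, pr[1], pr[2]))
    }
    list(nodes = sort(nodes[members]), sig = sort(nodes[cs]))
  })
  keep <- vapply(regions, function(rg)
    length(rg$nodes) >= s && any(isLnc[rg$nodes]), logical(1))
  regions[keep]
}

# canonical string form of a region list for set comparison
regionKey <- function(regions) {
  sort(vapply(regions, function(rg)
    paste(paste(rg$nodes, collapse = ","), "|",
          paste(rg$sig, collapse = ",")), character(1)))
}
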