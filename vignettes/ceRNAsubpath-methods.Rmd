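---
title: "Methods: locating lncRNA-competitively-regulated signal subpathways"
author: "ceRNAsubpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating lncRNA-competitively-regulated signal subpathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAsubpath)
```

# The model

Competing endogenous RNA (ceRNA) regulation rests on shared miRNA binding:
a lncRNA that binds the same miRNAs as an mRNA can titrate those miRNAs away
and thereby raise the mRNA's abundance. Two observable consequences drive
this package's inference: competing pairs share *more* miRNA partners than
chance predicts, and — because titration de-represses the target — their
expression is *positively* correlated across samples. Neither signal alone
is trustworthy (shared-miRNA catalogs are noisy; correlation has countless
non-ceRNA causes), so the pipeline demands both, then asks *where in the
pathway map* the surviving regulation concentrates, and finally asks whether
that concentration is larger than a weighted-sampling null allows.

The four stages and their assumptions:

1. **Shared-miRNA evidence.** For a universe of $N$ miRNAs, an mRNA with
   $K$ partners, a lncRNA with $M$, and overlap $s$, the null is that the
   two partner sets are independent uniform draws, giving the upper tail
   $P(X \ge s)$, $X \sim \mathrm{Hypergeom}(N, K, M)$. The Jaccard
   coefficient $s/(K+M-s)$ measures the *strength* of overlap; requiring it
   to rank in the top 20% of all candidate pairs guards against pairs that
   are significant only because their partner sets are huge.
2. **Positive co-expression.** Pearson $r$ over samples, tested through
   Fisher's Z, $z=\operatorname{atanh}(r)\sqrt{n-3}$, approximately standard
   normal under independence for roughly Gaussian profiles. Retention
   demands $r>0$ with two-sided $p<\alpha$; a null pair therefore survives
   with probability $\alpha/2$ (0.025 at the default $\alpha=0.05$). This is
   the calibration of the usual "significant positive correlation" rule
   (two-sided test, positive sign), and the package's tests verify it
   empirically on 10,000 null pairs. The one-sided upper-tail
   $1-\Phi(z)$ is exported as `fisherZPositiveP()` for direct use.
3. **Lenient-distance subpathway location.** Embedded lncRNAs and
   interesting genes are *signature nodes*. Two signature nodes merge when
   at most $n$ molecules separate them on a shortest path of the LRSP
   (distance $\le n+1$); merging is transitive. The merged region keeps
   every node on *any* shortest path between a linked pair — disease signal
   travels through non-differential linker genes, and keeping all shortest
   paths (rather than one arbitrary one) makes the output deterministic.
   Regions need at least $s$ molecules and at least one lncRNA.
4. **Weighted biased-urn significance.** Pathway-membership tests are
   biased when some genes are more likely to be "interesting" a priori;
   here the bias of interest is competing regulation itself. A subpathway
   with $P_G$ member mRNAs, $G_L$ of them regulated by member lncRNAs, gets
   odds weight $W = 1+\beta(-\log_2(G_L/P_G))$ and is scored by the
   Wallenius noncentral hypergeometric upper tail: drawing the $x$
   interesting mRNAs sequentially from the $n$ background mRNAs, subpathway
   members are drawn with odds $W$ : 1. At $\beta=0$ (or $G_L=P_G$) the
   test reduces exactly to the central hypergeometric.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `hypergAlpha` | 0.05 | shared-miRNA significance threshold (strict `<`) |
| `jaccardTopFraction` | 0.20 | fraction of top-ranking Jaccard values kept |
| `coexprAlpha` | 0.05 | two-sided positive co-expression threshold |
| `n` | 1 | max molecules between merged signature nodes |
| `s` | 8 | minimum subpathway size, in molecules |
| `beta` | 1 | weight control; 0 disables the bias entirely |
| `deFdr` | 0.1 | BH threshold of the t-test "interesting gene" stage |
| `fdrThreshold` | 0.01 | BH threshold for reporting significance |

`n` and `s` trade sensitivity against interpretability: larger `n` merges
more distant signal and larger `s` discards small fragments. The defaults
(1 and 8) are the method's standard operating point. All thresholds are
plain probabilities; expression units are arbitrary (RPKM, normalized
intensities, ...) as only correlations, t statistics and ranks are used.

# Design choices where the method is under-determined

* **Hypergeometric universe $N$.** Defined as the union of all miRNAs in
  both catalogs — the only background derivable from the inputs alone.
  `interactionCatalog(mirnaUniverse =)` overrides it.
* **Jaccard "top 20%" scope and ties.** Ranked globally over all candidate
  pairs; the cutoff is the `ceiling(0.2 * n)`-th largest value and ties at
  the cutoff are kept, so results cannot depend on input order. A
  per-lncRNA ranking mode is available (`jaccardScope = "perLncrna"`).
* **Correlation sample scope.** Both groups pooled by default (the matched
  profiles are used as one cohort); `samples = "case"` restricts to case
  samples for condition-specific networks.
* **Positive-only rule.** Implemented as $r>0$ with two-sided $p<\alpha$
  (null retention $\alpha/2$), the conventional reading of "significant
  positive threshold"; see stage 2 above.
* **Counting molecules.** "Molecules between" two signature nodes means
  intermediate nodes, so the merge condition is $d(u,v) \le n+1$ in edges.
  lncRNA regulation edges count like gene-gene edges — two genes may merge
  through a shared lncRNA regulator — and lncRNAs count toward `s`.
* **$G_L$ membership.** Only regulation edges from *member* lncRNAs to
  member mRNAs count; regulation from LRSP lncRNAs outside the subpathway
  does not inflate the weight.
* **Urn background.** Default: union of all pathway genes intersected with
  the expressed mRNAs (`backgroundMode = "expression"`); the unrestricted
  pathway-gene union is available. Only mRNAs enter the urn — all five urn
  parameters are mRNA counts; lncRNAs act through $G_L$ and $W$.
* **Subpathways without lncRNAs** are discarded by the locator: the weight
  needs $G_L \ge 1$, and a region without competing regulation is not the
  object of this method.
* **FDR.** Benjamini–Hochberg throughout (`bhFdr()`, a validated front over
  `stats::p.adjust`).
* **Interface.** The package is driven from R — `runPipeline()` /
  `runRobustness()` over a `pipelineConfig()` — mirroring how its users
  script analyses; per-stage writers/readers make every stage resumable
  from its TSV artifacts.

# Numerical choices

* **Wallenius tail.** Computed by an exact forward recursion over the
  biased-urn draw states, implemented in C++: after $j$ draws with $k$
  weighted balls removed, the next draw is weighted with probability
  $w(m_1-k)\,/\,(w(m_1-k) + (n-m_1-(j-k)))$. The draw-count pair is a
  Markov state, so this recursion *is* the distribution — no quadrature, no
  saddlepoint approximation, no Monte-Carlo. The test suite verifies
  agreement with an exhaustive ordered-draw enumeration oracle on all urns
  with $n \le 12$ (four weights) and with the central hypergeometric tail
  on all urns with $n \le 60$ at $w=1$ (observed worst error ~3e-15).
* **Correlations** are computed from unit-normalized centered profiles and
  clamped to $[-1, 1]$; $|r| \ge 1$ is clamped to $1-10^{-12}$ before the Z
  transform (with a warning), and zero-variance profiles drop the pair
  rather than failing the run.
* **Tie-breaks.** Subpathway numbering is by decreasing node count, then
  lexicographically smallest member ID; result rows sort by FDR then p.
  Both make equal-input runs byte-identical.
* **Degenerate inputs.** No shared miRNA anywhere → empty network with a
  warning; a pathway gaining no lncRNA is still a valid (empty-embedding)
  LRSP; zero located subpathways → header-only results table and a normal
  exit; a subpathway with no background mRNA, or no regulated member gene,
  is skipped with a warning; $m_2=0$ returns tail exactly 1.

# The synthetic generator

`simulateScenario()` builds the study the test-suite conditions use: 200
mRNAs partitioned into 8 connected pathway graphs of 25 genes (random tree
plus Bernoulli(0.15) extra edges), 40 lncRNAs, a 100-miRNA universe with 10
baseline partners per RNA, 5 planted competing pairs sharing 15 extra
miRNAs each, 100+100 samples of Gaussian expression (mean 5, sd 1), planted
pairs driven by a shared latent factor to Pearson $r \approx 0.8$, and a
10-gene connected region of one pathway carrying a +2 case-group shift and
the planted pairs' regulated mRNAs. Baseline partner count, planted
overlap, noise level and graph density were fixed once at values a
practitioner would call realistic for curated catalogs (overlap far above
the background expectation of ~1 shared miRNA) and are not tuned
thereafter.

The generator emulates the *statistical* structure the method assumes —
overlap enrichment, positive co-expression, spatially concentrated
differential expression — and deliberately not the properties of real
RNA-seq: no counts, no library-size or GC effects, no correlated background
co-expression, no scale-free degree distributions, no batch structure.
Passing tests therefore demonstrate that the algorithms do what they claim
under their own model, not that the biological discoveries on any real
cohort would replicate.

Smaller variants of the same scenario (4 pathways × 15 genes, 30+30
samples) drive the fast unit tests; the full scenario above is used for the
end-to-end recovery (50 seeds) and robustness (20 replicates per deletion
fraction, 5%–30%) checks.

# Robustness harness

`runRobustness()` repeats the analysis after deleting a random fraction of
expression features (both RNA classes pooled) or of LRSP edges (gene-gene
and regulation edges pooled), and reports the mean recall of the reference
run's significant pathways — complete-pathway identity, FDR < 0.01 —
across replicates. Deletion counts use `floor(fraction × size)` so runs are
exactly reproducible from the seed.

# Known limitations

* Interaction catalogs are taken as given; no target prediction, CLIP
  filtering or ID mapping is attempted, and IDs are opaque case-sensitive
  strings — the caller must harmonize ID spaces across inputs.
* The differential-expression stage is a plain equal-variance t-test with
  BH; count-based models are out of scope (supply your own gene list for
  count data).
* Pathway graphs are undirected and unsigned; activation/inhibition
  semantics and edge types are discarded at conversion.
* Pearson correlation captures linear co-expression only, and the pooled
  default can pick up group-driven correlation when both members are
  differential; use `samples = "case"` when that is a concern.
* The Wallenius recursion is exact but $O(x \cdot m_1)$ per tail; for the
  genome-scale urns of this method (thousands of background genes) that is
  milliseconds, but it is not meant for urns with millions of draws.
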