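Package: ceRNAsubpath
Title: Identification of Signal Subpathways Competitively Regulated by
    lncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies signal subpathways competitively regulated by long
    noncoding RNAs (lncRNAs) acting as competing endogenous RNAs. A candidate
    lncRNA-mRNA competing network is built from shared-miRNA evidence using a
    dual hypergeometric / Jaccard filter, pruned to significantly positively
    co-expressed pairs by Fisher's Z transform of the Pearson correlation, and
    the surviving lncRNAs are embedded into KEGG-style pathway graphs. Within
    each lncRNA-regulated signal pathway (LRSP), subpathways are located by
    lenient-distance merging of signature nodes and scored with a weighted
    Wallenius noncentral hypergeometric test, with Benjamini-Hochberg FDR
    control. Includes a synthetic-data generator with planted ground truth
    and a robustness harness based on random deletion of features or edges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
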