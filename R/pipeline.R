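#' @importFrom jsonlite write_json
NULL

#' Assemble a pipeline configuration
#'
#' Inputs may be given as in-memory objects (\code{catalog}, \code{pathways},
#' \code{expr}, \code{interestingGenes}) or as file paths read through the
#' package readers; objects win when both are present. Threshold defaults are
#' the method's: hypergeometric p < 0.05 and Jaccard top 20% for the
#' candidate network, one-sided co-expression p < 0.05, lenient-distance
#' parameters n = 1 and s = 8, weight control beta = 1, differential
#' expression at FDR < 0.1, and significance reporting at FDR < 0.01.
#'
#' @param catalog [InteractionCatalog-class], or NULL to read from paths.
#' @param lncCatalogPath,mrnaCatalogPath catalog files for
#'   [readInteractionCatalog()].
#' @param pathways list of [PathwayGraph-class], or NULL.
#' @param pathwayPaths character vector of edge-list files for
#'   [readPathwayEdgelist()].
#' @param expr \linkS4class{SummarizedExperiment}, or NULL.
#' @param matrixPath,groupsPath,classesPath,lncPattern arguments of
#'   [readExpression()].
#' @param interestingGenes character vector, or NULL to run the t-test stage.
#' @param interestingGenesPath one-ID-per-line file alternative.
#' @param hypergAlpha,jaccardTopFraction candidate-network thresholds.
#' @param coexprAlpha co-expression threshold.
#' @param n,s lenient-distance merging parameters.
#' @param beta weight control parameter.
#' @param deFdr differential-expression FDR threshold.
#' @param backgroundMode \code{"expression"} (pathway genes intersected with
#'   expressed mRNAs) or \code{"pathways"} (all pathway genes).
#' @param fdrThreshold FDR threshold defining significant subpathways.
#' @param samples correlation sample scope, \code{"all"} or \code{"case"}.
#' @param outputDir optional directory for the stage TSVs and run manifest.
#' @param seed optional integer echoed into the manifest (the pipeline itself
#'   is deterministic).
#' @return a \code{list} of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(catalog = NULL, lncCatalogPath = NULL,
                           mrnaCatalogPath = NULL, pathways = NULL,
                           pathwayPaths = NULL, expr = NULL,
                           matrixPath = NULL, groupsPath = NULL,
                           classesPath = NULL, lncPattern = NULL,
                           interestingGenes = NULL,
                           interestingGenesPath = NULL,
                           hypergAlpha = 0.05, jaccardTopFraction = 0.20,
                           coexprAlpha = 0.05, n = 1L, s = 8L, beta = 1,
                           deFdr = 0.1,
                           backgroundMode = c("expression", "pathways"),
                           fdrThreshold = 0.01,
                           samples = c("all", "case"), outputDir = NULL,
                           seed = NULL) {
  stopifnot(hypergAlpha > 0, hypergAlpha <= 1,
            jaccardTopFraction > 0, jaccardTopFraction <= 1,
            coexprAlpha > 0, coexprAlpha <= 1,
            deFdr > 0, deFdr <= 1, fdrThreshold > 0, fdrThreshold <= 1,
            n >= 0, s >= 1, beta >= 0)
  structure(list(
    catalog = catalog, lncCatalogPath = lncCatalogPath,
    mrnaCatalogPath = mrnaCatalogPath, pathways = pathways,
    pathwayPaths = pathwayPaths, expr = expr, matrixPath = matrixPath,
    groupsPath = groupsPath, classesPath = classesPath,
    lncPattern = lncPattern, interestingGenes = interestingGenes,
    interestingGenesPath = interestingGenesPath,
    hypergAlpha = hypergAlpha, jaccardTopFraction = jaccardTopFraction,
    coexprAlpha = coexprAlpha, n = as.integer(n), s = as.integer(s),
    beta = beta, deFdr = deFdr,
    backgroundMode = match.arg(backgroundMode),
    fdrThreshold = fdrThreshold, samples = match.arg(samples),
    outputDir = outputDir, seed = seed), class = "PipelineConfig")
}

.loadInputs <- function(config) {
  fail <- function(stage, msg) stop("[", stage, "] ", msg, call. = FALSE)
  catalog <- config$catalog
  if (is.null(catalog)) {
    for (p in c(config$lncCatalogPath, config$mrnaCatalogPath))
      if (!file.exists(p)) fail("inputs", paste("missing input file:", p))
    catalog <- interactionCatalog(
      readInteractionCatalog(config$lncCatalogPath),
      readInteractionCatalog(config$mrnaCatalogPath))
  }
  pathways <- config$pathways
  if (is.null(pathways)) {
    for (p in config$pathwayPaths)
      if (!file.exists(p)) fail("inputs", paste("missing input file:", p))
    pathways <- lapply(config$pathwayPaths, readPathwayEdgelist)
  }
  expr <- config$expr
  if (is.null(expr)) {
    for (p in c(config$matrixPath, config$groupsPath))
      if (!file.exists(p)) fail("inputs", paste("missing input file:", p))
    expr <- readExpression(config$matrixPath, config$groupsPath,
                           config$classesPath, config$lncPattern)
  }
  interesting <- config$interestingGenes
  if (is.null(interesting) && !is.null(config$interestingGenesPath)) {
    if (!file.exists(config$interestingGenesPath))
      fail("inputs", paste("missing input file:",
                           config$interestingGenesPath))
    interesting <- readLines(config$interestingGenesPath, warn = FALSE)
    interesting <- interesting[nzchar(interesting)]
  }
  list(catalog = catalog, pathways = pathways, expr = expr,
       interestingGenes = interesting)
}

#' Run the full subpathway identification pipeline
#'
#' Executes the four stages in order: candidate competing network from shared
#' miRNAs, positive co-expression filter plus lncRNA embedding into each
#' pathway (LRSP construction), signature mapping and lenient-distance
#' subpathway location, and weighted biased-urn scoring with BH correction.
#' When \code{config$outputDir} is set, writes \code{network.tsv},
#' \code{coexpression_edges.tsv}, \code{subpathways.tsv},
#' \code{results.tsv} and a JSON \code{manifest.json} with the configuration
#' echo and per-stage counts. Zero significant subpathways is a normal
#' outcome, not an error.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list with \code{results} (the enrichment
#'   data.frame), \code{network}, \code{edges}, \code{lrsps},
#'   \code{subpathways}, \code{interestingGenes}, \code{background},
#'   \code{significantPathways} (complete-pathway IDs at
#'   \code{fdrThreshold}) and \code{counts}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  inputs <- .loadInputs(config)

  network <- stage("build-network",
    buildCandidateNetwork(inputs$catalog, config$hypergAlpha,
                          config$jaccardTopFraction))
  edges <- stage("coexpr-filter",
    filterByCoexpression(network, inputs$expr, config$coexprAlpha,
                         config$samples))
  lrsps <- stage("build-lrsp",
    lapply(inputs$pathways, buildLRSP, retainedEdges = edges))
  names(lrsps) <- vapply(lrsps, pathwayId, character(1))
  interesting <- inputs$interestingGenes
  if (is.null(interesting))
    interesting <- stage("de", computeInterestingGenes(inputs$expr,
                                                       config$deFdr))
  subpathways <- stage("locate",
    unlist(lapply(lrsps, locateSubpathways,
                  interestingGenes = interesting,
                  n = config$n, s = config$s),
           recursive = FALSE, use.names = FALSE))
  background <- backgroundMrnas(
    inputs$pathways, expr = inputs$expr,
    restrictToExpression = config$backgroundMode == "expression")
  results <- stage("enrich",
    suppressMessages(evaluateSubpathways(subpathways, lrsps, interesting,
                                         background, config$beta)))
  sigPathways <- sort(unique(results$pathway_id[
    results$fdr < config$fdrThreshold]))
  counts <- list(
    candidatePairs = nrow(retainedPairs(network, all = TRUE)),
    retainedPairs = nrow(retainedPairs(network)),
    coexpressionEdges = nrow(edges),
    interestingGenes = length(interesting),
    lrspsWithLncrna = sum(vapply(lrsps, function(l)
      length(lncrnaNodes(l)) > 0, logical(1))),
    subpathways = length(subpathways),
    scored = nrow(results),
    significant = sum(results$fdr < config$fdrThreshold))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$outputDir, f)
    writeNetwork(network, o("network.tsv"))
    writeCoexpressionEdges(edges, o("coexpression_edges.tsv"))
    writeLines(as.character(interesting), o("interesting_genes.txt"))
    writeSubpathways(subpathways, o("subpathways.tsv"))
    writeResults(results, o("results.tsv"))
    manifest <- list(
      package = "ceRNAsubpath",
      version = as.character(utils::packageVersion("ceRNAsubpath")),
      config = config[!vapply(config, is.null, logical(1)) &
                      !names(config) %in% c("catalog", "pathways", "expr",
                                            "interestingGenes")],
      counts = counts,
      significantPathways = sigPathways,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, force = TRUE)
  }
  invisible(list(results = results, network = network, edges = edges,
                 lrsps = lrsps, subpathways = subpathways,
                 interestingGenes = interesting, background = background,
                 significantPathways = sigPathways, counts = counts))
}

#' Write/read the retained co-expression edges TSV
#'
#' @param edges data.frame from [filterByCoexpression()].
#' @param path file path.
#' @return \code{path} (writer) or the edges data.frame (reader).
#' @export
writeCoexpressionEdges <- function(edges, path) {
  out <- edges[, c("lncrna", "mrna", "r", "nSamples", "p")]
  names(out) <- c("lncrna_id", "mrna_id", "r", "n_samples", "p")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCoexpressionEdges
#' @export
readCoexpressionEdges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- c("lncrna", "mrna", "r", "nSamples", "p")
  df$lncrna <- as.character(df$lncrna)
  df$mrna <- as.character(df$mrna)
  df
}

#' Robustness of the significant-pathway set under random deletion
#'
#' Re-runs the analysis on randomly perturbed inputs and measures, for each
#' deletion fraction, the mean recall of the reference run's significant
#' pathways (complete-pathway IDs of subpathways at
#' \code{FDR < fdrThreshold}). In \code{"deleteFeatures"} mode a fraction of
#' expression features (both RNA classes) is deleted and the analysis is
#' repeated from the co-expression stage; in \code{"deleteEdges"} mode a
#' fraction of LRSP edges is deleted and the analysis is repeated from the
#' subpathway-location stage.
#'
#' @param config a [pipelineConfig()]; the reference run is executed from it.
#' @param fractions deletion fractions (default 5\% to 30\% in 5\% steps).
#' @param reps perturbation replicates per fraction.
#' @param mode \code{"deleteFeatures"} or \code{"deleteEdges"}.
#' @param seed integer seed for the perturbation stream.
#' @return data.frame with columns \code{fraction} and \code{meanRecall};
#'   attribute \code{"perRep"} holds the per-replicate recalls. Errors when
#'   the reference run has no significant pathway (recall undefined).
#' @export
runRobustness <- function(config, fractions = seq(0.05, 0.30, by = 0.05),
                          reps = 20,
                          mode = c("deleteFeatures", "deleteEdges"),
                          seed = 1) {
  mode <- match.arg(mode)
  ref <- runPipeline(config)
  sigRef <- ref$significantPathways
  if (!length(sigRef))
    stop("reference run has no significant pathway; recall is undefined")
  inputs <- .loadInputs(config)
  userGenes <- inputs$interestingGenes

  rerun <- function(fraction, repSeed) {
    if (mode == "deleteFeatures") {
      exprP <- perturbForRobustness(inputs$expr, fraction,
                                    "deleteFeatures", seed = repSeed)
      edges <- filterByCoexpression(ref$network, exprP, config$coexprAlpha,
                                    config$samples)
      lrsps <- lapply(inputs$pathways, buildLRSP, retainedEdges = edges)
      names(lrsps) <- vapply(lrsps, pathwayId, character(1))
      interesting <- if (is.null(userGenes))
        computeInterestingGenes(exprP, config$deFdr) else userGenes
      background <- backgroundMrnas(
        inputs$pathways, expr = exprP,
        restrictToExpression = config$backgroundMode == "expression")
    } else {
      lrsps <- perturbForRobustness(ref$lrsps, fraction, "deleteEdges",
                                    seed = repSeed)
      names(lrsps) <- vapply(lrsps, pathwayId, character(1))
      interesting <- ref$interestingGenes
      background <- ref$background
    }
    sps <- unlist(lapply(lrsps, locateSubpathways,
                         interestingGenes = interesting,
                         n = config$n, s = config$s),
                  recursive = FALSE, use.names = FALSE)
    res <- suppressWarnings(suppressMessages(
      evaluateSubpathways(sps, lrsps, interesting, background,
                          config$beta)))
    unique(res$pathway_id[res$fdr < config$fdrThreshold])
  }

  perRep <- do.call(rbind, lapply(seq_along(fractions), function(fi) {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      repSeed <- (as.integer(seed) + 7919L * fi + r) %% .Machine$integer.max
      sigP <- rerun(fractions[fi], repSeed)
      data.frame(fraction = fractions[fi], rep = r,
                 recall = length(intersect(sigP, sigRef)) / length(sigRef))
    }))
  }))
  out <- aggregate(recall ~ fraction, perRep, mean)
  names(out) <- c("fraction", "meanRecall")
  attr(out, "perRep") <- perRep
  out
}
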