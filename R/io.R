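#' @importFrom utils read.delim write.table
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
NULL

# Strip "#"-comment and blank lines from raw TSV lines, keeping the original
# line numbers for error messages.
.readTsvLines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  list(lines = raw[keep], lineno = which(keep))
}

#' Read an RNA-to-miRNA interaction catalog fragment
#'
#' Reads either a two-column TSV edge list (\code{rna_id <TAB> mirna_id};
#' header auto-detected on the first line) or a GMT file where each set name
#' is an RNA and the members (third field onward) are its miRNAs. Duplicate
#' rows are collapsed. IDs are opaque, case-sensitive strings.
#'
#' @param path file path.
#' @param format \code{"tsv"}, \code{"gmt"}, or \code{"auto"} (by file
#'   extension, defaulting to TSV).
#' @return Named list mapping each RNA ID to its character vector of miRNA
#'   IDs. Combine two fragments into an [InteractionCatalog-class] with
#'   [interactionCatalog()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("L1\tm1", "L1\tm2", "L1\tm1"), f)
#' readInteractionCatalog(f)
#' @export
readInteractionCatalog <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  tl <- .readTsvLines(path)
  if (!length(tl$lines))
    stop("empty interaction catalog: ", path)
  if (format == "gmt") {
    fields <- strsplit(tl$lines, "\t", fixed = TRUE)
    short <- lengths(fields) < 3L
    if (any(short))
      stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields",
                   tl$lineno[which(short)[1]], path))
    out <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(out) <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(names(out))) {
      out <- tapply(out, names(out), function(x)
        unique(unlist(x, use.names = FALSE)), simplify = FALSE)
      out <- lapply(as.list(out), as.character)
    }
    return(out[order(names(out))])
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 2L
  if (any(bad))
    stop(sprintf("malformed line %d in %s: expected 2 tab-separated columns",
                 tl$lineno[which(bad)[1]], path))
  rna <- vapply(fields, `[[`, character(1), 1L)
  mir <- vapply(fields, `[[`, character(1), 2L)
  # header detection: first line repeated nowhere as data is unknowable, so
  # use the conventional column names
  if (tolower(rna[1]) %in% c("rna_id", "rna", "id") ||
      tolower(mir[1]) %in% c("mirna_id", "mirna")) {
    rna <- rna[-1]; mir <- mir[-1]
  }
  if (!length(rna))
    stop("empty interaction catalog (header only): ", path)
  out <- lapply(split(mir, rna), unique)
  out[order(names(out))]
}

#' Read a matched lncRNA/mRNA expression matrix
#'
#' Reads a features-by-samples TSV expression matrix (first column feature
#' ID) together with a two-column sample/group file, and returns a
#' \linkS4class{SummarizedExperiment} with the expression values in assay
#' \code{"expr"}, per-feature class (\code{"mRNA"} / \code{"lncRNA"}) in
#' \code{rowData()$featureClass} and per-sample group (\code{"case"} /
#' \code{"control"}) in \code{colData()$group}.
#'
#' Feature classes come from an explicit two-column class file when supplied;
#' otherwise from a regular expression matched against feature IDs
#' (\code{lncPattern}); classes are never inferred silently.
#'
#' @param matrixPath TSV: feature ID column then one column per sample.
#' @param groupsPath TSV: \code{sample_id <TAB> group}, group in
#'   \code{case}/\code{control} (header auto-detected).
#' @param classesPath optional TSV: \code{feature_id <TAB> class}, class in
#'   \code{mRNA}/\code{lncRNA}.
#' @param lncPattern optional regex; matching feature IDs are classed
#'   \code{lncRNA}, the rest \code{mRNA}. Ignored when \code{classesPath} is
#'   given.
#' @return A \linkS4class{SummarizedExperiment}.
#' @export
readExpression <- function(matrixPath, groupsPath, classesPath = NULL,
                           lncPattern = NULL) {
  m <- utils::read.delim(matrixPath, header = TRUE, check.names = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("expression matrix needs at least one sample column")
  featIds <- as.character(m[[1L]])
  if (anyDuplicated(featIds))
    stop("duplicated feature ID in ", matrixPath, ": ",
         featIds[anyDuplicated(featIds)])
  vals <- as.matrix(m[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow = nrow(vals)))) & !is.na(vals),
      arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric expression value at feature '%s', sample '%s'",
                   featIds[bad[1, 1]], colnames(vals)[bad[1, 2]]))
    storage.mode(vals) <- "double"
  }
  rownames(vals) <- featIds

  gtab <- utils::read.delim(groupsPath, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  if (ncol(gtab) != 2L) stop("groups file must have 2 columns")
  if (tolower(gtab[1, 1]) %in% c("sample_id", "sample"))
    gtab <- gtab[-1L, , drop = FALSE]
  groups <- setNames(as.character(gtab[[2L]]), as.character(gtab[[1L]]))
  missing <- setdiff(colnames(vals), names(groups))
  if (length(missing))
    stop("sample(s) in matrix missing from groups file: ",
         paste(missing, collapse = ", "))
  groups <- groups[colnames(vals)]
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")

  if (!is.null(classesPath)) {
    ctab <- utils::read.delim(classesPath, header = FALSE, comment.char = "#",
                              stringsAsFactors = FALSE)
    if (tolower(ctab[1, 1]) %in% c("feature_id", "feature"))
      ctab <- ctab[-1L, , drop = FALSE]
    cls <- setNames(as.character(ctab[[2L]]), as.character(ctab[[1L]]))
    absent <- setdiff(featIds, names(cls))
    if (length(absent))
      stop("feature(s) missing from class file: ",
           paste(utils::head(absent, 5), collapse = ", "))
    featureClass <- cls[featIds]
  } else if (!is.null(lncPattern)) {
    featureClass <- ifelse(grepl(lncPattern, featIds), "lncRNA", "mRNA")
  } else {
    stop("supply either 'classesPath' or 'lncPattern'; ",
         "feature classes are never inferred silently")
  }
  se <- SummarizedExperiment(
    assays = list(expr = vals),
    rowData = S4Vectors::DataFrame(featureClass = unname(featureClass)),
    colData = S4Vectors::DataFrame(group = unname(groups),
                                   row.names = colnames(vals)))
  validateExpression(se)
  se
}

#' Validate an expression container
#'
#' Checks the invariants the pipeline relies on: unique feature and sample
#' IDs, \code{featureClass} in mRNA/lncRNA, \code{group} in case/control, and
#' at least 4 samples (Fisher's Z needs n > 3).
#'
#' @param se a \linkS4class{SummarizedExperiment} as produced by
#'   [readExpression()] or [simulateExpression()].
#' @return \code{se}, invisibly; errors describe the first violation.
#' @export
validateExpression <- function(se) {
  if (!methods::is(se, "SummarizedExperiment"))
    stop("expression object must be a SummarizedExperiment")
  if (!"expr" %in% SummarizedExperiment::assayNames(se))
    stop("assay 'expr' is required")
  if (is.null(rownames(se)) || anyDuplicated(rownames(se)))
    stop("feature IDs must be present and unique")
  if (is.null(colnames(se)) || anyDuplicated(colnames(se)))
    stop("sample IDs must be present and unique")
  fc <- SummarizedExperiment::rowData(se)$featureClass
  if (is.null(fc) || !all(fc %in% c("mRNA", "lncRNA")))
    stop("rowData()$featureClass must be 'mRNA' or 'lncRNA' for every feature")
  gr <- SummarizedExperiment::colData(se)$group
  if (is.null(gr) || anyNA(gr) || !all(gr %in% c("case", "control")))
    stop("colData()$group must be 'case' or 'control' for every sample")
  if (ncol(se) < 4L)
    stop("at least 4 samples are required (Fisher's Z needs n > 3)")
  invisible(se)
}

#' Read a pathway from the edge-list dialect
#'
#' The dialect is: header lines \code{"#id <pathway_id>"} and optionally
#' \code{"#name <name>"}, then two-column tab-separated gene pairs. Self-loops
#' are dropped and duplicate (or reversed-duplicate) edges collapsed.
#'
#' @param path file path.
#' @return A [PathwayGraph-class].
#' @seealso [writePathwayEdgelist()] for the inverse operation.
#' @export
readPathwayEdgelist <- function(path) {
  raw <- readLines(path, warn = FALSE)
  idLine <- grep("^#id\\s+", raw, value = TRUE)
  if (!length(idLine))
    stop("pathway edge list ", path, " lacks a '#id <pathway_id>' header")
  pid <- sub("^#id\\s+", "", idLine[1])
  nameLine <- grep("^#name\\s+", raw, value = TRUE)
  pname <- if (length(nameLine)) sub("^#name\\s+", "", nameLine[1]) else ""
  isolated <- sub("^#node\\s+", "", grep("^#node\\s+", raw, value = TRUE))
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  if (!length(lines))
    return(pathwayGraph(pid, nodes = isolated, name = pname))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) != 2L
  if (any(bad))
    stop(sprintf("malformed line %d in %s: expected 2 columns",
                 which(keep)[which(bad)[1]], path))
  em <- cbind(vapply(fields, `[[`, character(1), 1L),
              vapply(fields, `[[`, character(1), 2L))
  pathwayGraph(pid, edges = em, nodes = isolated, name = pname)
}

#' Write a pathway in the edge-list dialect
#'
#' Writes \code{"#id"}/\code{"#name"} headers, one line per edge, and a
#' \code{"#node <id>"} line for each isolated node so that reading the file
#' back reproduces the graph exactly.
#'
#' @param pathway a [PathwayGraph-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePathwayEdgelist <- function(pathway, path) {
  el <- pathwayEdges(pathway)
  touched <- unique(c(el$from, el$to))
  isolated <- setdiff(pathwayNodes(pathway), touched)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#id ", pathway@pathwayId), con)
  if (nzchar(pathway@name)) writeLines(paste0("#name ", pathway@name), con)
  if (length(isolated)) writeLines(paste0("#node ", isolated), con)
  if (nrow(el)) writeLines(paste(el$from, el$to, sep = "\t"), con)
  invisible(path)
}

#' Read a KGML (KEGG XML) pathway
#'
#' Parses the KGML subset relevant to graph conversion: \code{entry} elements
#' of type \code{"gene"} become nodes (one node per gene name listed in the
#' entry's \code{name} attribute, whitespace-separated) and \code{relation}
#' elements become undirected edges between the genes of the two entries
#' (relation subtype ignored, direction discarded). Entries of other types
#' (compound, group, map, ...) are ignored.
#'
#' @param path KGML file path.
#' @return A [PathwayGraph-class]; a warning is raised when the file contains
#'   no gene entries (an empty graph is still returned).
#' @export
readKGML <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document (no <pathway> root): ", path)
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- xml2::xml_attr(root, "number")
  pname <- xml2::xml_attr(root, "title")
  if (is.na(pname)) pname <- ""
  entries <- xml2::xml_find_all(doc, "//entry[@type='gene']")
  if (!length(entries)) {
    warning("KGML file ", path, " contains no gene entries; empty graph")
    return(pathwayGraph(pid, name = pname))
  }
  entryGenes <- lapply(entries, function(e)
    strsplit(trimws(xml2::xml_attr(e, "name")), "\\s+")[[1]])
  names(entryGenes) <- xml2::xml_attr(entries, "id")
  rels <- xml2::xml_find_all(doc, "//relation")
  edges <- NULL
  if (length(rels)) {
    e1 <- xml2::xml_attr(rels, "entry1")
    e2 <- xml2::xml_attr(rels, "entry2")
    pairs <- mapply(function(a, b) {
      ga <- entryGenes[[a]]; gb <- entryGenes[[b]]
      if (is.null(ga) || is.null(gb)) return(NULL)  # non-gene endpoint
      as.matrix(expand.grid(ga, gb, stringsAsFactors = FALSE))
    }, e1, e2, SIMPLIFY = FALSE)
    pairs <- pairs[!vapply(pairs, is.null, logical(1))]
    if (length(pairs)) edges <- do.call(rbind, pairs)
  }
  pathwayGraph(pid, edges = edges,
               nodes = unique(unlist(entryGenes, use.names = FALSE)),
               name = pname)
}

#' Write enrichment results as TSV
#'
#' Writes one row per scored subpathway, sorted by FDR (then p) ascending,
#' with the urn parameters, weight inputs and member lists. An empty result
#' yields a header-only file.
#'
#' @param rows data.frame as returned by [evaluateSubpathways()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(rows, path) {
  cols <- c("subpathway_id", "pathway_id", "pathway_name", "node_count",
            "gene_count", "lncrna_count", "x", "n", "m1", "m2", "G_L", "P_G",
            "W", "pvalue", "fdr", "member_genes", "member_lncrnas")
  if (is.null(rows) || nrow(rows) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
  } else {
    out <- rows[order(rows$fdr, rows$pvalue), cols, drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export one subpathway as SIF or GraphML
#'
#' The induced subgraph of the LRSP on the subpathway's members is written
#' with edge types distinguishing pathway (gene-gene) edges from competing
#' (lncRNA-mRNA regulation) edges.
#'
#' @param sp a [Subpathway-class].
#' @param lrsp the [LRSPGraph-class] the subpathway was located in.
#' @param path output file path.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
exportSubpathway <- function(sp, lrsp, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  sub <- igraph::induced_subgraph(lrsp@graph,
                                  vids = intersect(pathwayNodes(lrsp),
                                                   subpathwayNodes(sp)))
  tp <- setNames(igraph::vertex_attr(sub, "nodeType"),
                 igraph::V(sub)$name)
  el <- igraph::as_edgelist(sub, names = TRUE)
  etype <- ifelse(tp[el[, 1]] == "lncRNA" | tp[el[, 2]] == "lncRNA",
                  "competes", "pathway")
  if (format == "sif") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(el))
      writeLines(paste(el[, 1], etype, el[, 2], sep = "\t"), con)
    solo <- setdiff(igraph::V(sub)$name, unique(as.character(el)))
    if (length(solo)) writeLines(solo, con)
  } else {
    sub <- igraph::set_edge_attr(sub, "interaction", value = unname(etype))
    igraph::write_graph(sub, path, format = "graphml")
  }
  invisible(path)
}
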