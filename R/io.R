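#' Write a signature collection as GMT-style text with a JSON sidecar
#'
#' The GMT file has one line per chemical: id, description (the chemical
#' name), then the member genes, tab-separated. Citation counts and build
#' parameters go to the JSON sidecar so the pair round-trips losslessly.
#'
#' @param collection a [SignatureCollection-class].
#' @param gmtPath output GMT path.
#' @param jsonPath output sidecar path (default: gmtPath with .json).
#' @return invisible list of the two paths.
#' @export
writeSignatures <- function(collection, gmtPath,
                            jsonPath = sub("\\.gmt$", ".json", gmtPath)) {
  stopifnot(is(collection, "SignatureCollection"))
  if (identical(jsonPath, gmtPath)) jsonPath <- paste0(gmtPath, ".json")
  lines <- vapply(names(collection@signatures), function(ch) {
    paste(c(ch, unname(collection@chemicalNames[ch]),
            names(collection@signatures[[ch]])), collapse = "\t")
  }, "")
  writeLines(lines, gmtPath)
  jsonlite::write_json(
    list(minGenes = collection@minGenes,
         dropped = collection@dropped,
         citationCounts = lapply(collection@signatures, as.list)),
    jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(list(gmt = gmtPath, json = jsonPath))
}

#' Read a signature collection written by [writeSignatures()]
#'
#' @param gmtPath GMT path.
#' @param jsonPath sidecar path; without it citation counts default to 1.
#' @return a [SignatureCollection-class].
#' @export
readSignatures <- function(gmtPath,
                           jsonPath = sub("\\.gmt$", ".json", gmtPath)) {
  lines <- readLines(gmtPath)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  nms <- vapply(parts, `[[`, "", 2L)
  sidecar <- if (file.exists(jsonPath))
    jsonlite::read_json(jsonPath) else NULL
  sig <- lapply(seq_along(parts), function(i) {
    genes <- parts[[i]][-(1:2)]
    cnt <- if (!is.null(sidecar)) {
      unlist(sidecar$citationCounts[[ids[i]]])[genes]
    } else structure(rep(1L, length(genes)), names = genes)
    structure(as.integer(cnt), names = genes)
  })
  names(sig) <- ids
  minGenes <- if (!is.null(sidecar)) as.integer(sidecar$minGenes) else
    min(lengths(sig))
  ord <- order(ids)
  new("SignatureCollection",
      signatures = lapply(sig[ord], function(s) s[order(names(s))]),
      chemicalNames = structure(nms[ord], names = ids[ord]),
      minGenes = minGenes,
      geneUniverse = sort(unique(unlist(lapply(sig, names),
                                        use.names = FALSE))),
      dropped = if (!is.null(sidecar)) as.integer(sidecar$dropped) else 0L)
}

# "GENE1(12);GENE2(3)" rendering of an overlap vector
.formatOverlap <- function(ov) {
  if (is.null(ov) || !length(ov)) return("")
  paste(sprintf("%s(%d)", names(ov), as.integer(ov)), collapse = ";")
}

#' Write a prediction list as a report TSV
#'
#' Columns follow the report-table layout: chemical id and name, p, rank,
#' percentile, q, positive call, k/K/n/N, and the overlap genes with their
#' citation counts rendered as \code{GENE(count);...}.
#'
#' @param observed a [PredictionList-class] (q filled for the positive
#'   column; NA q leaves the column NA).
#' @param path output TSV path.
#' @param alpha,qMax positive-call thresholds used for the \code{positive}
#'   column.
#' @return the path, invisibly.
#' @export
writePredictions <- function(observed, path, alpha = 0.001, qMax = 0.1) {
  stopifnot(is(observed, "PredictionList"))
  rec <- observed@records
  out <- data.frame(
    chemicalId = rec$chemicalId, chemicalName = rec$chemicalName,
    p = signif(rec$p, 6), rank = rec$rank, percentile = rec$percentile,
    q = signif(rec$q, 6),
    positive = if (anyNA(rec$q)) NA else rec$p <= alpha & rec$q < qMax,
    k = rec$k, K = rec$K, n = rec$n, N = rec$N,
    overlapGenes = vapply(rec$overlapGenes, .formatOverlap, ""),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write interaction records in the CTD-dialect TSV layout
#'
#' Inverse of [parseInteractions()] (citation sets joined with \code{"|"}),
#' used by the simulate subcommand to emit parseable fixtures.
#'
#' @param records interaction records.
#' @param path output TSV path.
#' @param columns column mapping, see [ctdColumns()].
#' @return the path, invisibly.
#' @export
writeInteractions <- function(records, path, columns = ctdColumns()) {
  out <- data.frame(records$chemicalName, records$chemicalId,
                    records$geneSymbol, records$taxon,
                    records$interaction,
                    vapply(records$citations, paste, "", collapse = "|"),
                    stringsAsFactors = FALSE)
  names(out) <- unlist(columns[c("chemicalName", "chemicalId", "geneSymbol",
                                 "organism", "interaction", "citations")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a homology table's rows in the Homologene-dialect layout
#' @param records data.frame with group, taxon, geneId, symbol columns
#'   (e.g. [genHomology()]'s \code{records}).
#' @param path output TSV path (headerless, as in homologene.data).
#' @return the path, invisibly.
#' @export
writeHomology <- function(records, path) {
  write.table(records[, c("group", "taxon", "geneId", "symbol")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a disease-chemical map as a TSV
#' @param map a [DiseaseChemicalMap-class].
#' @param path output TSV path.
#' @param columns column mapping, see [diseaseColumns()].
#' @return the path, invisibly.
#' @export
writeDiseaseMap <- function(map, path, columns = diseaseColumns()) {
  stopifnot(is(map, "DiseaseChemicalMap"))
  did <- rep.int(names(map@associations), lengths(map@associations))
  out <- data.frame(did, unname(map@diseaseNames[did]),
                    unlist(map@associations, use.names = FALSE),
                    stringsAsFactors = FALSE)
  names(out) <- unlist(columns[c("diseaseId", "diseaseName", "chemicalId")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression experiment and its label file as TSVs
#' @param se a \code{SummarizedExperiment} (assay 1, rowData symbol).
#' @param exprPath,labelsPath output paths.
#' @return invisible list of both paths.
#' @export
writeExpression <- function(se, exprPath, labelsPath) {
  m <- SummarizedExperiment::assay(se, 1)
  out <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(
    colnames(m),
    as.character(SummarizedExperiment::colData(se)$condition))
  write.table(lab, labelsPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(list(expression = exprPath, labels = labelsPath))
}

#' Write every fixture of a synthetic scenario to a directory
#'
#' Emits the interaction, homology, expression, label and disease-map TSVs
#' in the dialects the parsers consume, plus \code{manifest.json}.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir output directory (created if needed).
#' @return invisible named list of paths.
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "SyntheticScenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    interactions = file.path(dir, "interactions.tsv"),
    homology = file.path(dir, "homology.tsv"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    diseaseMap = file.path(dir, "disease_map.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeInteractions(scenario@interactions, paths$interactions)
  writeHomology(scenario@homology@members, paths$homology)
  writeExpression(scenario@expression, paths$expression, paths$labels)
  writeDiseaseMap(scenario@diseaseMap, paths$diseaseMap)
  jsonlite::write_json(scenario@manifest, paths$manifest,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
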