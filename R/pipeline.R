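#' Predict chemicals associated with a two-class expression dataset
#'
#' The core pipeline: map the platform into ortholog-group space, select
#' differentially expressed genes with the permutation d-statistic at a
#' target median FDR (or accept a precomputed DE gene list), build the
#' eligible universe, score every signature with the upper-tail
#' hypergeometric test, and fill resampling q-values from B random gene
#' draws of the same size.
#'
#' @param x expression \code{SummarizedExperiment} (see
#'   [makeExpressionExperiment()]); may be NULL when \code{de} is given
#'   together with \code{platformGenes}.
#' @param collection a [SignatureCollection-class].
#' @param homology optional [HomologyTable-class]; without it genes match by
#'   upper-cased symbol.
#' @param de optional precomputed DE gene list (symbols or group ids); when
#'   given, the differential expression stage is skipped.
#' @param platformGenes platform symbols when \code{x} is NULL.
#' @param taxon platform taxon when \code{de}/\code{platformGenes} are plain
#'   symbols.
#' @param targetFdr target median FDR for [selectDelta()]. The default 0.07
#'   is the upper bound of the 5-7\% range the gene lists are controlled to.
#' @param delta optional fixed delta (bypasses the target-FDR search).
#' @param nPermutations Monte-Carlo label permutations when complete
#'   enumeration exceeds 1000.
#' @param B resamplings for the q-value null.
#' @param universePolicy see [buildUniverse()].
#' @param qMax,alpha positive-call thresholds recorded in provenance.
#' @param seed RNG seed covering both DE permutations and the resampling
#'   null.
#' @return list with \code{predictions} (a [PredictionList-class] with q
#'   filled), \code{de} (the [DEResult-class], or NULL for a precomputed
#'   list), \code{universe}, and \code{ensemble}.
#' @export
predictChemicals <- function(x = NULL, collection, homology = NULL,
                             de = NULL, platformGenes = NULL,
                             taxon = 9606L, targetFdr = 0.07, delta = NULL,
                             nPermutations = 100, B = 100,
                             universePolicy = c("intersection", "platform"),
                             qMax = 0.1, alpha = 0.001, seed = 1) {
  universePolicy <- match.arg(universePolicy)
  deResult <- NULL
  if (is.null(x)) {
    if (is.null(de) || is.null(platformGenes))
      stop("without an expression object, supply both 'de' and 'platformGenes'")
    symbols <- as.character(platformGenes)
    taxa <- rep_len(as.integer(taxon), length(symbols))
    deSymbols <- as.character(de)
    deTaxa <- rep_len(as.integer(taxon), length(deSymbols))
  } else {
    rd <- SummarizedExperiment::rowData(x)
    symbols <- if ("symbol" %in% names(rd)) as.character(rd$symbol) else
      rownames(x)
    taxa <- if ("taxon" %in% names(rd)) as.integer(rd$taxon) else
      rep_len(as.integer(taxon), length(symbols))
    if (is.null(de)) {
      deResult <- if (is.null(delta))
        selectDelta(x, targetFdr = targetFdr,
                    nPermutations = nPermutations, seed = seed)
      else callGenes(x, delta = delta, nPermutations = nPermutations,
                     seed = seed)
      deSymbols <- calledGenes(deResult)
      hit <- match(deSymbols, rownames(x))
      deTaxa <- taxa[hit]
    } else {
      deSymbols <- as.character(de)
      deTaxa <- rep_len(as.integer(taxon), length(deSymbols))
    }
  }
  if (is.null(homology)) {
    platformGroups <- unique(toupper(symbols))
    deGroups <- unique(toupper(deSymbols))
  } else {
    platformGroups <- unique(toGroupSpace(symbols, taxa, homology)$mapping)
    deGroups <- unique(toGroupSpace(deSymbols, deTaxa, homology)$mapping)
  }
  universe <- buildUniverse(platformGroups, collection,
                            policy = universePolicy)
  deU <- intersect(deGroups, universe@genes)
  message("pipeline: ", length(deGroups), " DE genes, ", length(deU),
          " inside the ", length(universe@genes), "-gene universe")
  pred <- enrichAll(deU, collection, universe)
  ensemble <- buildNull(universe, n = length(deU), collection, B = B,
                        seed = seed)
  pred <- qValues(pred, ensemble)
  pred@provenance$seed <- seed
  pred@provenance$targetFdr <- targetFdr
  pred@provenance$qMax <- qMax
  pred@provenance$alpha <- alpha
  pred@provenance$universePolicy <- universePolicy
  if (!is.null(deResult)) {
    pred@provenance$deltaUsed <- deResult@delta
    pred@provenance$deMedianFdr <- deResult@medianFdr
    pred@provenance$s0 <- deResult@s0
  }
  list(predictions = pred, de = deResult, universe = universe,
       ensemble = ensemble)
}

#' Run the full file-in/file-out pipeline
#'
#' Orchestrates: interaction parsing and signature building, homology
#' mapping, differential expression (or DE-list passthrough), enrichment
#' with resampling q-values, optional disease validation, and optional
#' bioactivity clustering. All tabular outputs are deterministic TSVs; a
#' provenance JSON captures every parameter and seed.
#'
#' @param interactionsFile chemical-gene interaction TSV (CTD dialect).
#' @param expressionFile,labelsFile expression matrix and sample-class TSVs
#'   (see [readExpression()]); alternatively pass \code{deFile}, a one- or
#'   two-column TSV of DE gene symbols (with \code{platformFile} listing all
#'   platform genes).
#' @param deFile optional precomputed DE gene list TSV (no header, first
#'   column symbols).
#' @param platformFile platform gene list TSV, required with \code{deFile}.
#' @param homologyFile optional Homologene-dialect TSV.
#' @param diseaseMapFile optional curated disease-chemical TSV.
#' @param diseaseId disease to validate against (with a disease map).
#' @param bioassayFile optional chemical x assay score TSV (first column
#'   chemical id).
#' @param outDir output directory (created if needed).
#' @param minGenes signature size filter.
#' @param targetFdr,B,qMax,seed,universePolicy pipeline parameters, see
#'   [predictChemicals()].
#' @param alphas selection thresholds swept in the disease validation.
#' @param removeSources optional citation ids whose relations are purged
#'   before building signatures (see [removeRelationsBySource()]).
#' @param taxon platform taxon id.
#' @return invisible list with the in-memory results and output paths.
#' @export
runPipeline <- function(interactionsFile, expressionFile = NULL,
                        labelsFile = NULL, deFile = NULL,
                        platformFile = NULL, homologyFile = NULL,
                        diseaseMapFile = NULL, diseaseId = NULL,
                        bioassayFile = NULL, outDir,
                        minGenes = 5, targetFdr = 0.07, B = 100,
                        alphas = c(1e-4, 1e-3, 1e-2, 0.05), qMax = 0.1,
                        seed = 1,
                        universePolicy = c("intersection", "platform"),
                        removeSources = NULL, taxon = 9606L) {
  universePolicy <- match.arg(universePolicy)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  message("stage signatures: parsing ", interactionsFile)
  records <- parseInteractions(interactionsFile)
  message("  ", nrow(records), " interaction records (",
          attr(records, "skipped"), " rows skipped)")
  if (!is.null(removeSources)) {
    records <- removeRelationsBySource(records, removeSources)
    message("  removed ", attr(records, "removedRecords"),
            " relations citing excluded sources")
  }
  homology <- NULL
  if (!is.null(homologyFile)) {
    message("stage homology: parsing ", homologyFile)
    homology <- parseHomology(homologyFile)
    message("  ", length(unique(homology@members$group)), " groups, ",
            homology@conflicts, " conflicts")
  }
  collection <- buildSignatures(records, homology, minGenes = minGenes)
  message("stage signatures: ", length(collection@signatures),
          " signatures kept (", collection@dropped,
          " chemicals below ", minGenes, " genes)")

  if (!is.null(expressionFile)) {
    if (is.null(labelsFile)) stop("labelsFile is required with expressionFile")
    message("stage diffexpr: reading ", expressionFile)
    se <- readExpression(expressionFile, labelsFile, taxon = taxon)
    res <- predictChemicals(se, collection, homology,
                            targetFdr = targetFdr, B = B,
                            universePolicy = universePolicy, qMax = qMax,
                            seed = seed)
  } else {
    if (is.null(deFile) || is.null(platformFile))
      stop("supply expressionFile+labelsFile, or deFile+platformFile")
    deList <- .readTsv(deFile, header = FALSE)[[1]]
    platform <- .readTsv(platformFile, header = FALSE)[[1]]
    message("stage diffexpr: passthrough of ", length(deList),
            " precomputed DE genes")
    res <- predictChemicals(NULL, collection, homology, de = deList,
                            platformGenes = platform, taxon = taxon,
                            B = B, universePolicy = universePolicy,
                            qMax = qMax, seed = seed)
  }
  predPath <- file.path(outDir, "predictions.tsv")
  writePredictions(res$predictions, predPath, qMax = qMax)
  message("stage enrichment: wrote ", predPath)

  validation <- NULL
  if (!is.null(diseaseMapFile) && !is.null(diseaseId)) {
    message("stage validation: parsing ", diseaseMapFile)
    map <- parseDiseaseMap(diseaseMapFile)
    rows <- lapply(alphas, function(a) {
      fa <- fpAssessment(res$predictions, diseaseId, map, alpha = a)
      true <- fa@records[fa@records$diseaseId == diseaseId, ]
      data.frame(alpha = a, nSelected = true$nSelected,
                 trueDiseaseP = true$p, nOverlap = true$nOverlap,
                 fractionOfCurated = true$fractionOfCurated,
                 fpRate = fa@fpRate, nBetter = fa@nBetter,
                 stringsAsFactors = FALSE)
    })
    validation <- do.call(rbind, rows)
    valPath <- file.path(outDir, "validation.tsv")
    write.table(validation, valPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    message("stage validation: wrote ", valPath)
  } else if (!is.null(diseaseMapFile) || !is.null(diseaseId)) {
    warning("disease validation skipped: both diseaseMapFile and diseaseId ",
            "are required")
  } else {
    message("stage validation: skipped (no disease map supplied)")
  }

  bio <- NULL
  if (!is.null(bioassayFile)) {
    message("stage bioactivity: parsing ", bioassayFile)
    sc <- .readTsv(bioassayFile)
    scores <- as.matrix(sc[, -1, drop = FALSE])
    storage.mode(scores) <- "double"
    rownames(scores) <- sc[[1]]
    sim <- similarityFromScores(scores)
    ord <- clusterOrder(sim)
    ht <- heatmapTable(list(predictions = res$predictions),
                       chemicalOrder = intersect(ord$order,
                                                 res$predictions@records$chemicalId))
    htPath <- file.path(outDir, "heatmap.tsv")
    write.table(data.frame(chemicalId = rownames(ht), ht,
                           check.names = FALSE),
                htPath, sep = "\t", quote = FALSE, row.names = FALSE)
    writeClusterTree(ord$tree, file.path(outDir, "bioactivity_tree.nwk"))
    bio <- list(similarity = sim, order = ord$order)
    message("stage bioactivity: wrote ", htPath)
  }

  prov <- list(
    parameters = list(minGenes = minGenes, targetFdr = targetFdr, B = B,
                      alphas = alphas, qMax = qMax, seed = seed,
                      universePolicy = universePolicy, taxon = taxon),
    inputs = list(interactions = interactionsFile,
                  expression = expressionFile, labels = labelsFile,
                  de = deFile, homology = homologyFile,
                  diseaseMap = diseaseMapFile, bioassay = bioassayFile),
    counts = list(nSignatures = length(collection@signatures),
                  droppedChemicals = collection@dropped,
                  nDeGenes = length(res$predictions@deGenes),
                  universeSize = length(res$universe@genes)),
    de = res$predictions@provenance[c("deltaUsed", "deMedianFdr", "s0")],
    packageVersion = as.character(utils::packageVersion("chemsig")))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(collection = collection, predictions = res$predictions,
                 de = res$de, universe = res$universe,
                 validation = validation, bioactivity = bio,
                 outDir = outDir))
}
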