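#' Generate a synthetic ortholog-group table
#'
#' One group per gene-pool entry, with one member per taxon. Symbols follow
#' the field's casing conventions (upper-case for human, title case for
#' rodents) so that case-insensitive matching is exercised.
#'
#' @param nGroups number of ortholog groups (the gene pool size).
#' @param taxa taxon ids represented in every group.
#' @param seed RNG seed (NULL = current stream).
#' @return list with \code{table} (a [HomologyTable-class]), \code{records}
#'   (the raw rows: group, taxon, geneId, symbol), and \code{manifest}.
#' @export
genHomology <- function(nGroups, taxa = c(9606L, 10090L, 10116L),
                        seed = NULL) {
  nGroups <- .assertCount(nGroups, "nGroups", min = 1L)
  .withSeed(seed, {
    gids <- sprintf("GRP%05d", seq_len(nGroups))
    base <- sprintf("GENE%04d", seq_len(nGroups))
    rows <- do.call(rbind, lapply(seq_along(taxa), function(ti) {
      tx <- taxa[ti]
      sym <- if (tx == 9606L) base else
        paste0(substr(base, 1, 1), tolower(substr(base, 2, nchar(base))))
      data.frame(group = gids, taxon = tx,
                 geneId = as.character(ti * 10^6 + seq_len(nGroups)),
                 symbol = sym, stringsAsFactors = FALSE)
    }))
    list(table = .buildHomologyTable(rows), records = rows,
         manifest = list(nGroups = nGroups, taxa = taxa, seed = seed))
  })
}

#' Generate a synthetic chemical-gene interaction table
#'
#' Per-chemical set sizes follow a discretized log-normal calibrated to the
#' curated database's reported quantiles (median 2, 70th percentile 5, 75th
#' percentile 7), reproducing its heavy right tail. Citation counts per
#' relation are 1 + Geometric (long-tailed, cosmetic for report fidelity).
#'
#' @param nChemicals number of chemicals.
#' @param homology optional result of [genHomology()]'s \code{table}; the
#'   gene pool is then its group ids and each relation carries the symbol of
#'   a randomly drawn member taxon. Alternatively pass \code{genePool}.
#' @param genePool character vector of gene symbols when no homology table
#'   is used.
#' @param sizeMeanlog,sizeSdlog log-normal parameters of the set-size
#'   distribution; defaults meet the 2/5/7 quantile targets
#'   (\code{sizeSdlog = 0} gives a degenerate all-equal distribution).
#' @param citationProb geometric success probability for citation counts.
#' @param taxa,taxonWeights taxon sampling for each relation (used with a
#'   homology table).
#' @param seed RNG seed.
#' @return list with \code{records} (the [parseInteractions()] layout) and
#'   \code{manifest} (generator bookkeeping: relation and pair counts,
#'   per-chemical set sizes, citation total).
#' @export
genInteractions <- function(nChemicals, homology = NULL, genePool = NULL,
                            sizeMeanlog = log(2), sizeSdlog = 1.747,
                            citationProb = 0.35,
                            taxa = c(9606L, 10090L, 10116L),
                            taxonWeights = c(0.5, 0.3, 0.2),
                            seed = NULL) {
  nChemicals <- .assertCount(nChemicals, "nChemicals", min = 1L)
  if (sizeSdlog < 0) stop("sizeSdlog must be >= 0")
  useHomology <- !is.null(homology)
  if (useHomology) {
    stopifnot(is(homology, "HomologyTable"))
    mem <- homology@members
    pool <- unique(mem$group)
    symKey <- paste0(mem$group, "\r", mem$taxon)
  } else {
    if (is.null(genePool)) stop("provide 'homology' or 'genePool'")
    pool <- unique(as.character(genePool))
  }
  if (length(pool) < 2) stop("gene pool too small")
  .withSeed(seed, {
    sizes <- as.integer(pmin(length(pool),
                             ceiling(rlnorm(nChemicals, sizeMeanlog,
                                            sizeSdlog))))
    chemIds <- sprintf("CHEM%05d", seq_len(nChemicals))
    geneIdx <- lapply(sizes, function(sz) sample.int(length(pool), sz))
    chem <- rep.int(chemIds, sizes)
    gene <- pool[unlist(geneIdx, use.names = FALSE)]
    nRel <- length(gene)
    if (useHomology) {
      tx <- sample(taxa, nRel, replace = TRUE, prob = taxonWeights)
      sym <- mem$symbol[match(paste0(gene, "\r", tx), symKey)]
      if (anyNA(sym))
        stop("homology table lacks a member for a drawn (group, taxon)")
    } else {
      tx <- rep.int(9606L, nRel)
      sym <- gene
    }
    nCit <- 1L + rgeom(nRel, citationProb)
    citPool <- sum(nCit) * 5L
    citIds <- sprintf("PMID%08d", sample.int(citPool, sum(nCit)))
    cit <- split(citIds, rep.int(seq_len(nRel), nCit))
    cit <- lapply(cit, unique)
    verbs <- c("increases expression of", "decreases expression of",
               "affects expression of")
    records <- data.frame(
      chemicalId = chem,
      chemicalName = sub("CHEM", "chemical-", chem),
      geneSymbol = sym, taxon = tx,
      interaction = paste(sample(verbs, nRel, replace = TRUE), sym),
      stringsAsFactors = FALSE)
    records$citations <- unname(cit)
    manifest <- list(nChemicals = nChemicals, nRelations = nRel,
                     nPairs = length(unique(paste(chem, gene))),
                     setSizes = structure(sizes, names = chemIds),
                     totalCitations = sum(lengths(cit)),
                     sizeMeanlog = sizeMeanlog, sizeSdlog = sizeSdlog,
                     citationProb = citationProb, seed = seed)
    list(records = records, manifest = manifest)
  })
}

#' Generate a two-class expression matrix with a planted signature
#'
#' Background genes are Normal(0, noiseSd) in both classes; a fixed fraction
#' of the signature genes is shifted by \code{effect} in the case class.
#' With \code{effect = 0} nothing is shifted and the truth set is empty.
#'
#' @param signatureGenes platform symbols of the planted signature.
#' @param platformGenes all platform symbols (the matrix rows).
#' @param effect log-scale shift added in cases (units of expression; an
#'   effect of \code{2 * noiseSd} is a 2-sigma spike-in).
#' @param nCase,nControl samples per class.
#' @param noiseSd background standard deviation.
#' @param fraction fraction of signature genes actually shifted, in [0, 1];
#'   the count is \code{floor(fraction * |signature|)}.
#' @param taxon platform taxon id.
#' @param seed RNG seed.
#' @return list with \code{expression} (a \code{SummarizedExperiment}),
#'   \code{truth} (the shifted symbols), and \code{manifest}.
#' @export
genExpression <- function(signatureGenes, platformGenes, effect = 2,
                          nCase = 5, nControl = 5, noiseSd = 1,
                          fraction = 0.75, taxon = 9606L, seed = NULL) {
  nCase <- .assertCount(nCase, "nCase", min = 2L)
  nControl <- .assertCount(nControl, "nControl", min = 2L)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  platformGenes <- as.character(platformGenes)
  sig <- intersect(as.character(signatureGenes), platformGenes)
  if (length(sig) < length(unique(signatureGenes)))
    warning("signature genes missing from the platform were ignored")
  .withSeed(seed, {
    nG <- length(platformGenes); nS <- nCase + nControl
    vals <- matrix(rnorm(nG * nS, 0, noiseSd), nG, nS)
    nShift <- if (effect == 0) 0L else floor(fraction * length(sig) + 1e-9)
    shifted <- if (nShift > 0) sample(sig, nShift) else character()
    if (nShift > 0)
      vals[match(shifted, platformGenes), seq_len(nCase)] <-
        vals[match(shifted, platformGenes), seq_len(nCase)] + effect
    labels <- c(rep("case", nCase), rep("control", nControl))
    colnames(vals) <- c(sprintf("case_%02d", seq_len(nCase)),
                        sprintf("control_%02d", seq_len(nControl)))
    se <- makeExpressionExperiment(vals, symbols = platformGenes,
                                   taxon = taxon, labels = labels)
    list(expression = se, truth = shifted,
         manifest = list(nGenes = nG, nCase = nCase, nControl = nControl,
                         effect = effect, noiseSd = noiseSd,
                         fraction = fraction, nShifted = nShift,
                         seed = seed))
  })
}

#' Generate a synthetic disease-chemical map with one planted disease
#'
#' The planted disease's curated set contains the planted chemicals plus
#' random decoys; the remaining diseases draw their chemical sets uniformly.
#' All diseases meet the minimum-size eligibility rule.
#'
#' @param nDiseases number of diseases (all eligible at \code{minSize}).
#' @param chemicals chemical id pool to draw from.
#' @param plantedChemicals chemicals guaranteed inside the planted disease
#'   (empty for a fully random map).
#' @param minSize,maxSize curated set size range (uniform).
#' @param nDecoys random chemicals added to the planted set.
#' @param seed RNG seed.
#' @return list with \code{map} (a [DiseaseChemicalMap-class]),
#'   \code{plantedDisease} (id, or NA for a fully random map), and
#'   \code{manifest}.
#' @export
genDiseaseMap <- function(nDiseases, chemicals,
                          plantedChemicals = character(),
                          minSize = 5, maxSize = 20, nDecoys = 4,
                          seed = NULL) {
  nDiseases <- .assertCount(nDiseases, "nDiseases", min = 1L)
  minSize <- .assertCount(minSize, "minSize", min = 1L)
  chemicals <- unique(as.character(chemicals))
  plantedChemicals <- unique(as.character(plantedChemicals))
  if (!all(plantedChemicals %in% chemicals))
    stop("planted chemicals must belong to the chemical pool")
  .withSeed(seed, {
    ids <- sprintf("MESH:D%06d", seq_len(nDiseases))
    assoc <- vector("list", nDiseases)
    sizes <- sample(seq(minSize, max(minSize, maxSize)), nDiseases,
                    replace = TRUE)
    for (i in seq_len(nDiseases))
      assoc[[i]] <- sample(chemicals, sizes[i])
    planted <- NA_character_
    if (length(plantedChemicals)) {
      planted <- ids[1]
      decoys <- sample(setdiff(chemicals, plantedChemicals),
                       max(nDecoys, minSize - length(plantedChemicals)))
      assoc[[1]] <- c(plantedChemicals, decoys)
    }
    names(assoc) <- ids
    map <- DiseaseChemicalMap(
      assoc, structure(sub("MESH:", "disease-", ids), names = ids))
    list(map = map, plantedDisease = planted,
         manifest = list(nDiseases = nDiseases, minSize = minSize,
                         maxSize = maxSize, nDecoys = nDecoys,
                         plantedChemicals = plantedChemicals, seed = seed))
  })
}

#' Simulate a complete spike-in study
#'
#' Generates, end to end and from a single seed: an ortholog-group table, an
#' interaction table whose filtered signature database has exactly
#' \code{nSignatures} sets, an expression matrix in which a planted
#' chemical's 20-gene signature is shifted in the case class, and a disease
#' map whose first disease's curated set contains the planted chemical. The
#' defaults mirror the curated-database scale the method was designed for
#' (1,338 signatures over a 5,000-gene space, 5 vs 5 samples, a 2-sigma
#' effect on 75\% of the planted signature, 141 eligible diseases).
#' Regeneration from the manifest's parameters and seed is bit-identical.
#'
#' @param seed RNG seed for the whole scenario.
#' @param nSignatures signatures retained after the minimum-size filter.
#' @param genePoolSize ortholog groups in the gene pool; the expression
#'   platform covers exactly this pool.
#' @param nChemicals chemicals drawn before filtering (must leave at least
#'   \code{nSignatures} passing sets).
#' @param plantedSize planted signature size.
#' @param effect case-class shift in units of \code{noiseSd}-scaled
#'   expression.
#' @param deFraction fraction of planted signature genes actually shifted.
#' @param nCase,nControl samples per class.
#' @param noiseSd background standard deviation.
#' @param nDiseases diseases in the map.
#' @param minGenes signature size filter.
#' @return a [SyntheticScenario-class].
#' @export
simulateScenario <- function(seed = 1, nSignatures = 1338,
                             genePoolSize = 5000, nChemicals = 5000,
                             plantedSize = 20, effect = 2,
                             deFraction = 0.75, nCase = 5, nControl = 5,
                             noiseSd = 1, nDiseases = 141, minGenes = 5) {
  .withSeed(seed, {
    hom <- genHomology(genePoolSize)
    gi <- genInteractions(nChemicals, homology = hom$table)
    records <- gi$records
    mem <- hom$table@members
    pool <- unique(mem$group)
    planted <- "CHEM00001"
    plantedGroups <- sample(pool, plantedSize)
    human <- mem[mem$taxon == 9606L, ]
    humanSym <- structure(human$symbol[match(plantedGroups, human$group)],
                          names = plantedGroups)
    nCit <- 1L + rgeom(plantedSize, 0.15)   # well-cited planted relations
    cit <- lapply(seq_len(plantedSize), function(i)
      sprintf("PMIDP%07d", i * 100L + seq_len(nCit[i])))
    plantedRec <- data.frame(
      chemicalId = planted, chemicalName = "chemical-00001",
      geneSymbol = unname(humanSym), taxon = 9606L,
      interaction = paste("increases expression of", unname(humanSym)),
      stringsAsFactors = FALSE)
    plantedRec$citations <- cit
    records <- rbind(records[records$chemicalId != planted, ], plantedRec)
    records <- records[order(records$chemicalId), , drop = FALSE]
    rownames(records) <- NULL

    coll0 <- buildSignatures(records, hom$table, minGenes = minGenes)
    keep <- chemicalIds(coll0)
    if (!planted %in% keep) stop("internal: planted signature filtered out")
    if (length(keep) < nSignatures)
      stop("only ", length(keep), " signatures passed the filter; ",
           "increase nChemicals")
    keep <- c(planted, setdiff(keep, planted)[seq_len(nSignatures - 1L)])
    keep <- sort(keep)
    collection <- .subsetCollection(coll0, keep)
    records <- records[records$chemicalId %in% keep, , drop = FALSE]
    rownames(records) <- NULL

    platform <- sprintf("GENE%04d", seq_len(genePoolSize))
    ge <- genExpression(unname(humanSym), platform, effect = effect,
                        nCase = nCase, nControl = nControl,
                        noiseSd = noiseSd, fraction = deFraction)
    shiftedGroups <- unname(toGroupSpace(ge$truth, 9606L,
                                         hom$table)$mapping)

    dm <- genDiseaseMap(nDiseases, chemicalIds(collection),
                        plantedChemicals = planted)

    manifest <- list(seed = seed, nSignatures = nSignatures,
                     genePoolSize = genePoolSize, nChemicals = nChemicals,
                     plantedSize = plantedSize, effect = effect,
                     deFraction = deFraction, nCase = nCase,
                     nControl = nControl, noiseSd = noiseSd,
                     nDiseases = nDiseases, minGenes = minGenes,
                     plantedChemical = planted,
                     plantedGroups = plantedGroups,
                     shiftedSymbols = ge$truth,
                     nRelations = nrow(records),
                     droppedBySizeFilter = coll0@dropped,
                     interactions = gi$manifest[c("nRelations", "nPairs")],
                     expression = ge$manifest, diseaseMap = dm$manifest)

    new("SyntheticScenario", interactions = records,
        homology = hom$table, expression = ge$expression,
        collection = collection, diseaseMap = dm$map,
        plantedChemicals = planted,
        plantedGenes = unique(shiftedGroups),
        plantedDisease = dm$plantedDisease, manifest = manifest)
  })
}
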