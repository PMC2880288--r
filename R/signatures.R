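#' Column mapping for CTD-dialect interaction tables
#'
#' The interaction parser is config-driven so it tolerates column drift
#' across database releases. The defaults name the columns of the curated
#' chemical-gene interaction export.
#'
#' @param chemicalId,chemicalName,geneSymbol,organism,interaction,citations
#'   column names in the input header. \code{interaction} (the free-text
#'   description, which encodes direction of change) is optional and parsed
#'   but never used downstream.
#' @return a named list consumed by [parseInteractions()].
#' @export
ctdColumns <- function(chemicalId = "ChemicalID",
                       chemicalName = "ChemicalName",
                       geneSymbol = "GeneSymbol",
                       organism = "OrganismID",
                       interaction = "Interaction",
                       citations = "PubMedIDs") {
  list(chemicalId = chemicalId, chemicalName = chemicalName,
       geneSymbol = geneSymbol, organism = organism,
       interaction = interaction, citations = citations)
}

#' Parse a chemical-gene interaction table
#'
#' Reads a tab-separated interaction table (gzip-transparent) into one
#' record per (chemical, gene, organism) with a merged set of citation
#' identifiers. Rows with a missing chemical id or gene symbol are skipped
#' and counted; duplicate rows merge their citation sets.
#'
#' @param file path to a TSV (optionally gzipped); alternatively pass the
#'   table as a string via \code{text}.
#' @param text literal TSV text (mainly for tests).
#' @param columns column mapping, see [ctdColumns()].
#' @param citationSep separator between citation ids within the citation
#'   column (default \code{"|"}).
#' @return a data.frame with columns \code{chemicalId}, \code{chemicalName},
#'   \code{geneSymbol}, \code{taxon} (integer), \code{interaction},
#'   \code{citations} (list column of character vectors). The number of
#'   skipped rows is attached as \code{attr(, "skipped")}.
#' @export
parseInteractions <- function(file = NULL, text = NULL,
                              columns = ctdColumns(), citationSep = "|") {
  df <- .readTsv(file, text)
  if (nrow(df) == 0) {
    warning("no interaction rows found; returning an empty record set")
    out <- .emptyInteractions()
    attr(out, "skipped") <- 0L
    return(out)
  }
  required <- c("chemicalId", "geneSymbol", "organism", "citations")
  for (what in required) {
    if (!columns[[what]] %in% names(df))
      stop(sprintf("mapped column '%s' (%s) not found in header",
                   columns[[what]], what))
  }
  chem <- trimws(df[[columns$chemicalId]])
  gene <- trimws(df[[columns$geneSymbol]])
  name <- if (columns$chemicalName %in% names(df))
    trimws(df[[columns$chemicalName]]) else chem
  taxon <- suppressWarnings(as.integer(df[[columns$organism]]))
  inter <- if (!is.null(columns$interaction) &&
               columns$interaction %in% names(df))
    df[[columns$interaction]] else rep(NA_character_, nrow(df))
  cit <- strsplit(df[[columns$citations]], citationSep, fixed = TRUE)
  cit <- lapply(cit, function(x) unique(x[nzchar(trimws(x))]))

  bad <- is.na(chem) | !nzchar(chem) | is.na(gene) | !nzchar(gene) |
    lengths(cit) == 0
  skipped <- sum(bad)
  keep <- which(!bad)
  if (!length(keep)) {
    warning("all interaction rows were skipped")
    out <- .emptyInteractions()
    attr(out, "skipped") <- skipped
    return(out)
  }
  chem <- chem[keep]; gene <- gene[keep]; name <- name[keep]
  taxon <- taxon[keep]; inter <- inter[keep]; cit <- cit[keep]

  # merge duplicate (chemical, gene, organism) rows, pooling citation sets
  key <- paste(chem, gene, taxon, sep = "\r")
  first <- !duplicated(key)
  if (any(!first)) {
    grp <- match(key, key[first])
    cit <- lapply(split(cit, grp), function(x) unique(unlist(x)))
    cit <- cit[order(as.integer(names(cit)))]
    chem <- chem[first]; gene <- gene[first]; name <- name[first]
    taxon <- taxon[first]; inter <- inter[first]
  }
  out <- data.frame(chemicalId = chem, chemicalName = name,
                    geneSymbol = gene, taxon = taxon,
                    interaction = inter, stringsAsFactors = FALSE)
  out$citations <- unname(cit)
  attr(out, "skipped") <- skipped
  out
}

.emptyInteractions <- function() {
  out <- data.frame(chemicalId = character(), chemicalName = character(),
                    geneSymbol = character(), taxon = integer(),
                    interaction = character(), stringsAsFactors = FALSE)
  out$citations <- list()
  out
}

# gene key for pooling: ortholog group id when a homology table is given
# (with a synthetic singleton group for unmapped genes), otherwise the
# upper-cased symbol (case-insensitive within-namespace pooling)
.geneKeys <- function(symbols, taxa, homology = NULL) {
  if (is.null(homology)) return(toupper(symbols))
  toGroupSpace(symbols, taxa, homology)$mapping
}

#' Build the chemical-gene-set prediction database
#'
#' Pools interaction records per chemical into gene sets ("signatures"),
#' counting for every gene the number of distinct citations across all of
#' that chemical-gene pair's records (summed over organisms). When a
#' [HomologyTable-class] is supplied, genes are first collapsed into
#' ortholog-group space so cross-species relations contribute a single gene
#' entry. Chemicals whose pooled set has fewer than \code{minGenes} genes
#' are dropped.
#'
#' @param records interaction records from [parseInteractions()] or
#'   [genInteractions()].
#' @param homology optional [HomologyTable-class] used to pool genes across
#'   species. Without it, genes pool by upper-cased symbol.
#' @param minGenes minimum signature size retained (default 5).
#' @return a [SignatureCollection-class].
#' @examples
#' rec <- genInteractions(50, genePool = sprintf("G%03d", 1:200), seed = 1)
#' buildSignatures(rec$records, minGenes = 5)
#' @export
buildSignatures <- function(records, homology = NULL, minGenes = 5) {
  minGenes <- .assertCount(minGenes, "minGenes", min = 1L)
  if (nrow(records) == 0) {
    warning("no interaction records; returning an empty collection")
    return(new("SignatureCollection", signatures = structure(list(), names = character()),
               chemicalNames = character(), minGenes = minGenes,
               geneUniverse = character(), dropped = 0L))
  }
  keys <- .geneKeys(records$geneSymbol, records$taxon, homology)
  pair <- paste0(records$chemicalId, "\r", keys)
  first <- which(!duplicated(pair))
  pid <- match(pair, pair[first])
  # distinct citations per (chemical, gene) pair
  nCit <- lengths(records$citations)
  longPid <- rep.int(pid, nCit)
  longCit <- unlist(records$citations, use.names = FALSE)
  citIdx <- match(longCit, unique(longCit))
  dup <- duplicated(longPid * (max(citIdx) + 1) + citIdx)
  support <- tabulate(longPid[!dup], nbins = length(first))
  chemOf <- records$chemicalId[first]
  geneOf <- keys[first]

  sig <- split(structure(support, names = geneOf), chemOf)
  sizes <- lengths(sig)
  dropped <- sum(sizes < minGenes)
  sig <- sig[sizes >= minGenes]
  sig <- sig[order(names(sig))]
  nm <- records$chemicalName[match(names(sig), records$chemicalId)]
  uni <- sort(unique(unlist(lapply(sig, names), use.names = FALSE)))
  new("SignatureCollection",
      signatures = lapply(sig, function(s) s[order(names(s))]),
      chemicalNames = structure(nm, names = names(sig)),
      minGenes = minGenes, geneUniverse = uni, dropped = as.integer(dropped))
}

# keep a subset of chemicals without re-pooling records
.subsetCollection <- function(collection, keep) {
  sig <- collection@signatures[keep]
  uni <- sort(unique(unlist(lapply(sig, names), use.names = FALSE)))
  new("SignatureCollection", signatures = sig,
      chemicalNames = collection@chemicalNames[keep],
      minGenes = collection@minGenes, geneUniverse = uni,
      dropped = collection@dropped)
}

#' Remove interaction relations backed by given citation sources
#'
#' Used to avoid circularity when the interaction database itself cites the
#' expression dataset being queried: relations supported only by the listed
#' sources are removed entirely; relations with partial overlap keep the
#' remaining citations.
#'
#' @param records interaction records ([parseInteractions()] layout).
#' @param sourceIds character vector of citation identifiers to purge.
#' @return the filtered records; counts are attached as
#'   \code{attr(, "removedRecords")} (relations removed entirely) and
#'   \code{attr(, "removedCitations")} (citations subtracted).
#' @export
removeRelationsBySource <- function(records, sourceIds) {
  sourceIds <- as.character(sourceIds)
  if (length(sourceIds) == 0 || nrow(records) == 0) {
    attr(records, "removedRecords") <- 0L
    attr(records, "removedCitations") <- 0L
    return(records)
  }
  newCit <- lapply(records$citations, setdiff, y = sourceIds)
  removedCitations <- sum(lengths(records$citations) - lengths(newCit))
  keep <- lengths(newCit) > 0
  out <- records[keep, , drop = FALSE]
  out$citations <- newCit[keep]
  rownames(out) <- NULL
  attr(out, "removedRecords") <- sum(!keep)
  attr(out, "removedCitations") <- as.integer(removedCitations)
  attr(out, "skipped") <- attr(records, "skipped")
  out
}

#' Column mapping for disease-chemical association tables
#' @param diseaseId,diseaseName,chemicalId column names in the input header.
#' @return a named list consumed by [parseDiseaseMap()].
#' @export
diseaseColumns <- function(diseaseId = "DiseaseID",
                           diseaseName = "DiseaseName",
                           chemicalId = "ChemicalID") {
  list(diseaseId = diseaseId, diseaseName = diseaseName,
       chemicalId = chemicalId)
}

#' Parse a curated disease-chemical association table
#'
#' @param file path to a TSV (MeSH disease id/name, chemical id); or pass
#'   \code{text}.
#' @param text literal TSV text.
#' @param columns column mapping, see [diseaseColumns()].
#' @return a [DiseaseChemicalMap-class]; duplicate (disease, chemical) rows
#'   collapse to a single membership.
#' @export
parseDiseaseMap <- function(file = NULL, text = NULL,
                            columns = diseaseColumns()) {
  df <- .readTsv(file, text)
  if (nrow(df) == 0) {
    warning("no disease-chemical rows found")
    return(new("DiseaseChemicalMap",
               associations = structure(list(), names = character()),
               diseaseNames = character()))
  }
  for (what in c("diseaseId", "chemicalId")) {
    if (!columns[[what]] %in% names(df))
      stop(sprintf("mapped column '%s' (%s) not found in header",
                   columns[[what]], what))
  }
  did <- trimws(df[[columns$diseaseId]])
  chem <- trimws(df[[columns$chemicalId]])
  nm <- if (columns$diseaseName %in% names(df))
    trimws(df[[columns$diseaseName]]) else did
  ok <- nzchar(did) & nzchar(chem)
  did <- did[ok]; chem <- chem[ok]; nm <- nm[ok]
  assoc <- lapply(split(chem, did), function(x) sort(unique(x)))
  names(assoc) <- sort(unique(did))
  dn <- structure(nm[match(names(assoc), did)], names = names(assoc))
  new("DiseaseChemicalMap", associations = assoc, diseaseNames = dn)
}

#' Construct a DiseaseChemicalMap from an in-memory list
#' @param associations named list, disease id -> character vector of
#'   chemical ids.
#' @param diseaseNames optional named character of display labels.
#' @return a [DiseaseChemicalMap-class].
#' @export
DiseaseChemicalMap <- function(associations, diseaseNames = NULL) {
  assoc <- lapply(associations, function(x) sort(unique(as.character(x))))
  if (is.null(diseaseNames))
    diseaseNames <- structure(names(assoc), names = names(assoc))
  new("DiseaseChemicalMap", associations = assoc,
      diseaseNames = diseaseNames)
}
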