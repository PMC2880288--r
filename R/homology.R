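#' Parse a Homologene-dialect ortholog group table
#'
#' Reads a headerless tab-separated table whose first four columns are
#' (group id, taxon id, gene id, gene symbol); extra columns (protein ids in
#' the homologene.data layout) are ignored. A gene listed in two groups keeps
#' its first assignment; the conflict is counted. Malformed rows (missing
#' group, taxon or symbol) are skipped and counted.
#'
#' @param file path to the TSV (gzip-transparent); or pass \code{text}.
#' @param text literal TSV text.
#' @return a [HomologyTable-class].
#' @export
parseHomology <- function(file = NULL, text = NULL) {
  df <- .readTsv(file, text, header = FALSE)
  if (nrow(df) == 0) {
    warning("no homology rows found")
    return(.buildHomologyTable(data.frame(group = character(),
                                          taxon = integer(),
                                          geneId = character(),
                                          symbol = character())))
  }
  if (ncol(df) < 4) stop("homology table needs >= 4 columns (group, taxon, gene id, symbol)")
  rec <- data.frame(group = trimws(df[[1]]),
                    taxon = suppressWarnings(as.integer(df[[2]])),
                    geneId = trimws(df[[3]]),
                    symbol = trimws(df[[4]]),
                    stringsAsFactors = FALSE)
  .buildHomologyTable(rec)
}

# shared by the parser and the synthetic generator
.buildHomologyTable <- function(rec) {
  bad <- !nzchar(rec$group) | is.na(rec$taxon) | !nzchar(rec$symbol)
  skipped <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]
  symKey <- paste0(rec$taxon, ":", toupper(rec$symbol))
  idKey <- paste0("id:", rec$taxon, ":", rec$geneId)
  # first-occurrence rule: a (taxon, gene) key maps to the first group seen
  dupSym <- duplicated(symKey)
  conflicts <- sum(dupSym & rec$group[match(symKey, symKey)] != rec$group)
  keep <- !dupSym
  index <- structure(rec$group[keep], names = symKey[keep])
  keepId <- !duplicated(idKey) & nzchar(rec$geneId)
  index <- c(index, structure(rec$group[keepId], names = idKey[keepId]))
  # group ids map to themselves so that group-space input is a fixed point
  gids <- unique(rec$group)
  index <- c(index, structure(gids, names = gids))
  index <- index[!duplicated(names(index))]
  members <- rec[keep, c("group", "taxon", "geneId", "symbol"),
                 drop = FALSE]
  rownames(members) <- NULL
  new("HomologyTable", members = members, index = index,
      conflicts = as.integer(conflicts), skipped = as.integer(skipped))
}

#' Map genes into ortholog-group space
#'
#' Each (taxon, gene) is looked up in the homology index (symbols matched
#' case-insensitively). Genes absent from the table are reported in the
#' \code{unmapped} set and, by default, assigned a synthetic singleton group
#' keyed \code{"T<taxon>:<SYMBOL>"} so they remain usable within-species
#' rather than being silently dropped. Input that is already in group space
#' maps to itself, so the mapping is idempotent.
#'
#' @param genes character vector of gene symbols, gene ids, or group ids.
#' @param taxa integer taxon id(s), recycled along \code{genes}.
#' @param table a [HomologyTable-class].
#' @param singletonFallback assign singleton groups to unmapped genes
#'   (default TRUE); with FALSE unmapped genes get NA in the mapping.
#' @return list with \code{groups} (unique mapped group ids, set semantics),
#'   \code{mapping} (per-input group id, named by input), and
#'   \code{unmapped} (inputs not found in the table).
#' @export
toGroupSpace <- function(genes, taxa, table, singletonFallback = TRUE) {
  stopifnot(is(table, "HomologyTable"))
  genes <- as.character(genes)
  taxa <- rep_len(as.integer(taxa), length(genes))
  up <- toupper(genes)
  idx <- table@index; keys <- names(idx)
  hit <- idx[match(genes, keys)]       # exact (group ids, pre-mapped input)
  miss <- is.na(hit)
  hit[miss] <- idx[match(paste0(taxa[miss], ":", up[miss]), keys)]
  stillMiss <- is.na(hit)
  unmapped <- unique(genes[stillMiss])
  if (singletonFallback) {
    hit[stillMiss] <- paste0("T", taxa[stillMiss], ":", up[stillMiss])
  }
  mapping <- structure(unname(hit), names = genes)
  list(groups = unique(mapping[!is.na(mapping)]),
       mapping = mapping,
       unmapped = unmapped)
}
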