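# shared fixtures, all generated in code

# small interaction table as literal TSV text (CTD dialect)
tinyInteractionTsv <- function() {
  paste(
    "ChemicalName\tChemicalID\tGeneSymbol\tOrganismID\tInteraction\tPubMedIDs",
    "tcdd\tC001\tCYP1A1\t9606\tincreases expression\ta",
    "tcdd\tC001\tCYP1A1\t9606\tincreases expression\tb",
    "tcdd\tC001\tAHR\t9606\taffects expression\tc|d",
    "estradiol\tC002\tESR1\t9606\tincreases expression\te",
    sep = "\n")
}

# records data.frame built directly (parseInteractions layout)
makeRecords <- function(chem, gene, taxon = 9606L, citations) {
  out <- data.frame(chemicalId = chem,
                    chemicalName = paste0("name-", chem),
                    geneSymbol = gene,
                    taxon = rep_len(taxon, length(chem)),
                    interaction = NA_character_,
                    stringsAsFactors = FALSE)
  out$citations <- citations
  out
}

# a chemical with `size` genes, one citation each
recordsOfSizes <- function(sizes) {
  chem <- rep(names(sizes), sizes)
  gene <- unlist(lapply(seq_along(sizes), function(i)
    sprintf("%s_G%02d", names(sizes)[i], seq_len(sizes[i]))))
  makeRecords(chem, gene,
              citations = as.list(sprintf("ref%04d", seq_along(chem))))
}

# small homology table: nGroups groups x 3 taxa
tinyHomology <- function(nGroups = 4) {
  genHomology(nGroups, seed = 42)$table
}

# a ready-made small enrichment setting: collection over a known universe
tinyEnrichmentSetting <- function(nChem = 30, poolSize = 120, seed = 7) {
  gi <- genInteractions(nChem, genePool = sprintf("G%03d", seq_len(poolSize)),
                        seed = seed)
  coll <- buildSignatures(gi$records, minGenes = 2)
  uni <- buildUniverse(sprintf("G%03d", seq_len(poolSize)), coll,
                       policy = "intersection")
  list(collection = coll, universe = uni, manifest = gi$manifest)
}

# independent oracle: exhaustive enumeration of all n-subsets of 1..N,
# counting draws overlapping the K-set {1..K} in at least k elements
enumHypergeomUpper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# independent oracle: double-loop q-value recomputation from raw matrices
bruteForceQ <- function(obsP, nullMat, B) {
  raw <- vapply(obsP, function(p) {
    (sum(nullMat <= p) / B) / max(1, sum(obsP <= p))
  }, 0)
  raw <- pmin(pmax(raw, 0), 1)
  ord <- order(obsP)
  q <- raw
  q[ord] <- rev(cummin(rev(raw[ord])))
  q
}
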