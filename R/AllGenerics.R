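#' Accessors for chemsig objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a chemsig S4 object.
#' @return the slot content documented per method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("signatures", function(object) standardGeneric("signatures"))

#' @rdname accessors
#' @export
setGeneric("chemicalIds", function(object) standardGeneric("chemicalIds"))

#' @rdname accessors
#' @export
setGeneric("chemicalNames", function(object) standardGeneric("chemicalNames"))

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(object) standardGeneric("geneUniverse"))

#' @rdname accessors
#' @export
setGeneric("minGenes", function(object) standardGeneric("minGenes"))

#' @rdname accessors
#' @export
setGeneric("universeGenes", function(object) standardGeneric("universeGenes"))

#' @rdname accessors
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))

#' @rdname accessors
#' @export
setGeneric("deGenes", function(object) standardGeneric("deGenes"))

#' @rdname accessors
#' @export
setGeneric("calledGenes", function(object) standardGeneric("calledGenes"))

#' @rdname accessors
#' @export
setGeneric("medianFdr", function(object) standardGeneric("medianFdr"))

#' @rdname accessors
#' @export
setGeneric("associations", function(object) standardGeneric("associations"))

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(object) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("fpRate", function(object) standardGeneric("fpRate"))

#' @rdname accessors
#' @export
setGeneric("similarity", function(object) standardGeneric("similarity"))

# ---- methods ----

#' @rdname accessors
setMethod("signatures", "SignatureCollection", function(object) object@signatures)

#' @rdname accessors
setMethod("chemicalIds", "SignatureCollection",
          function(object) names(object@signatures))

#' @rdname accessors
setMethod("chemicalNames", "SignatureCollection",
          function(object) object@chemicalNames)

#' @rdname accessors
setMethod("geneUniverse", "SignatureCollection",
          function(object) object@geneUniverse)

#' @rdname accessors
setMethod("minGenes", "SignatureCollection", function(object) object@minGenes)

#' @rdname accessors
setMethod("universeGenes", "GeneUniverse", function(object) object@genes)

#' @rdname accessors
setMethod("predictions", "PredictionList", function(object) object@records)

#' @rdname accessors
setMethod("deGenes", "PredictionList", function(object) object@deGenes)

#' @rdname accessors
setMethod("universeGenes", "PredictionList",
          function(object) object@universe@genes)

#' @rdname accessors
setMethod("calledGenes", "DEResult", function(object) object@called)

#' @rdname accessors
setMethod("medianFdr", "DEResult", function(object) object@medianFdr)

#' @rdname accessors
setMethod("associations", "DiseaseChemicalMap",
          function(object) object@associations)

#' @rdname accessors
setMethod("diseaseIds", "DiseaseChemicalMap",
          function(object) names(object@associations))

#' @rdname accessors
setMethod("fpRate", "FPAssessment", function(object) object@fpRate)

#' @rdname accessors
setMethod("similarity", "BioactivitySimilarity",
          function(object) object@similarity)

# ---- show methods ----

setMethod("show", "SignatureCollection", function(object) {
  sizes <- lengths(object@signatures)
  cat("SignatureCollection with", length(object@signatures),
      "chemical-gene sets (minGenes =", object@minGenes, ")\n")
  cat("  gene universe:", length(object@geneUniverse), "genes\n")
  if (length(sizes))
    cat("  set sizes: median", stats::median(sizes), "range",
        min(sizes), "-", max(sizes), "\n")
  cat("  chemicals dropped by size filter:", object@dropped, "\n")
})

setMethod("show", "HomologyTable", function(object) {
  cat("HomologyTable with", length(unique(object@members$group)), "groups,",
      length(object@index), "index keys\n")
  cat("  conflicts resolved by first occurrence:", object@conflicts,
      "; malformed rows skipped:", object@skipped, "\n")
})

setMethod("show", "DiseaseChemicalMap", function(object) {
  cat("DiseaseChemicalMap with", length(object@associations), "diseases,",
      sum(lengths(object@associations)), "disease-chemical associations\n")
})

setMethod("show", "GeneUniverse", function(object) {
  cat("GeneUniverse with", length(object@genes), "genes (",
      object@source, ")\n")
})

setMethod("show", "DEResult", function(object) {
  cat("DEResult:", length(object@called), "of", length(object@statistic),
      "genes called (delta =", signif(object@delta, 3),
      ", s0 =", signif(object@s0, 3), ")\n")
  cat("  median FDR:", signif(object@medianFdr, 3), "over",
      object@nPermutations, "label permutations\n")
})

setMethod("show", "PredictionList", function(object) {
  r <- object@records
  cat("PredictionList over", nrow(r), "chemical-gene sets;",
      length(object@deGenes), "DE genes tested against",
      length(object@universe@genes), "universe genes\n")
  if (nrow(r)) {
    top <- head(r[, c("chemicalId", "p", "rank", "percentile", "q", "k", "K")], 5)
    print(top, row.names = FALSE)
  }
})

setMethod("show", "NullEnsemble", function(object) {
  cat("NullEnsemble:", object@B, "resamplings of", object@n,
      "genes from a", object@universeSize, "gene universe, scored against",
      ncol(object@pvalues), "signatures\n")
})

setMethod("show", "FPAssessment", function(object) {
  cat("FPAssessment at alpha =", object@alpha, "for",
      object@trueDiseaseId, "\n")
  cat("  eligible diseases:", nrow(object@records),
      "; competitors with lower p:", object@nBetter,
      "; fp rate:", signif(object@fpRate, 3), "\n")
})

setMethod("show", "BioactivitySimilarity", function(object) {
  cat("BioactivitySimilarity over", nrow(object@similarity), "chemicals (",
      object@provenance, "),", sum(object@mask), "masked pairs\n")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario (seed", object@manifest$seed, ")\n")
  cat("  collection:", length(object@collection@signatures), "signatures;",
      "expression:", nrow(object@expression), "genes x",
      ncol(object@expression), "samples\n")
  cat("  planted chemical(s):", paste(object@plantedChemicals, collapse = ", "),
      "with", length(object@plantedGenes), "shifted genes;",
      "planted disease:", object@plantedDisease, "\n")
})
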