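#' Select chemicals passing a significance threshold
#'
#' @param observed a [PredictionList-class].
#' @param alpha p-value threshold; chemicals with \code{p <= alpha} are
#'   selected. Nested thresholds give nested selections.
#' @return character vector of chemical ids.
#' @export
selectChemicals <- function(observed, alpha) {
  stopifnot(is(observed, "PredictionList"))
  rec <- observed@records
  rec$chemicalId[rec$p <= alpha]
}

#' Curated disease-chemical enrichment of a selected chemical set
#'
#' Tests whether chemicals selected from a prediction list are enriched for
#' a disease's curated chemical set, with the upper-tail hypergeometric test
#' over the chemical universe: N = |universe|, K = |curated in universe|,
#' n = |selected|, k = |selected in curated|. A disease with no curated
#' chemical inside the universe gets p = 1 and zero overlap.
#'
#' @param selected character vector of selected chemical ids (must lie in
#'   \code{chemicalUniverse}).
#' @param diseaseId disease to test (must be present in \code{map}).
#' @param map a [DiseaseChemicalMap-class].
#' @param chemicalUniverse character, the chemicals that could have been
#'   selected (normally the signature collection's chemicals).
#' @return one-row data.frame: diseaseId, diseaseName, nSelected, nOverlap,
#'   curatedSize (in universe), fractionOfCurated (overlap over all curated
#'   associations for the disease), p, and the overlapping chemicals as a
#'   comma-separated string.
#' @export
diseaseEnrichment <- function(selected, diseaseId, map, chemicalUniverse) {
  stopifnot(is(map, "DiseaseChemicalMap"))
  if (!diseaseId %in% names(map@associations))
    stop("disease not present in the map: ", diseaseId)
  chemicalUniverse <- unique(as.character(chemicalUniverse))
  selected <- unique(as.character(selected))
  if (!all(selected %in% chemicalUniverse))
    stop("selected chemicals must lie within the chemical universe")
  curated <- map@associations[[diseaseId]]
  curatedU <- intersect(curated, chemicalUniverse)
  ovl <- intersect(selected, curatedU)
  N <- length(chemicalUniverse); K <- length(curatedU)
  n <- length(selected); k <- length(ovl)
  p <- if (K == 0 || n == 0) 1 else hypergeomUpper(N, K, n, k)
  data.frame(diseaseId = diseaseId,
             diseaseName = unname(map@diseaseNames[diseaseId]),
             nSelected = n, nOverlap = k, curatedSize = K,
             fractionOfCurated = k / max(1, length(curated)),
             p = p,
             overlapChemicals = paste(sort(ovl), collapse = ","),
             stringsAsFactors = FALSE)
}

#' False-positive assessment across all eligible diseases
#'
#' Repeats the curated enrichment test of [diseaseEnrichment()] for every
#' disease with at least \code{minChemicals} curated associations, at a
#' fixed selection threshold \code{alpha}, and counts the diseases whose
#' enrichment p is strictly lower than the true disease's (ties do not count
#' against). The false-positive rate is that count over the number of
#' eligible competitor diseases.
#'
#' @param observed a [PredictionList-class].
#' @param trueDiseaseId the disease the expression dataset represents.
#' @param map a [DiseaseChemicalMap-class].
#' @param alpha selection threshold on the chemical p-values.
#' @param minChemicals eligibility floor on curated set size (default 5).
#' @param chemicalUniverse chemicals that could have been selected; defaults
#'   to all chemicals in the prediction list (the tested collection).
#' @return an [FPAssessment-class].
#' @export
fpAssessment <- function(observed, trueDiseaseId, map, alpha,
                         minChemicals = 5, chemicalUniverse = NULL) {
  stopifnot(is(observed, "PredictionList"), is(map, "DiseaseChemicalMap"))
  minChemicals <- .assertCount(minChemicals, "minChemicals", min = 1L)
  if (is.null(chemicalUniverse))
    chemicalUniverse <- observed@records$chemicalId
  eligible <- names(map@associations)[lengths(map@associations) >=
                                        minChemicals]
  if (!trueDiseaseId %in% eligible)
    stop("true disease ", trueDiseaseId, " is not eligible (needs >= ",
         minChemicals, " curated chemicals)")
  selected <- intersect(selectChemicals(observed, alpha), chemicalUniverse)
  rows <- lapply(eligible, function(d)
    diseaseEnrichment(selected, d, map, chemicalUniverse))
  rec <- do.call(rbind, rows)
  pTrue <- rec$p[rec$diseaseId == trueDiseaseId]
  nBetter <- sum(rec$p < pTrue & rec$diseaseId != trueDiseaseId)
  rec <- rec[order(rec$p, rec$diseaseId), , drop = FALSE]
  rownames(rec) <- NULL
  new("FPAssessment", trueDiseaseId = trueDiseaseId, alpha = alpha,
      records = rec, nBetter = as.integer(nBetter),
      fpRate = nBetter / max(1L, length(eligible) - 1L))
}
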