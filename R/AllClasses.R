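#' @import methods
#' @importFrom stats median phyper quantile rlnorm rnorm rgeom cor hclust
#'   as.dist cutree
#' @importFrom utils combn read.delim write.table head
NULL

#' SignatureCollection: the chemical-gene-set prediction database
#'
#' One gene set ("signature") per chemical, with per-gene citation support:
#' for every gene the number of distinct literature citations backing the
#' chemical-gene relation, pooled across organisms. Signatures smaller than
#' \code{minGenes} are removed at build time and never reappear downstream.
#'
#' @slot signatures named list; one element per chemical, each a named
#'   integer vector mapping gene (group-space id) to its citation count.
#' @slot chemicalNames named character, chemical id -> display name.
#' @slot minGenes integer(1), the minimum signature size enforced at build.
#' @slot geneUniverse character, union of all member genes.
#' @slot dropped integer(1), number of chemicals removed by the size filter.
#' @seealso [buildSignatures()], [enrichAll()]
#' @export
setClass("SignatureCollection", representation(
  signatures = "list",
  chemicalNames = "character",
  minGenes = "integer",
  geneUniverse = "character",
  dropped = "integer"
))

setValidity("SignatureCollection", function(object) {
  sig <- object@signatures
  if (length(sig) && is.null(names(sig)))
    return("signatures must be a named list keyed by chemical id")
  if (anyDuplicated(names(sig)))
    return("duplicate chemical ids in signatures")
  sizes <- lengths(sig)
  if (length(sig) && any(sizes < object@minGenes))
    return("a signature is smaller than minGenes")
  for (s in sig) {
    if (is.null(names(s)) || any(s < 1))
      return("each signature must map gene -> citation count >= 1")
  }
  uni <- unique(unlist(lapply(sig, names), use.names = FALSE))
  if (!setequal(uni, object@geneUniverse))
    return("geneUniverse does not equal the union of member gene sets")
  TRUE
})

#' HomologyTable: cross-species ortholog-group index
#'
#' Maps (taxon, gene symbol or gene id) pairs into a shared group-id
#' namespace, Homologene style. Each (taxon, gene) key belongs to at most one
#' group; conflicting rows are resolved by first occurrence and counted.
#'
#' @slot members data.frame with columns group, taxon, geneId, symbol (one
#'   row per retained group member).
#' @slot index named character, lookup key -> group id. Keys are
#'   \code{"<taxon>:<SYMBOL>"} (symbols upper-cased), \code{"id:<taxon>:<geneId>"},
#'   and every group id mapped to itself so that mapping is idempotent.
#' @slot conflicts integer(1), rows discarded by the first-occurrence rule.
#' @slot skipped integer(1), malformed rows skipped during parsing.
#' @seealso [parseHomology()], [toGroupSpace()]
#' @export
setClass("HomologyTable", representation(
  members = "data.frame",
  index = "character",
  conflicts = "integer",
  skipped = "integer"
))

setValidity("HomologyTable", function(object) {
  if (length(object@index) && is.null(names(object@index)))
    return("index must be named")
  if (anyDuplicated(names(object@index)))
    return("duplicate keys in homology index")
  TRUE
})

#' DiseaseChemicalMap: curated disease-to-chemical associations
#'
#' @slot associations named list, disease id (MeSH) -> character vector of
#'   chemical ids (no empty sets, no duplicate members).
#' @slot diseaseNames named character, disease id -> label.
#' @seealso [parseDiseaseMap()], [diseaseEnrichment()]
#' @export
setClass("DiseaseChemicalMap", representation(
  associations = "list",
  diseaseNames = "character"
))

setValidity("DiseaseChemicalMap", function(object) {
  a <- object@associations
  if (length(a) && is.null(names(a))) return("associations must be named")
  if (any(lengths(a) == 0)) return("empty chemical set for a disease")
  if (any(vapply(a, anyDuplicated, 0L) > 0))
    return("duplicate chemical within a disease set")
  TRUE
})

#' GeneUniverse: the eligible gene space of an enrichment run
#'
#' Houses N of the hypergeometric test. By default the universe is the
#' intersection of the expression platform's genes (in group space) with the
#' signature collection's gene universe, so genes that can never overlap any
#' signature do not inflate significance.
#'
#' @slot genes character, the eligible group-space gene ids (sorted, unique).
#' @slot source character(1), how the universe was derived.
#' @seealso [buildUniverse()]
#' @export
setClass("GeneUniverse", representation(
  genes = "character",
  source = "character"
))

setValidity("GeneUniverse", function(object) {
  if (length(object@genes) == 0) return("universe is empty")
  if (anyDuplicated(object@genes)) return("duplicate genes in universe")
  TRUE
})

#' DEResult: differential expression call from the permutation d-statistic
#'
#' @slot statistic named numeric, per-gene moderated d.
#' @slot s0 numeric(1), exchangeability constant added to the pooled standard
#'   error denominator.
#' @slot delta numeric(1), threshold on the deviation of ordered observed d
#'   from the permutation-averaged expected order statistics.
#' @slot called character, gene ids called differentially expressed.
#' @slot medianFdr numeric(1) in [0,1], median over permutations of the
#'   number of permuted statistics beyond the cutoffs divided by the number
#'   of called genes (pi0 fixed at 1).
#' @slot nPermutations integer(1), label permutations actually used.
#' @slot cutoffs numeric(2), lower and upper d cutoffs (-Inf/Inf when a side
#'   is inactive).
#' @slot provenance list of run metadata (seed, s0 policy, enumeration mode,
#'   delta grid when selected automatically).
#' @seealso [callGenes()], [selectDelta()]
#' @export
setClass("DEResult", representation(
  statistic = "numeric",
  s0 = "numeric",
  delta = "numeric",
  called = "character",
  medianFdr = "numeric",
  nPermutations = "integer",
  cutoffs = "numeric",
  provenance = "list"
))

setValidity("DEResult", function(object) {
  if (!all(object@called %in% names(object@statistic)))
    return("called genes must be a subset of the scored genes")
  if (object@medianFdr < 0 || object@medianFdr > 1)
    return("medianFdr must lie in [0,1]")
  TRUE
})

#' PredictionList: ranked chemical enrichment results for one dataset
#'
#' One record per signature in the collection, ordered by ascending
#' hypergeometric p (ties broken by chemical id), with rank, percentile
#' label, the test's (N, K, n, k), overlap genes with citation counts, and
#' (after [qValues()]) the resampling q-value.
#'
#' @slot records data.frame with columns chemicalId, chemicalName, p, k, K,
#'   n, N, rank, percentile, q, overlapGenes (list column of named integer
#'   vectors).
#' @slot universe [GeneUniverse-class] the test was run against.
#' @slot deGenes character, the differentially expressed genes actually
#'   tested (after universe intersection).
#' @slot provenance list of run metadata.
#' @seealso [enrichAll()], [qValues()], [callPositive()]
#' @export
setClass("PredictionList", representation(
  records = "data.frame",
  universe = "GeneUniverse",
  deGenes = "character",
  provenance = "list"
))

setValidity("PredictionList", function(object) {
  r <- object@records
  need <- c("chemicalId", "chemicalName", "p", "k", "K", "n", "N",
            "rank", "percentile", "q")
  if (!all(need %in% names(r)))
    return(paste("records missing columns:",
                 paste(setdiff(need, names(r)), collapse = ", ")))
  if (nrow(r)) {
    if (!identical(r$rank, seq_len(nrow(r))))
      return("ranks must be 1..nrow without gaps, in order")
    if (is.unsorted(r$p)) return("p must be non-decreasing with rank")
    if (any(r$k > pmin(r$K, r$n))) return("k exceeds min(K, n)")
  }
  TRUE
})

#' NullEnsemble: resampled null p-values for q-value estimation
#'
#' B seeded random gene draws of the observed DE-list size, each scored
#' against every signature with the same hypergeometric test as the observed
#' list (GoMiner-style resampling null).
#'
#' @slot pvalues B x n_chemicals numeric matrix of null p-values, columns
#'   named by chemical id in collection order.
#' @slot n integer(1), resample size (the observed DE-list size).
#' @slot B integer(1), number of resamplings.
#' @slot seed integer(1) or NA, RNG seed used for the draws.
#' @slot universeSize integer(1), |universe| the draws were taken from.
#' @seealso [buildNull()], [qValues()]
#' @export
setClass("NullEnsemble", representation(
  pvalues = "matrix",
  n = "integer",
  B = "integer",
  seed = "integer",
  universeSize = "integer"
))

setValidity("NullEnsemble", function(object) {
  p <- object@pvalues
  if (nrow(p) != object@B) return("pvalues must have B rows")
  if (is.null(colnames(p))) return("pvalues columns must be named by chemical")
  if (any(p <= 0) || any(p > 1)) return("null p-values must lie in (0,1]")
  TRUE
})

#' FPAssessment: false-positive sweep across curated diseases
#'
#' For a fixed prediction list and selection threshold alpha, the curated
#' disease-chemical enrichment of every eligible disease (>= minChemicals
#' curated associations), the number with p strictly below the true
#' disease's, and the implied false-positive rate.
#'
#' @slot trueDiseaseId character(1).
#' @slot alpha numeric(1), selection threshold on the chemical p-values.
#' @slot records data.frame, one row per eligible disease, sorted by p.
#' @slot nBetter integer(1), competitor diseases with strictly lower p.
#' @slot fpRate numeric(1), nBetter / (number of eligible diseases - 1).
#' @seealso [fpAssessment()]
#' @export
setClass("FPAssessment", representation(
  trueDiseaseId = "character",
  alpha = "numeric",
  records = "data.frame",
  nBetter = "integer",
  fpRate = "numeric"
))

setValidity("FPAssessment", function(object) {
  if (object@fpRate < 0 || object@fpRate > 1)
    return("fpRate must lie in [0,1]")
  if (!object@trueDiseaseId %in% object@records$diseaseId)
    return("true disease missing from records")
  TRUE
})

#' BioactivitySimilarity: pairwise chemical bioactivity similarity
#'
#' Square symmetric matrix in [-1, 1] with unit diagonal, either computed
#' from a chemical x assay score matrix (pairwise correlation over co-assayed
#' entries) or supplied precomputed. Pairs whose similarity could not be
#' estimated (too few shared assays) are zeroed and flagged in \code{mask}.
#'
#' @slot similarity numeric matrix, chemicals x chemicals.
#' @slot mask logical matrix, TRUE where similarity was not estimable.
#' @slot provenance character(1), "computed" or "provided".
#' @seealso [similarityFromScores()], [clusterOrder()]
#' @export
setClass("BioactivitySimilarity", representation(
  similarity = "matrix",
  mask = "matrix",
  provenance = "character"
))

setValidity("BioactivitySimilarity", function(object) {
  s <- object@similarity
  if (nrow(s) != ncol(s)) return("similarity must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    return("similarity must carry identical row and column chemical names")
  if (max(abs(s - t(s))) > 1e-8) return("similarity must be symmetric")
  if (any(abs(diag(s) - 1) > 1e-8)) return("diagonal must be 1")
  if (any(s < -1 - 1e-8) || any(s > 1 + 1e-8))
    return("similarities must lie in [-1,1]")
  TRUE
})

#' SyntheticScenario: a complete seeded synthetic study
#'
#' Bundles a synthetic interaction table, homology table, expression matrix
#' with a planted chemical signature shifted in the case class, and a disease
#' map with a planted disease, together with a manifest of every generating
#' parameter (sufficient to regenerate the scenario bit-identically).
#'
#' @slot interactions data.frame of interaction records (the
#'   [parseInteractions()] layout).
#' @slot homology [HomologyTable-class].
#' @slot expression SummarizedExperiment (assay "exprs", rowData symbol and
#'   taxon, colData condition in case/control).
#' @slot collection [SignatureCollection-class] built from the interactions.
#' @slot diseaseMap [DiseaseChemicalMap-class].
#' @slot plantedChemicals character, chemicals whose signature genes were
#'   shifted in cases.
#' @slot plantedGenes character, group-space ids of the shifted genes.
#' @slot plantedDisease character(1), disease whose curated set contains the
#'   planted chemicals.
#' @slot manifest list of all generator parameters, the seed, and bookkeeping
#'   counts.
#' @seealso [simulateScenario()]
#' @export
setClass("SyntheticScenario", representation(
  interactions = "data.frame",
  homology = "HomologyTable",
  expression = "ANY",
  collection = "SignatureCollection",
  diseaseMap = "DiseaseChemicalMap",
  plantedChemicals = "character",
  plantedGenes = "character",
  plantedDisease = "character",
  manifest = "list"
))
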