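#' Build the resampling null ensemble
#'
#' Draws B random gene subsets of the observed DE-list size (without
#' replacement, mirroring the hypergeometric sampling model) from the
#' universe and scores each draw against every signature with the same
#' upper-tail hypergeometric test as the observed list. The resulting
#' B x chemicals matrix of null p-values drives the q-value estimate.
#'
#' @param universe a [GeneUniverse-class].
#' @param n resample size, the observed DE-list size (\code{n <= |universe|}).
#' @param collection a [SignatureCollection-class].
#' @param B number of resamplings (default 100).
#' @param seed RNG seed; two runs with the same seed are identical.
#' @return a [NullEnsemble-class].
#' @export
buildNull <- function(universe, n, collection, B = 100, seed = NULL) {
  stopifnot(is(universe, "GeneUniverse"),
            is(collection, "SignatureCollection"))
  n <- .assertCount(n, "n", min = 1L)
  B <- .assertCount(B, "B", min = 1L)
  uni <- universe@genes
  if (n > length(uni))
    stop("resample size n = ", n, " exceeds the universe (",
         length(uni), " genes)")
  M <- .signatureMatrix(collection, uni)
  K <- as.integer(Matrix::colSums(M))
  ind <- .withSeed(seed, {
    out <- matrix(0, length(uni), B)
    for (b in seq_len(B)) out[sample.int(length(uni), n), b] <- 1
    out
  })
  kmat <- as.matrix(Matrix::crossprod(M, ind))      # chemicals x B
  pm <- phyper(kmat - 1, K, length(uni) - K, n, lower.tail = FALSE)
  pm <- pmin(pmax(pm, 0), 1)
  pvalues <- t(pm)
  colnames(pvalues) <- names(collection@signatures)
  new("NullEnsemble", pvalues = pvalues, n = n, B = B,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      universeSize = length(uni))
}

#' Fill resampling q-values into a prediction list
#'
#' For each observed p, the raw q is the average number of null p-values at
#' or below it per resampling, divided by the number of observed p-values at
#' or below it; clamped to [0, 1] and made monotone non-decreasing in p by a
#' cumulative minimum from the largest p downward.
#'
#' @param observed a [PredictionList-class] from [enrichAll()].
#' @param ensemble a [NullEnsemble-class] built with the same collection and
#'   universe.
#' @return the prediction list with the \code{q} column filled.
#' @export
qValues <- function(observed, ensemble) {
  stopifnot(is(observed, "PredictionList"), is(ensemble, "NullEnsemble"))
  rec <- observed@records
  if (!setequal(rec$chemicalId, colnames(ensemble@pvalues)))
    stop("ensemble was built against a different signature collection")
  if (ensemble@universeSize != length(observed@universe@genes))
    stop("ensemble was built against a different universe")
  p <- rec$p                               # non-decreasing by construction
  nullSorted <- sort(as.vector(ensemble@pvalues))
  nullCount <- findInterval(p, nullSorted)       # ties included
  obsCount <- findInterval(p, p)                 # ties included
  q <- (nullCount / ensemble@B) / pmax(1, obsCount)
  q <- pmin(pmax(q, 0), 1)
  q <- rev(cummin(rev(q)))
  rec$q <- q
  observed@records <- rec
  observed@provenance$B <- ensemble@B
  observed@provenance$nullSeed <- ensemble@seed
  observed
}

#' Positive-prediction rule
#'
#' A chemical is called a positive prediction when its enrichment p-value is
#' at or below \code{alpha} and its resampling q-value is strictly below
#' \code{qMax} (default 0.1).
#'
#' @param observed a [PredictionList-class] with q filled (see [qValues()]).
#' @param alpha p-value threshold.
#' @param qMax q-value gate (default 0.1).
#' @return logical vector aligned with \code{predictions(observed)} rows.
#' @export
callPositive <- function(observed, alpha, qMax = 0.1) {
  stopifnot(is(observed, "PredictionList"))
  rec <- observed@records
  if (anyNA(rec$q)) stop("q-values are not filled; run qValues() first")
  rec$p <= alpha & rec$q < qMax
}
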