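#' Upper-tail hypergeometric probability
#'
#' Probability that a random draw of \code{n} genes from an \code{N}-gene
#' universe contains at least \code{k} of a \code{K}-gene set:
#' \deqn{p = \sum_{j=k}^{\min(n,K)} \frac{{K \choose j}{N-K \choose n-j}}{{N \choose n}}}
#' Evaluated through \code{stats::phyper} (log-space internally, numerically
#' stable); \code{p = 1} when \code{k = 0}. Vectorized over all arguments.
#'
#' @param N universe size.
#' @param K genes in the set (\code{K <= N}).
#' @param n genes drawn (\code{n <= N}).
#' @param k overlap observed (\code{0 <= k <= min(n, K)}).
#' @return p in (0, 1].
#' @examples
#' hypergeomUpper(10, 4, 5, 3)  # 66/252
#' @export
hypergeomUpper <- function(N, K, n, k) {
  len <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(as.numeric(N), len); K <- rep_len(as.numeric(K), len)
  n <- rep_len(as.numeric(n), len); k <- rep_len(as.numeric(k), len)
  for (nm in c("N", "K", "n", "k")) {
    v <- get(nm)
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
      stop("argument '", nm, "' must contain non-negative integers")
  }
  if (any(K > N)) stop("argument 'K' exceeds N")
  if (any(n > N)) stop("argument 'n' exceeds N")
  if (any(k > pmin(n, K))) stop("argument 'k' exceeds min(n, K)")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Build the eligible gene universe for enrichment
#'
#' The universe houses N of the hypergeometric test. Policy
#' \code{"intersection"} (default) restricts to platform genes that appear
#' in at least one signature, so genes that can never overlap any signature
#' do not inflate significance; \code{"platform"} uses every platform gene.
#'
#' @param platformGenes character, the expression platform's genes in group
#'   space.
#' @param collection a [SignatureCollection-class].
#' @param policy \code{"intersection"} or \code{"platform"}.
#' @return a [GeneUniverse-class].
#' @export
buildUniverse <- function(platformGenes, collection,
                          policy = c("intersection", "platform")) {
  policy <- match.arg(policy)
  platformGenes <- unique(as.character(platformGenes))
  genes <- switch(policy,
                  intersection = intersect(platformGenes,
                                           collection@geneUniverse),
                  platform = platformGenes)
  if (!length(genes))
    stop("empty universe: the platform shares no genes with the collection")
  new("GeneUniverse", genes = sort(genes),
      source = paste0(policy, " (platform ", length(platformGenes),
                      " genes, collection ",
                      length(collection@geneUniverse), " genes)"))
}

# sparse gene x chemical membership matrix restricted to the universe
.signatureMatrix <- function(collection, uni) {
  sigGenes <- lapply(collection@signatures,
                     function(s) names(s)[names(s) %in% uni])
  j <- rep.int(seq_along(sigGenes), lengths(sigGenes))
  i <- match(unlist(sigGenes, use.names = FALSE), uni)
  Matrix::sparseMatrix(i = i, j = j,
                       dims = c(length(uni), length(sigGenes)),
                       x = 1)
}

#' Score every chemical signature for DE-gene over-representation
#'
#' For each signature, tests whether the differentially expressed gene list
#' contains more of the signature's genes than expected at random, with the
#' upper-tail hypergeometric test over the shared universe. Signatures are
#' restricted to the universe for K; DE genes outside the universe are
#' dropped (and counted in provenance). Results are sorted by ascending p
#' with stable ties broken by chemical id, and carry rank, percentile label,
#' and the overlap genes with their citation counts.
#'
#' @param de character vector of DE genes (group space).
#' @param collection a [SignatureCollection-class].
#' @param universe a [GeneUniverse-class].
#' @return a [PredictionList-class]; q-values are NA until [qValues()].
#' @export
enrichAll <- function(de, collection, universe) {
  stopifnot(is(collection, "SignatureCollection"),
            is(universe, "GeneUniverse"))
  uni <- universe@genes
  de0 <- unique(as.character(de))
  de <- intersect(de0, uni)
  droppedDe <- length(de0) - length(de)
  if (!length(de))
    stop("no DE genes left after universe intersection; ",
         "review the DE threshold or universe policy")
  chems <- names(collection@signatures)
  if (!length(chems)) stop("empty signature collection")
  M <- .signatureMatrix(collection, uni)
  K <- as.integer(Matrix::colSums(M))
  ind <- as.numeric(uni %in% de)
  k <- as.integer(as.vector(Matrix::crossprod(M, ind)))
  N <- length(uni); n <- length(de)
  p <- hypergeomUpper(N, K, n, k)

  overlap <- vector("list", length(chems))
  hit <- which(k > 0)
  deSet <- de
  for (i in hit) {
    s <- collection@signatures[[i]]
    ov <- s[names(s) %in% deSet]
    overlap[[i]] <- ov[order(-ov, names(ov))]
  }
  ord <- order(p, chems)
  rec <- data.frame(
    chemicalId = chems[ord],
    chemicalName = unname(collection@chemicalNames[chems[ord]]),
    p = p[ord], k = k[ord], K = K[ord],
    n = rep.int(n, length(chems)), N = rep.int(N, length(chems)),
    rank = seq_along(chems),
    percentile = percentileLabel(seq_along(chems), length(chems)),
    q = rep(NA_real_, length(chems)),
    stringsAsFactors = FALSE)
  rec$overlapGenes <- overlap[ord]
  new("PredictionList", records = rec, universe = universe, deGenes = de,
      provenance = list(droppedDeGenes = droppedDe,
                        nSignatures = length(chems)))
}

#' Percentile label for a rank
#'
#' The report-table convention: \code{floor(100 * (1 - (rank - 1) / total))},
#' so rank 1 is the 100th percentile.
#'
#' @param rank integer rank(s), 1-based.
#' @param total list length.
#' @return integer percentile in 0-100.
#' @export
percentileLabel <- function(rank, total) {
  if (any(rank < 1) || any(rank > total))
    stop("rank must lie in 1..total")
  as.integer(floor(100 * (1 - (rank - 1) / total)))
}
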