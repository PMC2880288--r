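#' Bioactivity similarity from a chemical x assay score matrix
#'
#' Pairwise Pearson correlation over co-assayed (both non-missing) entries,
#' a transparent stand-in for server-side bioactivity-similarity tools.
#' Pairs sharing fewer than \code{minShared} assays (or with undefined
#' correlation) are set to 0 and flagged in the mask. Chemicals with no
#' scores at all are dropped with a warning.
#'
#' @param scores numeric matrix, chemicals x assays, NAs allowed.
#' @param minShared minimum co-assayed entries per pair (>= 2).
#' @return a [BioactivitySimilarity-class].
#' @export
similarityFromScores <- function(scores, minShared = 2) {
  minShared <- .assertCount(minShared, "minShared", min = 2L)
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- sprintf("chem%03d", seq_len(nrow(scores)))
  keep <- rowSums(!is.na(scores)) > 0
  if (any(!keep)) {
    warning(sum(!keep), " chemical(s) without any score dropped: ",
            paste(rownames(scores)[!keep], collapse = ", "))
    scores <- scores[keep, , drop = FALSE]
  }
  if (nrow(scores) < 2) stop(">= 2 chemicals with scores are required")
  shared <- tcrossprod((!is.na(scores)) * 1)
  sim <- suppressWarnings(cor(t(scores), use = "pairwise.complete.obs"))
  mask <- shared < minShared | !is.finite(sim)
  sim[mask] <- 0
  diag(sim) <- 1
  diag(mask) <- FALSE
  sim <- (sim + t(sim)) / 2
  mask <- mask | t(mask)
  new("BioactivitySimilarity", similarity = sim, mask = mask,
      provenance = "computed")
}

#' Wrap a precomputed similarity matrix
#'
#' Accepts a square symmetric matrix in [-1, 1] (e.g. exported from an
#' external bioactivity comparison service) verbatim as the primary input
#' path for clustering.
#'
#' @param mat square numeric matrix with identical row/column chemical
#'   names; small asymmetries (< 1e-8) are averaged out.
#' @return a [BioactivitySimilarity-class].
#' @export
asSimilarity <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) && !is.null(colnames(mat)))
    rownames(mat) <- colnames(mat)
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 1
  new("BioactivitySimilarity", similarity = mat,
      mask = matrix(FALSE, nrow(mat), ncol(mat),
                    dimnames = dimnames(mat)),
      provenance = "provided")
}

#' Order chemicals by agglomerative bioactivity clustering
#'
#' Hierarchical clustering on distance \code{1 - similarity}; the leaf order
#' is deterministic given the input order.
#'
#' @param sim a [BioactivitySimilarity-class].
#' @param linkage agglomeration method (default \code{"average"}).
#' @return list with \code{order} (chemical ids in leaf order) and
#'   \code{tree} (the \code{hclust} object).
#' @export
clusterOrder <- function(sim, linkage = "average") {
  stopifnot(is(sim, "BioactivitySimilarity"))
  s <- sim@similarity
  if (nrow(s) < 2) stop(">= 2 chemicals are required")
  hc <- hclust(as.dist(1 - s), method = linkage)
  list(order = rownames(s)[hc$order], tree = hc)
}

#' Export a clustering tree as Newick text
#'
#' @param tree an \code{hclust} object (from [clusterOrder()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeClusterTree <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Heatmap table of -log10 enrichment p-values across datasets
#'
#' Rows are chemicals in the supplied (typically bioactivity-clustered)
#' order; columns are datasets. A chemical absent from a dataset's
#' prediction list yields NA (masked), never 0.
#'
#' @param predLists named list of [PredictionList-class] objects, one per
#'   dataset.
#' @param chemicalOrder character vector of chemical ids (e.g. from
#'   [clusterOrder()]); defaults to the union in first-seen order. Chemicals
#'   present in no list are dropped with a warning.
#' @return numeric matrix of -log10(p), chemicals x datasets.
#' @export
heatmapTable <- function(predLists, chemicalOrder = NULL) {
  stopifnot(is.list(predLists), length(predLists) > 0)
  if (is.null(names(predLists)))
    names(predLists) <- sprintf("dataset%02d", seq_along(predLists))
  allChems <- unique(unlist(lapply(predLists,
                                   function(pl) pl@records$chemicalId)))
  if (is.null(chemicalOrder)) chemicalOrder <- allChems
  missing <- setdiff(chemicalOrder, allChems)
  if (length(missing)) {
    warning("chemicals absent from every prediction list dropped: ",
            paste(missing, collapse = ", "))
    chemicalOrder <- setdiff(chemicalOrder, missing)
  }
  out <- matrix(NA_real_, length(chemicalOrder), length(predLists),
                dimnames = list(chemicalOrder, names(predLists)))
  for (j in seq_along(predLists)) {
    rec <- predLists[[j]]@records
    hit <- match(chemicalOrder, rec$chemicalId)
    out[, j] <- -log10(rec$p[hit])
  }
  out
}
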