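#' Assemble a two-class expression experiment
#'
#' Thin constructor around \code{SummarizedExperiment} for a log-scale
#' gene x sample matrix with case/control labels.
#'
#' @param values numeric matrix, genes x samples (log-scale expression).
#' @param symbols per-row gene symbols (default rownames of \code{values}).
#' @param taxon integer taxon id for the platform (recycled per row).
#' @param labels per-column class, values in \code{c("case", "control")}.
#' @return a \code{SummarizedExperiment} with assay \code{"exprs"}, rowData
#'   columns \code{symbol} and \code{taxon}, and colData \code{condition}.
#' @export
makeExpressionExperiment <- function(values, symbols = rownames(values),
                                     taxon = 9606L, labels) {
  values <- as.matrix(values)
  if (is.null(symbols)) stop("gene symbols are required")
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("one class label per sample column is required")
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  if (anyDuplicated(symbols))
    stop("duplicate gene rows; aggregate the platform first")
  rownames(values) <- symbols
  if (is.null(colnames(values)))
    colnames(values) <- make.unique(labels, sep = "_")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    rowData = S4Vectors::DataFrame(symbol = symbols,
                                   taxon = rep_len(as.integer(taxon),
                                                   nrow(values))),
    colData = S4Vectors::DataFrame(
      condition = factor(labels, levels = c("control", "case")),
      row.names = colnames(values)))
}

# accept a SummarizedExperiment or a plain matrix + labels
.exprInput <- function(x, labels = NULL) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, 1)
    lab <- as.character(SummarizedExperiment::colData(x)$condition)
    if (is.null(lab)) stop("colData(x)$condition is required")
  } else {
    m <- as.matrix(x)
    if (is.null(labels)) stop("labels are required with a plain matrix")
    lab <- as.character(labels)
  }
  if (!all(lab %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  if (sum(lab == "case") < 2 || sum(lab == "control") < 2)
    stop(">= 2 samples per class are required for unpaired analysis")
  if (is.null(rownames(m))) rownames(m) <- sprintf("gene%06d", seq_len(nrow(m)))
  list(values = m, labels = lab)
}

# pooled standard error of the mean difference, unpaired two-class
.pooledSE <- function(values, caseCols) {
  n1 <- length(caseCols); n2 <- ncol(values) - n1
  ctrl <- setdiff(seq_len(ncol(values)), caseCols)
  m1 <- rowMeans(values[, caseCols, drop = FALSE])
  m2 <- rowMeans(values[, ctrl, drop = FALSE])
  ss1 <- rowSums((values[, caseCols, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, ctrl, drop = FALSE] - m2)^2)
  list(diff = m1 - m2,
       s = sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2)))
}

#' Moderated d-statistic for two-class expression data
#'
#' For each gene, the difference of class means divided by the pooled
#' standard error plus an exchangeability constant:
#' \code{d = (mean_case - mean_control) / (s + s0)} with
#' \code{s = sqrt((1/n1 + 1/n2) * (SS_case + SS_control) / (n1 + n2 - 2))}.
#' The constant \code{s0} damps the statistic for genes with tiny variance.
#'
#' @param x SummarizedExperiment (see [makeExpressionExperiment()]) or a
#'   numeric genes x samples matrix.
#' @param labels class labels when \code{x} is a matrix.
#' @param s0 exchangeability constant, \code{>= 0}.
#' @return named numeric vector of per-gene d values.
#' @examples
#' m <- rbind(g1 = c(3, 3, 1, 1))
#' dStatistic(m, labels = c("case", "case", "control", "control"), s0 = 0.5)
#' @export
dStatistic <- function(x, labels = NULL, s0) {
  if (!is.numeric(s0) || length(s0) != 1 || s0 < 0)
    stop("s0 must be a single number >= 0")
  inp <- .exprInput(x, labels)
  caseCols <- which(inp$labels == "case")
  ps <- .pooledSE(inp$values, caseCols)
  den <- ps$s + s0
  if (any(den == 0))
    stop("zero variance encountered with s0 = 0; supply a nonzero s0")
  structure(ps$diff / den, names = rownames(inp$values))
}

#' Choose the exchangeability constant s0
#'
#' Returns an order-statistic percentile of the per-gene pooled standard
#' errors (quantile type 1): the default is the 5th percentile, a simple,
#' transparent stand-in for fuller coefficient-of-variation tuning. The
#' chosen value is recorded in downstream [DEResult-class] provenance.
#'
#' @param s numeric vector of per-gene pooled standard errors.
#' @param percentile percentile in [0, 100]; 0 gives \code{min(s)}.
#' @return numeric(1), the s0 value.
#' @export
chooseS0 <- function(s, percentile = 5) {
  if (!length(s)) stop("empty s vector")
  if (percentile < 0 || percentile > 100)
    stop("percentile must lie in [0, 100]")
  unname(quantile(s, probs = percentile / 100, type = 1, names = FALSE))
}

# all label-permutation d statistics; complete enumeration of case-column
# assignments when choose(n, n1) <= 1000, else seeded Monte-Carlo draws
.samFit <- function(x, labels = NULL, nPermutations = 100, seed = NULL,
                    s0Percentile = 5, s0 = NULL) {
  inp <- .exprInput(x, labels)
  values <- inp$values
  caseCols <- which(inp$labels == "case")
  n1 <- length(caseCols); n <- ncol(values); n2 <- n - n1
  ps <- .pooledSE(values, caseCols)
  if (is.null(s0)) s0 <- chooseS0(ps$s, s0Percentile)
  if (all(ps$s + s0 == 0))
    stop("zero variance everywhere with s0 = 0; supply a nonzero s0")
  d <- structure(ps$diff / (ps$s + s0), names = rownames(values))

  total <- choose(n, n1)
  complete <- total <= 1000
  if (complete) {
    perms <- combn(n, n1)
  } else {
    nPermutations <- .assertCount(nPermutations, "nPermutations", min = 10L)
    perms <- .withSeed(seed, vapply(seq_len(nPermutations),
                                    function(i) sort(sample.int(n, n1)),
                                    integer(n1)))
  }
  P <- matrix(0, n, ncol(perms))
  P[cbind(as.vector(perms), rep(seq_len(ncol(perms)), each = n1))] <- 1
  sq <- values * values
  S1 <- values %*% P
  Q1 <- sq %*% P
  rs <- rowSums(values); rs2 <- rowSums(sq)
  m1 <- S1 / n1
  m2 <- (rs - S1) / n2
  ss1 <- Q1 - n1 * (m1 * m1); ss1[ss1 < 0] <- 0
  ss2 <- (rs2 - Q1) - n2 * (m2 * m2); ss2[ss2 < 0] <- 0
  si <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n - 2))
  permD <- (m1 - m2) / (si + s0)
  dsort <- sort(d)
  sortedPerm <- permD
  sortedPerm[] <- permD[order(col(permD), permD)]
  dbar <- rowMeans(sortedPerm)
  list(d = d, s0 = s0, permD = permD, dbar = dbar,
       dsort = dsort, dev = dsort - dbar,
       i0 = which.min(abs(dsort)),
       nPermutations = ncol(perms), complete = complete, seed = seed,
       s0Percentile = if (is.null(s0Percentile)) NA_real_ else s0Percentile)
}

# asymmetric cutoffs implied by a delta threshold: walking outward from the
# center, the first ordered d deviating from its expected order statistic by
# more than delta on each side
.cutsForDelta <- function(fit, delta) {
  upIdx <- which(fit$dev > delta); upIdx <- upIdx[upIdx >= fit$i0]
  loIdx <- which(fit$dev < -delta); loIdx <- loIdx[loIdx <= fit$i0]
  c(low = if (length(loIdx)) unname(fit$dsort[max(loIdx)]) else -Inf,
    up = if (length(upIdx)) unname(fit$dsort[min(upIdx)]) else Inf)
}

.applyCuts <- function(fit, cutLow, cutUp) {
  called <- names(fit$d)[fit$d >= cutUp | fit$d <= cutLow]
  counts <- 0
  if (is.finite(cutUp)) counts <- counts + colSums(fit$permD >= cutUp)
  if (is.finite(cutLow)) counts <- counts + colSums(fit$permD <= cutLow)
  mfdr <- if (length(called) == 0) 0 else
    min(1, median(counts) / length(called))
  list(called = called, cutUp = cutUp, cutLow = cutLow,
       medianFdr = mfdr, medianCount = median(counts))
}

# apply one delta threshold to a fitted permutation set
.applyDelta <- function(fit, delta) {
  cuts <- .cutsForDelta(fit, delta)
  .applyCuts(fit, cuts[["low"]], cuts[["up"]])
}

.deResult <- function(fit, delta, app) {
  new("DEResult", statistic = fit$d, s0 = fit$s0, delta = delta,
      called = app$called, medianFdr = app$medianFdr,
      nPermutations = as.integer(fit$nPermutations),
      cutoffs = c(lower = app$cutLow, upper = app$cutUp),
      provenance = list(seed = fit$seed, complete = fit$complete,
                        s0Percentile = fit$s0Percentile,
                        pi0 = 1))
}

#' Call differentially expressed genes at a fixed delta
#'
#' Sorted observed d values are compared with the permutation-averaged
#' expected order statistics; genes beyond the first deviation larger than
#' \code{delta} on either side of the center are called (asymmetric cut).
#' The median FDR is the median over permutations of the number of permuted
#' statistics beyond the same cutoffs, divided by the number of called genes
#' (pi0 fixed conservatively at 1).
#'
#' @inheritParams dStatistic
#' @param delta non-negative deviation threshold.
#' @param nPermutations Monte-Carlo permutations when complete enumeration
#'   exceeds 1000 assignments (>= 10).
#' @param seed RNG seed for Monte-Carlo permutations (unused when the
#'   enumeration is complete); results are deterministic given the seed.
#' @param s0Percentile percentile handed to [chooseS0()].
#' @param s0 optional explicit exchangeability constant (overrides the
#'   percentile policy).
#' @return a [DEResult-class].
#' @export
callGenes <- function(x, labels = NULL, delta, nPermutations = 100,
                      seed = NULL, s0Percentile = 5, s0 = NULL) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stop("delta must be a single number >= 0")
  fit <- .samFit(x, labels, nPermutations, seed, s0Percentile, s0)
  app <- .applyDelta(fit, delta)
  if (length(app$called) == 0)
    warning("no gene called at delta = ", delta,
            "; median FDR reported as 0")
  .deResult(fit, delta, app)
}

#' Select delta to meet a target median FDR
#'
#' Scans an increasing grid of delta values and returns the result for the
#' smallest delta whose median FDR is at or below \code{targetFdr} (the most
#' sensitive qualifying threshold). If no grid point qualifies, the most
#' stringent delta is returned with a warning.
#'
#' @inheritParams callGenes
#' @param targetFdr target median FDR (the pipeline controls its gene lists
#'   in the 0.05-0.07 range).
#' @param deltaGrid increasing numeric grid; by default 40 points spanning
#'   the observed deviations from the expected order statistics.
#' @return a [DEResult-class]; the grid and its FDR profile are stored in
#'   provenance.
#' @export
selectDelta <- function(x, labels = NULL, targetFdr = 0.05,
                        deltaGrid = NULL, nPermutations = 100, seed = NULL,
                        s0Percentile = 5, s0 = NULL) {
  if (!is.numeric(targetFdr) || targetFdr <= 0 || targetFdr >= 1)
    stop("targetFdr must lie in (0, 1)")
  fit <- .samFit(x, labels, nPermutations, seed, s0Percentile, s0)
  if (is.null(deltaGrid)) {
    hi <- max(abs(fit$dev)) * 1.05 + 1e-9
    deltaGrid <- seq(hi / 40, hi, length.out = 40)
  }
  deltaGrid <- sort(deltaGrid)
  # several deltas usually share the same implied cutoffs; count each
  # distinct cutoff pair only once
  cuts <- vapply(deltaGrid, function(dl) .cutsForDelta(fit, dl), numeric(2))
  key <- paste(cuts[1, ], cuts[2, ])
  uniq <- which(!duplicated(key))
  uniqApps <- lapply(uniq, function(i)
    .applyCuts(fit, cuts[1, i], cuts[2, i]))
  apps <- uniqApps[match(key, key[uniq])]
  fdrs <- vapply(apps, `[[`, 0, "medianFdr")
  ok <- which(fdrs <= targetFdr)
  if (length(ok)) {
    i <- ok[1]
  } else {
    i <- length(deltaGrid)
    warning("no delta on the grid met targetFdr = ", targetFdr,
            "; returning the most stringent grid point")
  }
  if (length(apps[[i]]$called) == 0)
    warning("no gene called at the selected delta = ", deltaGrid[i])
  res <- .deResult(fit, deltaGrid[i], apps[[i]])
  res@provenance$deltaGrid <- deltaGrid
  res@provenance$gridMedianFdr <- fdrs
  res@provenance$targetFdr <- targetFdr
  res
}

#' Read an expression TSV and sample-class file
#'
#' Expression layout: first column gene symbol, remaining columns samples.
#' Labels layout: two tab-separated columns (sample id, class) where class
#' is \code{case} or \code{control}.
#'
#' @param exprFile path to the expression TSV (gzip-transparent).
#' @param labelsFile path to the sample-class TSV.
#' @param taxon platform taxon id.
#' @return a \code{SummarizedExperiment}, see [makeExpressionExperiment()].
#' @export
readExpression <- function(exprFile, labelsFile, taxon = 9606L) {
  df <- .readTsv(exprFile)
  if (nrow(df) == 0) stop("empty expression file: ", exprFile)
  sym <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  lab <- .readTsv(labelsFile, header = FALSE)
  if (ncol(lab) < 2) stop("labels file needs two columns (sample, class)")
  cls <- structure(trimws(lab[[2]]), names = trimws(lab[[1]]))
  miss <- setdiff(colnames(vals), names(cls))
  if (length(miss))
    stop("samples without class labels: ", paste(miss, collapse = ", "))
  makeExpressionExperiment(vals, symbols = sym, taxon = taxon,
                           labels = unname(cls[colnames(vals)]))
}
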