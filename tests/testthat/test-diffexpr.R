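lab44 <- c(rep("case", 4), rep("control", 4))

test_that("the d-statistic matches its closed form and symmetries", {
  # hand computation: case {3,3}, control {1,1}, s0 = 0.5 -> s = 0, d = 4
  m <- rbind(g1 = c(3, 3, 1, 1))
  d <- dStatistic(m, labels = c("case", "case", "control", "control"),
                  s0 = 0.5)
  expect_equal(unname(d), 4)

  # identical case and control values give d = 0
  m2 <- rbind(g1 = c(2, 5, 2, 5))
  expect_equal(unname(dStatistic(m2, labels = c("case", "case",
                                                "control", "control"),
                                 s0 = 0.1))[1], 0)

  set.seed(1)
  x <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(sprintf("g%02d", 1:50)))
  d1 <- dStatistic(x, labels = lab44, s0 = 0.2)
  # negating all values negates every d
  expect_equal(dStatistic(-x, labels = lab44, s0 = 0.2), -d1)
  # swapping class labels negates every d
  expect_equal(dStatistic(x, labels = rev(lab44), s0 = 0.2), -d1)
  # permuting sample columns within a class changes nothing
  perm <- c(3, 1, 2, 4, 8, 5, 7, 6)
  expect_equal(dStatistic(x[, perm], labels = lab44, s0 = 0.2), d1)
  # zero variance with s0 = 0 is an instructive error
  expect_error(dStatistic(m, labels = c("case", "case", "control", "control"),
                          s0 = 0), "nonzero s0")
})

test_that("s0 selection follows the order-statistic percentile convention", {
  expect_equal(chooseS0(rep(2.5, 10), 50), 2.5)
  expect_equal(chooseS0(1:100, 5), 5)     # 5th order statistic
  expect_equal(chooseS0(c(4, 1, 9), 0), 1)
})

test_that("gene calling behaves at threshold extremes and is sample-order invariant", {
  set.seed(2)
  x <- matrix(rnorm(300 * 8), 300, 8,
              dimnames = list(sprintf("g%03d", 1:300)))
  # pure-noise matrix at a huge delta: nothing called, medianFdr 0
  expect_warning(res <- callGenes(x, labels = lab44, delta = 50),
                 "no gene called")
  expect_length(calledGenes(res), 0)
  expect_equal(medianFdr(res), 0)

  # reordering samples (labels attached) leaves the call unchanged
  res1 <- suppressWarnings(callGenes(x, labels = lab44, delta = 0.6))
  perm <- c(2, 4, 1, 3, 7, 5, 8, 6)
  res2 <- suppressWarnings(callGenes(x[, perm], labels = lab44[perm],
                                     delta = 0.6))
  expect_setequal(calledGenes(res1), calledGenes(res2))
  expect_equal(medianFdr(res1), medianFdr(res2))
  expect_equal(sort(res1@statistic), sort(res2@statistic))
})

test_that("spike-in recovery: a tuned delta recovers most shifted genes", {
  pool <- sprintf("GENE%04d", 1:2000)
  ge <- genExpression(pool[1:134], pool, effect = 2, fraction = 0.75,
                      seed = 31)                      # 100 shifted genes
  res <- callGenes(ge$expression, delta = 0.35)
  recall <- mean(ge$truth %in% calledGenes(res))
  expect_gte(recall, 0.8)
})

test_that("delta selection honors the target and its FDR profile declines", {
  pool <- sprintf("GENE%04d", 1:2000)
  ge <- genExpression(pool[1:134], pool, effect = 2, fraction = 0.75,
                      seed = 8)
  res <- selectDelta(ge$expression, targetFdr = 0.05)
  expect_lte(medianFdr(res), 0.05)
  expect_gt(length(calledGenes(res)), 0)
  # the selected delta is the smallest qualifying grid point
  prof <- res@provenance$gridMedianFdr
  grid <- res@provenance$deltaGrid
  expect_equal(res@delta, grid[which(prof <= 0.05)[1]])
  # median FDR declines along the grid (integer-count jitter aside)
  expect_true(all(diff(prof) <= 0.01))
  expect_lt(prof[length(prof)], prof[1])

  # an absurdly large single-point grid trivially qualifies with 0 called
  expect_warning(res0 <- selectDelta(ge$expression, targetFdr = 0.05,
                                     deltaGrid = 1e6),
                 "no gene called")
  expect_length(calledGenes(res0), 0)
})

test_that("expression IO round-trips through TSV files", {
  pool <- sprintf("G%03d", 1:40)
  ge <- genExpression(pool[1:10], pool, effect = 1, seed = 4)
  ep <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(ge$expression, ep, lp)
  back <- readExpression(ep, lp)
  expect_equal(SummarizedExperiment::assay(back, 1),
               SummarizedExperiment::assay(ge$expression, 1),
               tolerance = 1e-8)
  expect_equal(as.character(SummarizedExperiment::colData(back)$condition),
               as.character(SummarizedExperiment::colData(ge$expression)$condition))
})
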