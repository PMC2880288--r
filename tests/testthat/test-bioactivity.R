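test_that("similarity from scores matches correlation extremes and masks sparse pairs", {
  v <- c(1, 2, 3, 4, 5)
  scores <- rbind(a = v, b = v * 2 + 1, c = -v, d = c(1, NA, NA, NA, 2))
  sim <- similarityFromScores(scores, minShared = 2)
  s <- similarity(sim)
  expect_equal(s["a", "b"], 1)            # identical up to affine scale
  expect_equal(s["a", "c"], -1)           # anti-correlated
  expect_equal(diag(s), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(s, t(s))
  # d shares only 2 points with the others: kept at minShared = 2,
  # masked (and zeroed) at minShared = 3
  sim3 <- similarityFromScores(scores, minShared = 3)
  expect_true(sim3@mask["a", "d"])
  expect_equal(similarity(sim3)["a", "d"], 0)
  # a chemical with no scores at all is dropped with a warning
  expect_warning(s2 <- similarityFromScores(rbind(scores,
                                                  e = rep(NA_real_, 5))),
                 "without any score")
  expect_false("e" %in% rownames(similarity(s2)))
})

test_that("block-structured scores give higher within- than between-group similarity", {
  set.seed(12)
  base1 <- rnorm(40); base2 <- rnorm(40)
  mk <- function(base) base + rnorm(40, sd = 0.4)
  scores <- rbind(g1a = mk(base1), g1b = mk(base1), g1c = mk(base1),
                  g2a = mk(base2), g2b = mk(base2), g2c = mk(base2))
  s <- similarity(similarityFromScores(scores))
  within <- mean(c(s["g1a", "g1b"], s["g1a", "g1c"], s["g1b", "g1c"],
                   s["g2a", "g2b"], s["g2a", "g2c"], s["g2b", "g2c"]))
  between <- mean(s[c("g1a", "g1b", "g1c"), c("g2a", "g2b", "g2c")])
  expect_gt(within, between)

  # clustering separates the two planted blocks exactly (2-cut = truth)
  co <- clusterOrder(similarityFromScores(scores))
  cut2 <- cutree(co$tree, k = 2)
  expect_equal(length(unique(cut2[c("g1a", "g1b", "g1c")])), 1)
  expect_equal(length(unique(cut2[c("g2a", "g2b", "g2c")])), 1)
  expect_false(cut2[["g1a"]] == cut2[["g2a"]])
  # leaf order keeps each block contiguous
  pos <- match(names(cut2), co$order)
  expect_equal(diff(range(pos[cut2 == cut2[["g1a"]]])), 2)
})

test_that("clustering of two or three chemicals behaves deterministically", {
  s2 <- asSimilarity(matrix(c(1, 0.4, 0.4, 1), 2, 2,
                            dimnames = list(c("x", "y"), c("x", "y"))))
  co2 <- clusterOrder(s2)
  expect_setequal(co2$order, c("x", "y"))
  expect_equal(co2$tree$merge, matrix(c(-1, -2), 1, 2))
  # three chemicals with one clear pair: the pair sits adjacent
  m <- matrix(c(1, .9, .1, .9, 1, .1, .1, .1, 1), 3, 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  co3 <- clusterOrder(asSimilarity(m))
  expect_equal(abs(diff(match(c("p", "q"), co3$order))), 1)
  # newick export round-trips through ape
  path <- withr::local_tempfile(fileext = ".nwk")
  writeClusterTree(co3$tree, path)
  expect_setequal(ape::read.tree(path)$tip.label, c("p", "q", "r"))
})

test_that("heatmap tables carry -log10 p with masked absences", {
  st1 <- tinyEnrichmentSetting(seed = 1)
  st2 <- tinyEnrichmentSetting(nChem = 12, seed = 2)
  de1 <- universeGenes(st1$universe)[1:8]
  de2 <- universeGenes(st2$universe)[1:8]
  pl1 <- enrichAll(de1, st1$collection, st1$universe)
  pl2 <- enrichAll(de2, st2$collection, st2$universe)
  ht <- suppressWarnings(heatmapTable(list(one = pl1, two = pl2)))
  rec1 <- predictions(pl1)
  ch <- rec1$chemicalId[1]
  expect_equal(ht[ch, "one"], -log10(rec1$p[1]))
  onlyIn1 <- setdiff(rec1$chemicalId, predictions(pl2)$chemicalId)[1]
  expect_true(is.na(ht[onlyIn1, "two"]))
  # p = 0.001 renders as exactly 3
  fake <- pl1; fake@records$p[1] <- 0.001
  expect_equal(heatmapTable(list(x = fake))[fake@records$chemicalId[1], "x"], 3)
  # a supplied order permutes rows consistently with direct lookup
  ord <- rev(rownames(ht))
  ht2 <- suppressWarnings(heatmapTable(list(one = pl1, two = pl2),
                                       chemicalOrder = ord))
  expect_equal(ht2, ht[ord, ])
})
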