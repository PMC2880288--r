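test_that("generated set sizes meet the calibrated quantile targets", {
  gi <- genInteractions(2000, genePool = sprintf("G%04d", 1:5000), seed = 17)
  sizes <- gi$manifest$setSizes
  expect_lte(abs(median(sizes) - 2), 1)
  expect_lte(abs(quantile(sizes, 0.70, type = 1) - 5), 1)
  expect_lte(abs(quantile(sizes, 0.75, type = 1) - 7), 2)
  # roughly a third of chemicals survive the >= 5 filter at this scale
  expect_gt(mean(sizes >= 5), 0.2); expect_lt(mean(sizes >= 5), 0.45)
})

test_that("interaction generation is seeded and supports degenerate sizes", {
  pool <- sprintf("G%03d", 1:200)
  a <- genInteractions(50, genePool = pool, seed = 4)
  b <- genInteractions(50, genePool = pool, seed = 4)
  expect_identical(a$records, b$records)
  fixed <- genInteractions(30, genePool = pool, sizeMeanlog = log(5),
                           sizeSdlog = 0, seed = 1)
  expect_true(all(fixed$manifest$setSizes == 5))
  coll <- buildSignatures(fixed$records, minGenes = 5)
  expect_true(all(lengths(signatures(coll)) == 5))
})

test_that("expression generation plants exactly the documented fraction", {
  pool <- sprintf("G%03d", 1:500)
  ge <- genExpression(pool[1:20], pool, effect = 2, fraction = 0.75,
                      seed = 9)
  expect_length(ge$truth, 15)                     # floor(0.75 * 20)
  expect_true(all(ge$truth %in% pool[1:20]))
  # the planted shift is visible in the class means
  m <- SummarizedExperiment::assay(ge$expression, 1)
  lab <- SummarizedExperiment::colData(ge$expression)$condition
  gap <- rowMeans(m[ge$truth, lab == "case"]) -
    rowMeans(m[ge$truth, lab == "control"])
  expect_gt(mean(gap), 1)
  # a null scenario has an empty truth set
  null <- genExpression(pool[1:20], pool, effect = 0, seed = 9)
  expect_length(null$truth, 0)
  # different seeds differ in values but agree in truth size
  ge2 <- genExpression(pool[1:20], pool, effect = 2, fraction = 0.75,
                       seed = 10)
  expect_false(identical(SummarizedExperiment::assay(ge$expression, 1),
                         SummarizedExperiment::assay(ge2$expression, 1)))
  expect_length(ge2$truth, 15)
})

test_that("disease maps are eligible, planted, and reproducible", {
  chems <- sprintf("C%03d", 1:300)
  dm <- genDiseaseMap(141, chems, plantedChemicals = c("C001", "C002"),
                      seed = 6)
  expect_equal(length(associations(dm$map)), 141)
  expect_true(all(lengths(associations(dm$map)) >= 5))
  expect_true(all(c("C001", "C002") %in%
                    associations(dm$map)[[dm$plantedDisease]]))
  dm2 <- genDiseaseMap(141, chems, plantedChemicals = c("C001", "C002"),
                       seed = 6)
  expect_identical(associations(dm$map), associations(dm2$map))
})

test_that("scenario regeneration from the manifest seed is bit-identical", {
  a <- simulateScenario(seed = 5, nSignatures = 120, genePoolSize = 500,
                        nChemicals = 520, nDiseases = 25)
  b <- simulateScenario(seed = a@manifest$seed,
                        nSignatures = a@manifest$nSignatures,
                        genePoolSize = a@manifest$genePoolSize,
                        nChemicals = a@manifest$nChemicals,
                        nDiseases = a@manifest$nDiseases)
  expect_identical(a@interactions, b@interactions)
  expect_identical(signatures(a@collection), signatures(b@collection))
  expect_identical(SummarizedExperiment::assay(a@expression, 1),
                   SummarizedExperiment::assay(b@expression, 1))
  expect_identical(associations(a@diseaseMap), associations(b@diseaseMap))
  expect_identical(a@plantedGenes, b@plantedGenes)
})

test_that("scenarios honor their stated structure", {
  sc <- simulateScenario(seed = 2, nSignatures = 120, genePoolSize = 500,
                         nChemicals = 520, nDiseases = 25)
  expect_equal(length(signatures(sc@collection)), 120)
  expect_equal(nrow(sc@expression), 500)
  expect_true(sc@plantedChemicals %in% chemicalIds(sc@collection))
  sig <- signatures(sc@collection)[[sc@plantedChemicals]]
  expect_length(sig, 20)                      # planted signature size
  expect_true(all(sc@plantedGenes %in% names(sig)))
  expect_true(sc@plantedChemicals %in%
                associations(sc@diseaseMap)[[sc@plantedDisease]])
  # every fixture written for the parsers round-trips
  dir <- withr::local_tempdir()
  paths <- writeScenario(sc, dir)
  rec <- parseInteractions(paths$interactions)
  expect_equal(nrow(rec), nrow(sc@interactions))
  hom <- parseHomology(paths$homology)
  expect_equal(hom@index, sc@homology@index)
  map <- parseDiseaseMap(paths$diseaseMap)
  expect_equal(associations(map), associations(sc@diseaseMap))
  se <- readExpression(paths$expression, paths$labels)
  expect_equal(dim(se), dim(sc@expression))
  expect_true(file.exists(paths$manifest))
})
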