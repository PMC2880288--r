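# a prediction list + disease map with known structure
diseaseSetting <- function(seed = 21) {
  st <- tinyEnrichmentSetting(nChem = 40, poolSize = 150, seed = seed)
  uni <- universeGenes(st$universe)
  target <- chemicalIds(st$collection)[[1]]
  de <- intersect(names(signatures(st$collection)[[target]]), uni)
  pl <- enrichAll(de, st$collection, st$universe)
  list(setting = st, predictions = pl, target = target)
}

test_that("chemical selection is monotone and hits the documented extremes", {
  ds <- diseaseSetting()
  rec <- predictions(ds$predictions)
  expect_length(selectChemicals(ds$predictions, min(rec$p) / 10), 0)
  expect_equal(sort(selectChemicals(ds$predictions, 1)),
               sort(rec$chemicalId))           # everything at alpha = 1
  sel <- lapply(c(1e-4, 1e-3, 1e-2, 0.05), function(a)
    selectChemicals(ds$predictions, a))
  for (i in seq_len(length(sel) - 1))
    expect_true(all(sel[[i]] %in% sel[[i + 1]]))   # nested
})

test_that("disease enrichment handles empty, maximal, and planted overlaps", {
  ds <- diseaseSetting()
  chems <- predictions(ds$predictions)$chemicalId
  sel <- selectChemicals(ds$predictions, 0.05)
  map <- DiseaseChemicalMap(list(
    none = setdiff(paste0("X", 1:6), chems),     # nothing in universe
    hit = c(ds$target, chems[2:6]),
    all = sel))
  # zero curated chemicals inside the universe: p = 1, overlap 0
  r0 <- diseaseEnrichment(sel, "none", map, chems)
  expect_equal(r0$p, 1); expect_equal(r0$nOverlap, 0)
  expect_equal(r0$curatedSize, 0)
  # selected superset of curated set: k = K
  rAll <- diseaseEnrichment(sel, "all", map, chems)
  expect_equal(rAll$nOverlap, rAll$curatedSize)
  # planted: p recomputable through the same hypergeometric test
  rHit <- diseaseEnrichment(sel, "hit", map, chems)
  expect_equal(rHit$p, hypergeomUpper(length(chems), rHit$curatedSize,
                                      rHit$nSelected, rHit$nOverlap))
  expect_error(diseaseEnrichment(sel, "absent", map, chems), "absent")
})

test_that("fp assessment counts strictly lower p and uses the eligible denominator", {
  ds <- diseaseSetting()
  chems <- predictions(ds$predictions)$chemicalId
  set.seed(33)
  assoc <- c(list(planted = c(ds$target, sample(chems, 5))),
             lapply(1:20, function(i) sample(chems, 5)))
  names(assoc) <- c("planted", sprintf("D%02d", 1:20))
  assoc$tiny <- chems[1:2]                      # ineligible at minChemicals=5
  map <- DiseaseChemicalMap(assoc)
  fa <- fpAssessment(ds$predictions, "planted", map, alpha = 0.05)
  expect_equal(nrow(fa@records), 21)            # tiny excluded
  expect_equal(fa@fpRate, fa@nBetter / 20)
  pTrue <- fa@records$p[fa@records$diseaseId == "planted"]
  expect_equal(fa@nBetter,
               sum(fa@records$p < pTrue & fa@records$diseaseId != "planted"))
  expect_error(fpAssessment(ds$predictions, "tiny", map, alpha = 0.05),
               "eligible")

  # all diseases sharing one curated set: every p ties, none counts as better
  same <- DiseaseChemicalMap(setNames(rep(list(chems[1:6]), 8),
                                      sprintf("S%d", 1:8)))
  faSame <- fpAssessment(ds$predictions, "S1", same, alpha = 0.05)
  expect_equal(faSame@nBetter, 0L)
  expect_equal(faSame@fpRate, 0)
})

test_that("a curated set covering the spiked chemicals scores far below competitors", {
  sc <- simulateScenario(seed = 77, nSignatures = 150, genePoolSize = 600,
                         nChemicals = 620, nDiseases = 30)
  r <- suppressMessages(predictChemicals(sc@expression, sc@collection,
                                         sc@homology,
                                         de = sc@manifest$shiftedSymbols,
                                         seed = 77))
  sel <- selectChemicals(r$predictions, 0.05)
  expect_true(sc@plantedChemicals %in% sel)
  chems <- chemicalIds(sc@collection)
  set.seed(78)
  assoc <- c(list(planted = unique(c(sel, sample(chems, 5)))),
             setNames(lapply(1:29, function(i) sample(chems, 6)),
                      sprintf("D%02d", 1:29)))
  map <- DiseaseChemicalMap(assoc)
  fa <- fpAssessment(r$predictions, "planted", map, alpha = 0.05)
  pTrue <- fa@records$p[fa@records$diseaseId == "planted"]
  expect_lt(pTrue, 1e-3)
  expect_lte(fpRate(fa), 0.05)
  # the reported p is the shared hypergeometric code path
  true <- fa@records[fa@records$diseaseId == "planted", ]
  expect_equal(true$p, hypergeomUpper(length(chems), true$curatedSize,
                                      true$nSelected, true$nOverlap))
})
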