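test_that("interaction parsing merges duplicates, skips bad rows, flags missing columns", {
  rec <- parseInteractions(text = tinyInteractionTsv())
  expect_equal(nrow(rec), 3)
  tcddCyp <- rec[rec$chemicalId == "C001" & rec$geneSymbol == "CYP1A1", ]
  expect_setequal(tcddCyp$citations[[1]], c("a", "b"))
  expect_equal(attr(rec, "skipped"), 0L)

  withBad <- paste(tinyInteractionTsv(),
                   "orphan\tC003\t\t9606\tx\tf",       # empty gene symbol
                   "\t\tGENE1\t9606\tx\tg",            # empty chemical
                   sep = "\n")
  rec2 <- parseInteractions(text = withBad)
  expect_equal(nrow(rec2), 3)
  expect_equal(attr(rec2, "skipped"), 2L)

  expect_error(
    parseInteractions(text = "A\tB\nx\ty"),
    "ChemicalID")
  expect_warning(
    parseInteractions(text = "ChemicalName\tChemicalID\tGeneSymbol\tOrganismID\tPubMedIDs"),
    "no interaction rows")
})

test_that("parsed records round-trip through the TSV writer", {
  rec <- parseInteractions(text = tinyInteractionTsv())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeInteractions(rec, path)
  back <- parseInteractions(file = path)
  expect_equal(back$chemicalId, rec$chemicalId)
  expect_equal(back$geneSymbol, rec$geneSymbol)
  expect_equal(lapply(back$citations, sort), lapply(rec$citations, sort))
})

test_that("signature building enforces the minimum-size filter", {
  rec <- recordsOfSizes(c(A = 6, B = 5, C = 4))
  coll <- buildSignatures(rec, minGenes = 5)
  expect_setequal(chemicalIds(coll), c("A", "B"))
  expect_equal(coll@dropped, 1L)
  expect_equal(lengths(signatures(coll))[["A"]], 6L)

  # threshold 1 keeps everything
  all1 <- buildSignatures(rec, minGenes = 1)
  expect_setequal(chemicalIds(all1), c("A", "B", "C"))
  expect_equal(all1@dropped, 0L)
})

test_that("per-gene support counts distinct citations pooled across organisms", {
  # one chemical, three genes with 60 / 40 / 9 supporting citations,
  # split across duplicate rows and two organisms
  cit <- list(sprintf("c%03d", 1:30), sprintf("c%03d", 1:60),  # overlap -> 60
              sprintf("a%03d", 1:40), sprintf("b%03d", 1:9))
  rec <- makeRecords(rep("CH1", 4),
                     c("CYP1A1", "CYP1A1", "AHR", "AHR2"),
                     taxon = c(9606L, 10090L, 9606L, 7955L),
                     citations = cit)
  coll <- buildSignatures(rec, minGenes = 1)
  sig <- signatures(coll)[["CH1"]]
  expect_equal(sig[["CYP1A1"]], 60L)
  expect_equal(sig[["AHR"]], 40L)
  expect_equal(sig[["AHR2"]], 9L)
})

test_that("signature building is idempotent and respects the pair-count bound", {
  gi <- genInteractions(80, genePool = sprintf("G%03d", 1:150), seed = 11)
  c1 <- buildSignatures(gi$records, minGenes = 1)
  c2 <- buildSignatures(gi$records, minGenes = 1)
  expect_identical(c1, c2)
  # sum of signature sizes equals distinct pairs at minGenes = 1
  expect_equal(sum(lengths(signatures(c1))), gi$manifest$nPairs)
  # and can only shrink for larger thresholds
  c5 <- buildSignatures(gi$records, minGenes = 5)
  expect_lte(sum(lengths(signatures(c5))), gi$manifest$nPairs)
})

test_that("synthetic record counts match the generator manifest", {
  gi <- genInteractions(100, genePool = sprintf("G%03d", 1:200), seed = 3)
  expect_equal(nrow(gi$records), gi$manifest$nRelations)
  expect_equal(length(unique(paste(gi$records$chemicalId,
                                   gi$records$geneSymbol))),
               gi$manifest$nPairs)
  rec <- parseInteractions(text = {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeInteractions(gi$records, path)
    paste(readLines(path), collapse = "\n")
  })
  expect_equal(nrow(rec), gi$manifest$nRelations)
})

test_that("source removal subtracts citations and drops fully-sourced relations", {
  rec <- makeRecords(c("A", "A", "B"), c("G1", "G2", "G3"),
                     citations = list("x", c("x", "y"), "z"))
  out <- removeRelationsBySource(rec, "x")
  expect_equal(nrow(out), 2)
  expect_false("G1" %in% out$geneSymbol)          # fully removed
  expect_equal(out$citations[[which(out$geneSymbol == "G2")]], "y")
  expect_equal(attr(out, "removedRecords"), 1L)
  expect_equal(attr(out, "removedCitations"), 2L)
  # empty source set is the identity
  same <- removeRelationsBySource(rec, character())
  expect_equal(same$citations, rec$citations)
})

test_that("source removal never grows any signature", {
  gi <- genInteractions(60, genePool = sprintf("G%03d", 1:100), seed = 5)
  before <- buildSignatures(gi$records, minGenes = 1)
  someSources <- unique(unlist(gi$records$citations))[1:200]
  after <- buildSignatures(removeRelationsBySource(gi$records, someSources),
                           minGenes = 1)
  for (ch in chemicalIds(after)) {
    sa <- signatures(after)[[ch]]
    sb <- signatures(before)[[ch]]
    expect_true(all(names(sa) %in% names(sb)))
    expect_true(all(sa <= sb[names(sa)]))
  }
  # removing a known source drops exactly the relations citing only it
  rec10 <- makeRecords(sprintf("C%02d", 1:10), sprintf("G%02d", 1:10),
                       citations = rep(list("S"), 10))
  mixed <- rbind(gi$records, rec10)
  mixed$citations <- c(gi$records$citations, rec10$citations)
  out <- removeRelationsBySource(mixed, "S")
  expect_equal(nrow(mixed) - nrow(out), 10)
})

test_that("disease map parsing groups by disease and collapses duplicates", {
  txt <- paste("DiseaseID\tDiseaseName\tChemicalID",
               "D01\tprostate neoplasm\tC1",
               "D01\tprostate neoplasm\tC2",
               "D01\tprostate neoplasm\tC2",
               "D02\tlung neoplasm\tC3",
               sep = "\n")
  map <- parseDiseaseMap(text = txt)
  expect_equal(length(associations(map)), 2)
  expect_setequal(associations(map)[["D01"]], c("C1", "C2"))
  expect_equal(associations(map)[["D02"]], "C3")
  expect_error(parseDiseaseMap(text = "A\tB\nx\ty"), "DiseaseID")
})

test_that("signature collections round-trip through GMT + sidecar", {
  rec <- recordsOfSizes(c(A = 6, B = 5))
  coll <- buildSignatures(rec, minGenes = 5)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeSignatures(coll, gmt)
  back <- readSignatures(gmt)
  expect_equal(signatures(back), signatures(coll))
  expect_equal(minGenes(back), minGenes(coll))
  expect_equal(geneUniverse(back), geneUniverse(coll))
})
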