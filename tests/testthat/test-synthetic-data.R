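test_that("simulation is deterministic for a fixed spec and seed", {
  spec <- simSpec(nTaxa = 6, nLoci = 4, clockViolationLoci = 1, seed = 5)
  d1 <- simulateDataset(spec)
  d2 <- simulateDataset(spec)
  expect_identical(recovered(d1@recovery), recovered(d2@recovery))
  expect_identical(lapply(d1@alignments, as.matrix),
                   lapply(d2@alignments, as.matrix))
  expect_identical(lapply(d1@geneTrees, ape::write.tree),
                   lapply(d2@geneTrees, ape::write.tree))
  expect_identical(d1@truth, d2@truth)
  d3 <- simulateDataset(simSpec(nTaxa = 6, nLoci = 4, clockViolationLoci = 1,
                                seed = 6))
  expect_false(identical(recovered(d1@recovery), recovered(d3@recovery)))
})

test_that("trees and recovery are unchanged when alignments are skipped", {
  spec <- simSpec(nTaxa = 6, nLoci = 4, clockViolationLoci = 1, seed = 9)
  full <- simulateDataset(spec)
  lean <- simulateDataset(spec, alignments = FALSE)
  expect_identical(recovered(full@recovery), recovered(lean@recovery))
  expect_identical(lapply(full@geneTrees, ape::write.tree),
                   lapply(lean@geneTrees, ape::write.tree))
  expect_length(lean@alignments, 0L)
})

test_that("a noise-free generator produces perfect recovery and gap-free data", {
  spec <- simSpec(nTaxa = 6, nLoci = 4, clockViolationLoci = 0, rogueTaxa = 0,
                  fragBase = 1, fragSlope = 0, bankMu = 1, gapColFrac = 0,
                  seed = 3)
  ds <- simulateDataset(spec)
  expect_true(all(recovered(ds@recovery) == rep(targetLength(ds@recovery),
                                                each = 6)))
  sc <- coverageScores(ds@recovery)
  expect_equal(sc$score, rep(1, 6))
  expect_true(all(vapply(ds@alignments,
                         function(a) !any(as.matrix(a) == "-"), logical(1))))
})

test_that("planted rogue taxa are recovered by outlier flagging", {
  spec <- simSpec(nTaxa = 10, nLoci = 2, clockViolationLoci = 0, rogueTaxa = 1,
                  seed = 17)
  ds <- simulateDataset(spec, alignments = FALSE)
  rogue <- ds@truth$rogue_taxa
  for (tr in ds@geneTrees)
    expect_true(rogue %in% flagOutlierLeaves(tr)$flagged)
})

test_that("planted clock violators separate from clock-like loci", {
  ds <- simulateDataset(simSpec(nTaxa = 20, nLoci = 20, clockViolationLoci = 6,
                                rogueTaxa = 0, seed = 23), alignments = FALSE)
  st <- do.call(rbind, lapply(names(ds@geneTrees), function(id)
    clockStats(ds@geneTrees[[id]], speciesTree = ds@speciesTree, locusId = id)))
  isV <- st$locus_id %in% ds@truth$clock_violating_loci
  expect_gt(median(st$rtt_variance[isV]), median(st$rtt_variance[!isV]))
})

test_that("low-coverage accessions always score below fully recovered ones", {
  for (seed in 1:5) {
    spec <- simSpec(nTaxa = 8, nLoci = 10, clockViolationLoci = 0,
                    rogueTaxa = 0, fragBase = 0.15, fragSlope = 0,
                    bankMu = 1, bankNoise = 1e6, herbFrac = 0.5, seed = seed)
    ds <- simulateDataset(spec)
    sc <- coverageScores(ds@recovery)
    meta <- sampleMeta(ds@recovery)
    low <- ds@truth$low_coverage_accessions
    fullAcc <- meta$accession[meta$source != "herbarium"]
    if (length(low) == 0L) next
    expect_lt(max(sc$score[sc$entity_id %in% low]),
              min(sc$score[sc$entity_id %in% fullAcc]))
  }
})

test_that("simulated capture success recovers the planted age slope", {
  # moderate replication here; the full-power property runs in acceptance
  hits <- 0
  for (seed in 1:10) {
    ds <- simulateDataset(simSpec(nTaxa = 60, nLoci = 20,
                                  clockViolationLoci = 0, rogueTaxa = 0,
                                  seed = seed), alignments = FALSE)
    er <- ageEffectReport(ds@recovery)
    if (er$slope > 0 && er$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("fixture bundles contain the advertised files and round-trip", {
  dir <- withr::local_tempdir()
  fixtureSuite("small", dir, seed = 2)
  expect_length(list.files(file.path(dir, "alignments")), 12L)
  expect_length(list.files(file.path(dir, "gene_trees")), 12L)
  expect_true(file.exists(file.path(dir, "species_tree.nwk")))
  expect_true(file.exists(file.path(dir, "recovery.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  ds <- readDataset(dir)
  expect_equal(length(ds@alignments), 12L)
  expect_equal(nrow(recovered(ds@recovery)), 8L)
  gen <- simulateDataset(simSpec(nTaxa = 8, nLoci = 12,
                                 clockViolationLoci = 2, seed = 2))
  expect_identical(as.matrix(ds@alignments[[1]]),
                   as.matrix(gen@alignments[[1]]))
  expect_identical(recovered(ds@recovery), recovered(gen@recovery))
  expect_identical(sort(ds@truth$rogue_taxa), sort(gen@truth$rogue_taxa))
})

test_that("rewriting the same dataset yields identical file checksums", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fixtureSuite("small", d1, seed = 4)
  fixtureSuite("small", d2, seed = 4)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]])
})

test_that("generator rejects impossible settings", {
  expect_error(simSpec(nTaxa = 3), "at least 4")
  expect_error(simSpec(nLoci = 0), "at least 1")
  expect_error(simSpec(rogueTaxa = 1, rogueMultiplier = 1), "exceed 1")
  expect_error(simulateDataset(list()), "simSpec")
})
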