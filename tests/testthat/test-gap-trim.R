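test_that("trimming keeps columns by non-gap fraction with >= semantics", {
  aln <- GappedAlignment("t", c(a = "AAAT", b = "A-A-", c = "A-A-", d = "A-C-"))
  # per-column non-gap fractions: 1.0, 0.25, 1.0, 0.25
  expect_identical(as.matrix(trimAtThreshold(aln, 0)), as.matrix(aln))
  t03 <- trimAtThreshold(aln, 0.3)
  expect_equal(alnWidth(t03), 2L)
  t025 <- trimAtThreshold(aln, 0.25)   # boundary: kept at equality
  expect_equal(alnWidth(t025), 4L)
  t1 <- trimAtThreshold(aln, 1)
  expect_equal(alnWidth(t1), 2L)       # only gap-free columns
  expect_identical(taxa(t1), taxa(aln))
})

test_that("data loss counts non-gap residues; ? and N are present", {
  orig <- GappedAlignment("d", c(a = "AAA-", b = "AAC-", c = "C-A-", d = "C-CA"))
  expect_equal(dataLoss(orig, orig), 0)
  tr <- trimAtThreshold(orig, 0.6)
  expect_equal(dataLoss(orig, tr), 3 / 11)
  emptyTrim <- GappedAlignment("d", matrix("-", 4, 0,
                                           dimnames = list(taxa(orig), NULL)))
  expect_equal(dataLoss(orig, emptyTrim), 1)
  qn <- GappedAlignment("q", c(a = "?N", b = "AC"))
  expect_equal(dataLoss(qn, GappedAlignment("q", c(a = "?", b = "A"))), 0.5)
  gapsOnly <- GappedAlignment("g", c(a = "--", b = "--"))
  expect_error(dataLoss(gapsOnly, gapsOnly), "undefined")
  expect_equal(dataLoss(orig, tr, metric = "columns"), 0.5)
})

test_that("threshold optimization reproduces the worked sweep", {
  aln <- GappedAlignment("w", c(a = "AAA-", b = "AAC-", c = "C-A-", d = "C-CA"))
  res <- optimizeTrim(aln, trimConfig(thresholds = c(0.3, 0.6)))
  curve <- trimCurve(res)
  expect_equal(curve$p_pic, c(2 / 3, 1))
  expect_equal(curve$data_loss, c(1 / 11, 3 / 11))
  expect_equal(chosenGt(res), 0.6)
  expect_equal(verdict(res), "keep")
  expect_equal(alnWidth(trimmedAlignment(res)), 2L)
})

test_that("ties break toward the lowest threshold", {
  aln <- GappedAlignment("tie", c(a = "AACC", b = "AACC", c = "CCAA", d = "CCAA"))
  res <- optimizeTrim(aln)   # gap-free, fully informative at every gt
  expect_equal(chosenGt(res), 0)
  expect_equal(res@dataLoss, 0)
})

test_that("loci are discarded when signal requires too much loss", {
  # informative signal lives in sparse columns: any threshold that keeps
  # p_pic > 0 keeps everything (loss 0) but p_pic stays 0 only if trimmed out;
  # construct instead a case where every threshold loses > 30%
  m <- rbind(a = c("A", "A", rep("-", 8)),
             b = c("A", "A", rep("-", 8)),
             c = c("C", "C", strsplit(strrep("G", 8), "")[[1]]),
             d = c("C", "C", strsplit(strrep("G", 8), "")[[1]]))
  aln <- GappedAlignment("disc", m)
  # gt <= 0.5 keeps all 10 columns (loss 0, p_pic = 2/10); gt > 0.5 keeps
  # only the 2 informative columns, loss = 1 - 8/24 = 2/3 > 0.3
  res <- optimizeTrim(aln, trimConfig(thresholds = c(0.4, 0.9), maxDataLoss = 0.3))
  expect_equal(chosenGt(res), 0.4)
  # now force the low thresholds out of feasibility: all-or-nothing case
  res2 <- optimizeTrim(aln, trimConfig(thresholds = c(0.9), maxDataLoss = 0.3))
  expect_equal(verdict(res2), "discard")
  expect_true(is.na(chosenGt(res2)))
  # a feasible sweep whose best p_pic is 0 is also discarded
  allsame <- GappedAlignment("flat", c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_equal(verdict(optimizeTrim(allsame)), "discard")
})

test_that("optimization matches the brute-force oracle on random inputs", {
  set.seed(13)
  for (i in 1:40) {
    aln <- randomAlignment(sample(4:8, 1), sample(6:30, 1),
                           gapProb = runif(1, 0, 0.6))
    cfg <- trimConfig()
    res <- optimizeTrim(aln, cfg)
    o <- oracleOptimize(as.matrix(aln), cfg$thresholds, cfg$maxDataLoss)
    expect_identical(verdict(res), o$verdict)
    expect_equal(chosenGt(res), o$chosen)
  }
})

test_that("kept columns and data loss are monotone in the threshold", {
  set.seed(14)
  for (i in 1:10) {
    aln <- randomAlignment(6, 25, gapProb = 0.4)
    res <- optimizeTrim(aln)
    curve <- trimCurve(res)
    expect_true(all(diff(curve$n_col) <= 0))
    expect_true(all(diff(curve$data_loss) >= -1e-12))
  }
})

test_that("trimming twice equals one trim at the higher threshold", {
  set.seed(15)
  aln <- randomAlignment(5, 30, gapProb = 0.5)
  twice <- trimAtThreshold(trimAtThreshold(aln, 0.3), 0.7)
  once <- trimAtThreshold(aln, 0.7)
  expect_identical(as.matrix(twice), as.matrix(once))
})

test_that("trim configuration is validated", {
  expect_error(trimConfig(thresholds = numeric(0)), "empty")
  expect_error(trimConfig(thresholds = c(0.5, 0.2)), "increasing")
  expect_error(trimConfig(thresholds = c(0, 1.5)), "\\[0, 1\\]")
  expect_error(trimConfig(maxDataLoss = 2), "maxDataLoss")
})
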