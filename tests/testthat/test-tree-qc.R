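test_that("tree diameter matches path enumeration on known trees", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(treeDiameter(star), 2)
  cat3 <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  expect_equal(treeDiameter(cat3), 5)
  two <- ape::read.tree(text = "(A:0.3,B:0.2);")
  expect_equal(treeDiameter(two), 0.5)
  noLen <- ape::read.tree(text = "((A,B),C);")
  expect_error(treeDiameter(noLen), "branch lengths")
})

test_that("tree diameter equals brute force on random trees", {
  set.seed(31)
  for (i in 1:20) {
    tr <- randomTree(sample(4:12, 1))
    expect_equal(treeDiameter(tr), oracleDiameter(tr), tolerance = 1e-10)
  }
})

test_that("outlier flagging finds the long leaf and stops on symmetry", {
  sym <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_length(flagOutlierLeaves(sym)$flagged, 0L)

  lop <- ape::read.tree(text = "(A:10,B:1,C:1,D:1);")
  # D = 11; without A, D = 2; ratio 4.5 > 0.2
  fl <- flagOutlierLeaves(lop)
  expect_identical(fl$flagged, "A")
  expect_setequal(fl$tree$tip.label, c("B", "C", "D"))

  loose <- flagOutlierLeaves(lop, treeQCConfig(diameterBound = Inf))
  expect_length(loose$flagged, 0L)
  expect_equal(length(loose$tree$tip.label), 4L)

  expect_error(flagOutlierLeaves(ape::read.tree(text = "(A:1,B:1,C:1);")),
               "at least 4")
})

test_that("low-support contraction follows the inclusive-cutoff rule", {
  tr <- ape::read.tree(text = "((A:1,B:1)5:1,(C:1,D:1)95:1);")
  out <- collapseLowSupport(tr, treeQCConfig())
  expect_equal(out$Nnode, 2L)                       # one edge contracted
  expect_setequal(out$tip.label, tr$tip.label)
  # the CD clade survives with its support
  expect_true("95" %in% out$node.label)
  # contracted edge length is pushed onto the children (depths preserved)
  expect_equal(max(ape::node.depth.edgelength(out)),
               max(ape::node.depth.edgelength(tr)))

  # support exactly at the cutoff is contracted (<=, not <)
  atCut <- ape::read.tree(text = "((A:1,B:1)10:1,C:1);")
  cc <- collapseLowSupport(atCut, treeQCConfig())
  expect_equal(cc$Nnode, 1L)                        # star

  solid <- ape::read.tree(text = "((A:1,B:1)100:1,(C:1,D:1)90:1);")
  expect_equal(collapseLowSupport(solid, treeQCConfig())$Nnode, solid$Nnode)
})

test_that("contraction is idempotent and keeps the leaf set", {
  set.seed(33)
  for (i in 1:10) {
    tr <- randomTree(8)
    tr$node.label <- c("", as.character(sample(0:100, tr$Nnode - 1L, replace = TRUE)))
    once <- collapseLowSupport(tr, treeQCConfig(supportCutoff = 50))
    twice <- collapseLowSupport(once, treeQCConfig(supportCutoff = 50))
    expect_setequal(once$tip.label, tr$tip.label)
    expect_identical(ape::write.tree(twice), ape::write.tree(once))
    expect_lte(once$Nnode, tr$Nnode)
  }
})

test_that("unknown support is retained, not contracted", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1)5:1);")  # first clade unlabeled
  out <- collapseLowSupport(tr, treeQCConfig())
  expect_equal(out$Nnode, 2L)   # only the support-5 edge went
})

test_that("root-to-tip variance and tree length follow their definitions", {
  ultra <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  s <- clockStats(ultra, cfg = treeQCConfig(rooting = "given"), locusId = "u")
  expect_equal(s$rtt_variance, 0)
  expect_equal(s$tree_length, 6.5)
  expect_equal(s$n_taxa, 4L)

  skew <- ape::read.tree(text = "((A:1,B:1):0.5,C:2);")
  s2 <- clockStats(skew, cfg = treeQCConfig(rooting = "given"), locusId = "s")
  expect_equal(s2$rtt_variance, 1 / 12)   # depths 1.5, 1.5, 2.0

  # midpoint rooting equalizes the two deepest tips
  s3 <- clockStats(skew, locusId = "s")
  expect_lt(s3$rtt_variance, s2$rtt_variance)
})

test_that("concordance counts shared bipartitions after pruning", {
  sp <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  expect_equal(clockStats(sp, sp, locusId = "x")$concordance, 1)

  # same topology, different branch lengths: still fully concordant
  sp2 <- sp; sp2$edge.length <- sp$edge.length * runif(nrow(sp$edge), 0.1, 3)
  expect_equal(clockStats(sp2, sp, locusId = "x")$concordance, 1)

  conflict <- ape::read.tree(text = "(((A:1,C:1):1,(B:1,D:1):1):1,(E:1,F:1):1);")
  cc <- clockStats(conflict, sp, locusId = "y")$concordance
  expect_lt(cc, 1)

  pruned <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")  # no D, F
  expect_true(is.finite(clockStats(pruned, sp, locusId = "z")$concordance))

  two <- ape::read.tree(text = "(A:1,Z:1);")
  expect_error(clockStats(two, sp, locusId = "w"), "fewer than 2 taxa shared")
})

test_that("clock-locus selection applies strict bounds as printed", {
  stats <- data.frame(
    locus_id = c("good", "boundary_rtt", "short", "sparse", "discordant"),
    rtt_variance = c(0.001, 0.024, 0.001, 0.001, 0.001),
    tree_length = c(2, 2, 0.1, 2, 2),
    n_taxa = c(30, 30, 30, 24, 30),
    concordance = c(0.5, 0.5, 0.5, 0.5, 0.1))
  sel <- selectClockLoci(stats)
  expect_identical(sel$retained, "good")
  rep <- sel$report
  expect_equal(rep$failed[rep$locus_id == "boundary_rtt"], "rtt_variance")
  expect_equal(rep$failed[rep$locus_id == "short"], "tree_length")
  expect_equal(rep$failed[rep$locus_id == "sparse"], "n_taxa")
  expect_equal(rep$failed[rep$locus_id == "discordant"], "concordance")
  expect_length(selectClockLoci(stats[0, ])$retained, 0L)
})

test_that("concordance pies classify support, conflict and missing taxa", {
  sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  same <- sp
  conflict <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  reduced <- ape::read.tree(text = "(A:1,B:1);")

  pies <- concordancePies(list(same, conflict, reduced), sp)
  expect_equal(nrow(pies), 1L)    # one internal bipartition: AB|CD
  expect_equal(pies$n_concord, 1L)
  expect_equal(pies$n_conflict, 1L)
  expect_equal(pies$n_uninformative, 1L)
  expect_equal(pies$n_concord + pies$n_conflict + pies$n_uninformative, 3L)

  all_same <- concordancePies(list(sp, sp, sp), sp)
  expect_equal(all_same$n_concord, 3L)
  expect_equal(all_same$n_conflict, 0L)
})

test_that("unresolved gene-tree regions count as uninformative", {
  sp <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);")
  poly <- ape::read.tree(text = "(A:1,B:1,C:1,(D:1,E:1):1);")  # AB unresolved
  pies <- concordancePies(list(poly), sp)
  ab <- pies[pies$node_id == "A|B", ]
  expect_equal(ab$n_uninformative + ab$n_concord, 1L)
  expect_equal(ab$n_conflict, 0L)
})

test_that("tree QC configuration is validated", {
  expect_error(treeQCConfig(diameterBound = 0), "diameterBound")
  expect_error(treeQCConfig(supportCutoff = 150), "supportCutoff")
  expect_error(treeQCConfig(rooting = "outgroup"), "outgroup")
  expect_error(clockStats(ape::read.tree(text = "(A:1,B:1);"),
                          cfg = treeQCConfig(rooting = "outgroup",
                                             outgroup = "Z")),
               "no outgroup")
})
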