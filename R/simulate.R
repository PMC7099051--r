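#' Settings for the synthetic Hyb-Seq generator
#'
#' Describes a simulated target-capture study of herbarium-dominated
#' sampling: a pure-birth species tree, per-locus gene trees with
#' multiplicative per-branch rate noise, sequences evolved under an
#' equal-rates substitution model, and an age-dependent fragmentary
#' recovery process that injects gaps and missing rows into the
#' alignments.
#'
#' @param nTaxa number of accessions (>= 4).
#' @param nLoci number of loci (>= 1).
#' @param locusLengthMean,locusLengthSd normal distribution of target locus
#'   lengths (bp), floored at \code{minLocusLength}.
#' @param minLocusLength shortest locus generated (bp).
#' @param treeDepth species-tree root-to-tip depth (substitutions/site).
#' @param rateJitterSd lognormal sdlog of per-branch rate multipliers on
#'   clock-like loci (small: near-clock).
#' @param clockViolationLoci number of loci whose branches get strong rate
#'   heterogeneity.
#' @param clockViolationSd lognormal sdlog of per-branch rate multipliers on
#'   clock-violating loci.
#' @param rogueTaxa number of planted rogue accessions.
#' @param rogueMultiplier terminal branches of rogue taxa are set to this
#'   multiple of the gene tree's mean terminal branch length (emulating
#'   contaminant or paralogous sequence).
#' @param gapColFrac fraction of alignment columns made gap-rich.
#' @param herbFrac fraction of accessions drawn from herbarium material;
#'   the remainder split evenly between DNA-bank and silica sources.
#' @param yearRange herbarium collection-year range.
#' @param fragBase expected recovered fraction for a herbarium specimen
#'   collected in the first year of \code{yearRange}.
#' @param fragSlope increase in expected recovered fraction per collection
#'   year (linear decay of degradation with recency).
#' @param fragNoiseAcc Beta precision of accession-level recovery noise
#'   (small values give the large scatter typical of herbarium material).
#' @param fragNoiseLocus Beta precision of per-locus recovery noise around
#'   the accession mean.
#' @param bankMu expected recovered fraction for DNA-bank/silica samples.
#' @param bankNoise Beta precision for DNA-bank/silica samples.
#' @param minFragmentBp recovered fragments shorter than this are treated as
#'   unrecovered (assembly failure).
#' @param lowCoverageBelow accessions whose expected fraction falls below
#'   this value are recorded as planted low-coverage truth.
#' @param seed integer seed governing all randomness.
#' @return A validated list of class \code{simSpec}.
#' @export
simSpec <- function(nTaxa = 40, nLoci = 150,
                    locusLengthMean = 700, locusLengthSd = 450,
                    minLocusLength = 120,
                    treeDepth = 0.35, rateJitterSd = 0.05,
                    clockViolationLoci = 30, clockViolationSd = 1.5,
                    rogueTaxa = 1, rogueMultiplier = 10,
                    gapColFrac = 0.05,
                    herbFrac = 0.85, yearRange = c(1850, 2018),
                    fragBase = 0.55, fragSlope = 0.002,
                    fragNoiseAcc = 4, fragNoiseLocus = 20,
                    bankMu = 0.85, bankNoise = 40,
                    minFragmentBp = 50, lowCoverageBelow = 0.3,
                    seed = 1) {
  if (nTaxa < 4) stop("nTaxa must be at least 4")
  if (nLoci < 1) stop("nLoci must be at least 1")
  if (rogueTaxa > 0 && rogueMultiplier <= 1)
    stop("rogueMultiplier must exceed 1")
  stopifnot(gapColFrac >= 0, gapColFrac <= 1, herbFrac >= 0, herbFrac <= 1,
            fragBase >= 0, bankMu <= 1, clockViolationLoci <= nLoci,
            rogueTaxa <= nTaxa)
  spec <- as.list(environment())
  structure(spec, class = "simSpec")
}

## Beta draw parameterized by mean and precision; exact at the boundaries so
## noise-free scenarios (mu = 1) stay noise-free.
.rbetaMean <- function(n, mu, nu) {
  mu <- pmin(pmax(mu, 0), 1)
  out <- numeric(n)
  degen <- mu >= 1 - 1e-12 | mu <= 1e-12
  out[degen] <- mu[degen]
  if (any(!degen)) {
    md <- mu[!degen]
    out[!degen] <- stats::rbeta(sum(!degen), md * nu, (1 - md) * nu)
  }
  out
}

#' Simulate a complete synthetic dataset
#'
#' Draws a pure-birth species tree scaled to \code{treeDepth}, copies it
#' into per-locus gene trees with multiplicative per-branch rate noise
#' (strong on planted clock-violating loci), inflates the terminal branches
#' of planted rogue taxa, assigns bootstrap-style support labels, evolves
#' sequences under an equal-rates model, draws age-dependent fragmentary
#' recovery per accession and locus, and masks the alignments accordingly.
#' All planted features are recorded in the \code{truth} slot.
#'
#' @param spec a \code{\link{simSpec}}.
#' @param alignments if \code{FALSE}, skip sequence simulation and masking
#'   (trees, recovery matrix and truth are unchanged for the same spec).
#' @return A \linkS4class{SimDataset}.
#' @examples
#' ds <- simulateDataset(simSpec(nTaxa = 6, nLoci = 3, seed = 7))
#' ds
#' @export
simulateDataset <- function(spec, alignments = TRUE) {
  if (!inherits(spec, "simSpec")) stop("spec must come from simSpec()")
  set.seed(spec$seed)
  n <- spec$nTaxa; L <- spec$nLoci
  accs <- sprintf("acc%03d", seq_len(n))
  loci <- sprintf("locus%03d", seq_len(L))

  ## --- sample metadata -----------------------------------------------------
  nHerb <- max(1L, round(spec$herbFrac * n))
  nOther <- n - nHerb
  source <- c(rep("herbarium", nHerb),
              rep(c("dna_bank", "silica"), length.out = nOther))
  source <- sample(source)
  years <- integer(n)
  isHerb <- source == "herbarium"
  years[isHerb] <- round(stats::runif(sum(isHerb), spec$yearRange[1], spec$yearRange[2]))
  years[!isHerb] <- round(stats::runif(sum(!isHerb), 1990, 2018))
  meta <- data.frame(accession = accs, collection_year = years,
                     source = source, stringsAsFactors = FALSE)

  ## --- species tree --------------------------------------------------------
  sp <- ape::rphylo(n, birth = 1, death = 0)
  sp$tip.label <- sample(accs)
  depth <- max(ape::node.depth.edgelength(sp))
  sp$edge.length <- sp$edge.length * spec$treeDepth / depth

  ## --- loci ----------------------------------------------------------------
  lens <- pmax(spec$minLocusLength,
               round(stats::rnorm(L, spec$locusLengthMean, spec$locusLengthSd)))
  names(lens) <- loci
  lclass <- sample(c("coding", "flanking"), L, replace = TRUE)
  names(lclass) <- loci
  violators <- sort(sample(loci, spec$clockViolationLoci))
  rogues <- sort(sample(accs, spec$rogueTaxa))

  ## --- recovery process (drawn before sequences so the recovery matrix is
  ##     identical whether or not alignments are simulated) ------------------
  mu <- ifelse(isHerb,
               spec$fragBase + spec$fragSlope * (years - spec$yearRange[1]),
               spec$bankMu)
  nu <- ifelse(isHerb, spec$fragNoiseAcc, spec$bankNoise)
  fAcc <- .rbetaMean(n, mu, nu)
  ## one precision per accession: vectorised draw done row-wise
  fCell <- matrix(0, n, L, dimnames = list(accs, loci))
  for (i in seq_len(n))
    fCell[i, ] <- .rbetaMean(L, rep(fAcc[i], L), spec$fragNoiseLocus)
  recLen <- round(sweep(fCell, 2L, lens, `*`))
  recLen[recLen < spec$minFragmentBp] <- 0
  readsTotal <- round(stats::rlnorm(n, log(740000), 0.4))
  onFrac <- stats::rbeta(n, 0.115 * 200, 0.885 * 200)
  reads <- data.frame(accession = accs, reads_total = readsTotal,
                      reads_on_target = round(readsTotal * onFrac),
                      stringsAsFactors = FALSE)
  recovery <- RecoveryMatrix(recLen, lens, meta = meta, reads = reads)

  ## --- gene trees ----------------------------------------------------------
  geneTrees <- vector("list", L); names(geneTrees) <- loci
  for (j in seq_len(L)) {
    g <- sp
    s <- if (loci[j] %in% violators) spec$clockViolationSd else spec$rateJitterSd
    ## median-preserving multipliers: half the branches speed up, half slow
    ## down, so violation strength raises depth spread rather than shrinking
    ## the tree
    mult <- stats::rlnorm(nrow(g$edge), meanlog = 0, sdlog = s)
    g$edge.length <- g$edge.length * mult
    term <- g$edge[, 2L] <= length(g$tip.label)
    if (length(rogues)) {
      meanTerm <- mean(g$edge.length[term])
      for (r in rogues) {
        e <- which(term & g$tip.label[g$edge[, 2L]] == r)
        g$edge.length[e] <- spec$rogueMultiplier * meanTerm
      }
    }
    sup <- as.character(round(100 * stats::rbeta(g$Nnode, 2, 0.4)))
    sup[1L] <- ""   # no support on the root
    g$node.label <- sup
    geneTrees[[j]] <- g
  }

  ## --- sequences and masking ----------------------------------------------
  alns <- list()
  informativeCols <- NULL
  if (alignments) {
    alns <- vector("list", L); names(alns) <- loci
    informativeCols <- vector("list", L); names(informativeCols) <- loci
    for (j in seq_len(L)) {
      len <- lens[j]
      pd <- phangorn::simSeq(geneTrees[[j]], l = len, type = "DNA", rate = 1)
      m <- toupper(as.character(pd))[accs, , drop = FALSE]
      ## fragmentary recovery: keep one contiguous window per accession
      for (i in seq_len(n)) {
        r <- recLen[i, j]
        if (r >= len) next
        if (r == 0) { m[i, ] <- "-"; next }
        start <- sample.int(len - r + 1L, 1L)
        mask <- setdiff(seq_len(len), seq.int(start, start + r - 1L))
        m[i, mask] <- "-"
      }
      ## gap-rich columns (alignment slop around ragged flanks)
      nGapCol <- round(spec$gapColFrac * len)
      if (nGapCol > 0) {
        cols <- sample.int(len, nGapCol)
        for (cc in cols) {
          p <- stats::runif(1, 0.3, 0.7)
          hit <- stats::runif(n) < p
          m[hit, cc] <- "-"
        }
      }
      aln <- GappedAlignment(loci[j], m)
      alns[[j]] <- aln
      informativeCols[[j]] <- which(.columnFlags(m)$informative)
    }
  }

  truth <- list(
    rogue_taxa = rogues,
    clock_violating_loci = violators,
    low_coverage_accessions = accs[fAcc < spec$lowCoverageBelow],
    expected_fraction = stats::setNames(fAcc, accs),
    locus_class = lclass,
    informative_columns = informativeCols,
    seed = spec$seed)

  new("SimDataset", alignments = alns, geneTrees = geneTrees,
      speciesTree = sp, recovery = recovery, truth = truth,
      spec = unclass(spec))
}

#' Write a fixture bundle to disk
#'
#' Simulates a dataset of a standard size and writes it as plain-text
#' fixtures: one FASTA per locus, one newick per gene tree, the species
#' tree, a long-form recovery table, a sample-metadata table, and a JSON
#' truth manifest. The small size is 8 taxa by 12 loci; the medium size,
#' 40 taxa by 150 loci, mirrors a typical retained herbariomic data matrix.
#'
#' @param size \code{"small"} or \code{"medium"}.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{simSpec}}.
#' @return The directory path, invisibly; side effect: files written.
#' @export
fixtureSuite <- function(size = c("small", "medium"), dir, seed = 1, ...) {
  size <- match.arg(size)
  dims <- switch(size, small = c(8L, 12L), medium = c(40L, 150L))
  args <- list(nTaxa = dims[1L], nLoci = dims[2L], seed = seed, ...)
  if (is.null(args$clockViolationLoci))   # scale the planted violators down
    args$clockViolationLoci <- max(1L, round(0.2 * dims[2L]))
  spec <- do.call(simSpec, args)
  ds <- simulateDataset(spec)
  writeDataset(ds, dir)
}

#' Write a SimDataset as plain-text files
#'
#' @param ds a \linkS4class{SimDataset}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory %s", dir))
  for (sub in c("alignments", "gene_trees"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  for (id in names(ds@alignments))
    writeAlignment(ds@alignments[[id]],
                   file.path(dir, "alignments", paste0(id, ".fasta")))
  for (id in names(ds@geneTrees))
    writeTree(ds@geneTrees[[id]],
              file.path(dir, "gene_trees", paste0(id, ".nwk")))
  writeTree(ds@speciesTree, file.path(dir, "species_tree.nwk"))
  writeRecoveryTable(ds@recovery, file.path(dir, "recovery.tsv"))
  meta <- sampleMeta(ds@recovery)
  reads <- readCounts(ds@recovery)
  if (nrow(reads)) meta <- merge(meta, reads, by = "accession", sort = FALSE)
  utils::write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- ds@truth
  truth$informative_columns <- NULL   # bulky; recomputable from alignments
  truth$locus_class <- as.list(truth$locus_class)
  truth$expected_fraction <- as.list(truth$expected_fraction)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture directory back into a SimDataset
#'
#' @param dir a directory written by \code{\link{writeDataset}} /
#'   \code{\link{fixtureSuite}}.
#' @return A \linkS4class{SimDataset} (the \code{spec} slot holds only the
#'   seed echoed through the truth manifest).
#' @export
readDataset <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such directory: %s", dir))
  alnFiles <- sort(list.files(file.path(dir, "alignments"),
                              pattern = "\\.fasta$", full.names = TRUE))
  trFiles <- sort(list.files(file.path(dir, "gene_trees"),
                             pattern = "\\.nwk$", full.names = TRUE))
  alns <- lapply(alnFiles, readAlignment)
  names(alns) <- vapply(alns, locusId, character(1))
  trees <- lapply(trFiles, readTree)
  names(trees) <- sub("\\.nwk$", "", basename(trFiles))
  spTree <- readTree(file.path(dir, "species_tree.nwk"))
  recovery <- readRecoveryTable(file.path(dir, "recovery.tsv"),
                                format = "long",
                                meta = file.path(dir, "samples.tsv"))
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else list()
  truth$expected_fraction <- unlist(truth$expected_fraction)
  truth$locus_class <- unlist(truth$locus_class)
  new("SimDataset", alignments = alns, geneTrees = trees,
      speciesTree = spTree, recovery = recovery, truth = truth,
      spec = list(seed = truth$seed))
}
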