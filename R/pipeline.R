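#' Pipeline configuration
#'
#' Bundles the stage thresholds with their conventional defaults: coverage
#' cutoff 0.5, maximum trimming data loss 0.30, diameter bound 0.20,
#' support cutoff 10, and the clock-locus criteria (concordance > 0.1,
#' root-to-tip variance < 0.024, tree length > 0.1, >= 25 taxa).
#'
#' @param coverageCutoff inclusive minimum accession coverage score.
#' @param trim a \code{\link{trimConfig}}.
#' @param treeQC a \code{\link{treeQCConfig}}.
#' @param clock a \code{\link{clockCriteria}}.
#' @param groups optional named vector mapping loci to region classes for
#'   the alignment summary table.
#' @param outDir optional directory; when given, every stage table is
#'   written there as TSV together with a JSON run manifest.
#' @return A list of class \code{qcConfig}.
#' @export
qcConfig <- function(coverageCutoff = 0.5, trim = trimConfig(),
                     treeQC = treeQCConfig(), clock = clockCriteria(),
                     groups = NULL, outDir = NULL) {
  if (coverageCutoff < 0 || coverageCutoff > 1)
    stop("coverageCutoff must be in [0, 1]")
  structure(list(coverageCutoff = coverageCutoff, trim = trim,
                 treeQC = treeQC, clock = clock, groups = groups,
                 outDir = outDir), class = "qcConfig")
}

#' Run the full QC pipeline
#'
#' Executes the stages in the order used in practice: accession coverage
#' scoring and filtering; gap-threshold trimming optimization with locus
#' discard; alignment summary statistics; diameter-outlier leaf pruning
#' (pruned taxa are also dropped from the trimmed alignments, which stands
#' in for realignment); low-support branch contraction; clock/concordance
#' statistics and locus selection; and per-bipartition concordance
#' accounting. An entity discarded at any stage is excluded downstream.
#'
#' @param ds a \linkS4class{SimDataset} (or a fixture directory path, which
#'   is read with \code{\link{readDataset}}).
#' @param cfg a \code{\link{qcConfig}}.
#' @return A list of class \code{QCReport}: per-stage tables
#'   (\code{scores}, \code{trim}, \code{alignment_stats},
#'   \code{alignment_summary}, \code{outliers}, \code{clock_report},
#'   \code{concordance}), the retained identifiers
#'   (\code{retained_accessions}, \code{retained_loci},
#'   \code{clock_loci}), a per-stage \code{counts} table and a \code{config}
#'   echo.
#' @export
runQC <- function(ds, cfg = qcConfig()) {
  if (is.character(ds)) ds <- readDataset(ds)
  if (!is(ds, "SimDataset")) stop("ds must be a SimDataset or a directory")
  if (length(ds@alignments) == 0L)
    stop("empty input: no alignments to process")
  counts <- list()
  note <- function(stage, nin, nout)
    counts[[length(counts) + 1L]] <<- data.frame(stage = stage, n_in = nin,
                                                 n_out = nout,
                                                 stringsAsFactors = FALSE)

  ## reconcile loci keyed by shared identifiers
  lociAln <- names(ds@alignments)
  lociTr <- names(ds@geneTrees)
  loci <- intersect(lociAln, lociTr)
  if (length(loci) < length(union(lociAln, lociTr)))
    warning(sprintf("%d locus id(s) present as alignment or tree only; excluded",
                    length(union(lociAln, lociTr)) - length(loci)))
  note("locus_reconciliation", length(union(lociAln, lociTr)), length(loci))

  ## stage 1: accession coverage scores
  scores <- coverageScores(ds@recovery, axis = "accessions")
  keepAcc <- filterByScore(scores, cfg$coverageCutoff)
  note("accession_coverage", nrow(scores), length(keepAcc))
  if (length(keepAcc) < 4L)
    stop("fewer than 4 accessions pass the coverage cutoff")

  alns <- lapply(ds@alignments[loci], function(a) {
    m <- as.matrix(a)
    GappedAlignment(locusId(a), m[intersect(rownames(m), keepAcc), , drop = FALSE])
  })
  trees <- lapply(ds@geneTrees[loci], function(t)
    ape::keep.tip(t, intersect(t$tip.label, keepAcc)))
  spTree <- ape::keep.tip(ds@speciesTree,
                          intersect(ds@speciesTree$tip.label, keepAcc))

  ## stage 2: trimming optimization
  trimRes <- lapply(alns, optimizeTrim, cfg = cfg$trim)
  trimTab <- do.call(rbind, lapply(trimRes, function(r) {
    before <- alignmentSummary(alns[[r@locusId]])
    data.frame(locus_id = r@locusId, chosen_gt = r@chosenGt,
               p_pic_before = before$p_pic,
               p_pic_after = if (alnWidth(r@trimmed) > 0)
                 sum(.columnFlags(as.matrix(r@trimmed))$informative) /
                   alnWidth(r@trimmed) else 0,
               data_loss = r@dataLoss, verdict = r@verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(trimTab) <- NULL
  keptLoci <- names(trimRes)[vapply(trimRes, verdict, character(1)) == "keep"]
  note("trim_optimization", length(loci), length(keptLoci))
  trimmed <- lapply(trimRes[keptLoci], trimmedAlignment)

  ## stage 3: alignment statistics on the trimmed, kept loci
  alnStats <- do.call(rbind, lapply(trimmed, alignmentSummary))
  rownames(alnStats) <- NULL
  alnSummary <- summarizeAlignments(alnStats, groups = cfg$groups)

  ## stage 4: outlier-leaf pruning (alignment rows masked, not realigned)
  outRows <- list()
  prunedTrees <- list()
  for (id in keptLoci) {
    t <- trees[[id]]
    if (length(t$tip.label) >= 4L) {
      fl <- flagOutlierLeaves(t, cfg$treeQC)
      prunedTrees[[id]] <- fl$tree
      if (length(fl$flagged))
        outRows[[id]] <- data.frame(locus_id = id, leaf = fl$flagged,
                                    stringsAsFactors = FALSE)
      if (length(fl$flagged)) {
        m <- as.matrix(trimmed[[id]])
        trimmed[[id]] <- GappedAlignment(id,
          m[setdiff(rownames(m), fl$flagged), , drop = FALSE])
      }
    } else {
      prunedTrees[[id]] <- t
    }
  }
  outliers <- if (length(outRows)) do.call(rbind, c(outRows, list(make.row.names = FALSE)))
              else data.frame(locus_id = character(0), leaf = character(0))
  note("outlier_leaves", sum(vapply(trees[keptLoci], function(t)
    length(t$tip.label), integer(1))),
    sum(vapply(prunedTrees, function(t) length(t$tip.label), integer(1))))

  ## stage 5: low-support contraction
  collapsed <- lapply(prunedTrees, collapseLowSupport, cfg = cfg$treeQC)

  ## stage 6: clock statistics and locus selection
  clockTab <- do.call(rbind, lapply(keptLoci, function(id)
    clockStats(collapsed[[id]], speciesTree = spTree, cfg = cfg$treeQC,
               locusId = id)))
  sel <- selectClockLoci(clockTab, cfg$clock)
  note("clock_selection", length(keptLoci), length(sel$retained))

  ## stage 7: concordance accounting across all kept gene trees
  concord <- concordancePies(collapsed, spTree)

  report <- structure(list(
    scores = scores,
    retained_accessions = keepAcc,
    trim = trimTab,
    alignment_stats = alnStats,
    alignment_summary = alnSummary,
    outliers = outliers,
    clock_report = sel$report,
    clock_loci = sel$retained,
    retained_loci = keptLoci,
    concordance = concord,
    trimmed_alignments = trimmed,
    final_trees = collapsed,
    counts = do.call(rbind, counts),
    config = cfg), class = "QCReport")
  if (!is.null(cfg$outDir)) writeQCReport(report, cfg$outDir)
  report
}

#' Write a QCReport's tables to a directory
#'
#' Tables are written as TSV with fixed formatting so identical runs produce
#' byte-identical files; a JSON manifest echoes the configuration.
#'
#' @param report a \code{QCReport} from \code{\link{runQC}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeQCReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(report$scores, "scores.tsv")
  wt(report$trim, "trim_report.tsv")
  wt(report$alignment_stats, "alignment_stats.tsv")
  wt(report$alignment_summary, "alignment_summary.tsv")
  wt(report$outliers, "outlier_leaves.tsv")
  wt(report$clock_report, "clock_report.tsv")
  wt(report$concordance, "concordance.tsv")
  wt(report$counts, "stage_counts.tsv")
  cfg <- report$config
  manifest <- list(
    retained_accessions = report$retained_accessions,
    retained_loci = report$retained_loci,
    clock_loci = report$clock_loci,
    thresholds = list(coverage_cutoff = cfg$coverageCutoff,
                      max_data_loss = cfg$trim$maxDataLoss,
                      gap_thresholds = cfg$trim$thresholds,
                      diameter_bound = cfg$treeQC$diameterBound,
                      support_cutoff = cfg$treeQC$supportCutoff,
                      min_concordance = cfg$clock$minConcordance,
                      max_rtt_variance = cfg$clock$maxRttVariance,
                      min_tree_length = cfg$clock$minTreeLength,
                      min_taxa = cfg$clock$minTaxa))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("hybQC pipeline report\n")
  cat(sprintf("  accessions retained: %d of %d\n",
              length(x$retained_accessions), nrow(x$scores)))
  cat(sprintf("  loci kept after trimming: %d\n", length(x$retained_loci)))
  cat(sprintf("  outlier leaves flagged: %d\n", nrow(x$outliers)))
  cat(sprintf("  clock-grade loci: %d\n", length(x$clock_loci)))
  cat("  per-stage counts:\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}
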