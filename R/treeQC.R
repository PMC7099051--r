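#' Configuration for tree-level QC
#'
#' @param diameterBound relative diameter-increase bound above which a leaf
#'   is flagged as an outlier (default 0.20).
#' @param supportCutoff integer 0-100; internal edges with support less than
#'   or equal to this value are contracted (default 10; the rule is
#'   inclusive).
#' @param rooting \code{"midpoint"} (default), \code{"outgroup"}, or
#'   \code{"given"} to keep the rooting the tree already carries.
#' @param outgroup character vector of outgroup tips, required when
#'   \code{rooting = "outgroup"}.
#' @return A validated list of class \code{treeQCConfig}.
#' @export
treeQCConfig <- function(diameterBound = 0.20, supportCutoff = 10,
                         rooting = c("midpoint", "outgroup", "given"),
                         outgroup = NULL) {
  rooting <- match.arg(rooting)
  if (diameterBound <= 0) stop("diameterBound must be > 0")
  if (supportCutoff < 0 || supportCutoff > 100)
    stop("supportCutoff must be in [0, 100]")
  if (rooting == "outgroup" && is.null(outgroup))
    stop("outgroup rooting requires outgroup tips")
  structure(list(diameterBound = diameterBound, supportCutoff = supportCutoff,
                 rooting = rooting, outgroup = outgroup),
            class = "treeQCConfig")
}

#' Selection thresholds for clock-like loci
#'
#' Defaults follow the usual practice for selecting dating-grade loci:
#' concordance with the species tree strictly above 0.1, root-to-tip
#' variance strictly below 0.024, tree length strictly above 0.1, and at
#' least 25 taxa.
#'
#' @param minConcordance strict lower bound on species-tree concordance.
#' @param maxRttVariance strict upper bound on root-to-tip variance
#'   (squared substitutions/site).
#' @param minTreeLength strict lower bound on total tree length
#'   (substitutions/site).
#' @param minTaxa inclusive lower bound on the number of taxa.
#' @return A validated list of class \code{clockCriteria}.
#' @export
clockCriteria <- function(minConcordance = 0.1, maxRttVariance = 0.024,
                          minTreeLength = 0.1, minTaxa = 25) {
  structure(list(minConcordance = minConcordance,
                 maxRttVariance = maxRttVariance,
                 minTreeLength = minTreeLength, minTaxa = minTaxa),
            class = "clockCriteria")
}

#' Tree diameter
#'
#' Maximum leaf-to-leaf path length (sum of branch lengths).
#'
#' @param tree an ape \code{phylo} object with branch lengths.
#' @return The diameter; 0 for a tree with fewer than 2 leaves.
#' @export
treeDiameter <- function(tree) {
  if (length(tree$tip.label) < 2L) return(0)
  if (is.null(tree$edge.length))
    stop(sprintf("missing branch lengths on all %d edges", nrow(tree$edge)))
  max(ape::cophenetic.phylo(tree))
}

#' Flag and prune diameter-outlier leaves
#'
#' Greedy analogue of signature-based long-branch pruning: at each step the
#' leaf whose removal shrinks the tree diameter the most is flagged if its
#' relative diameter contribution (D - D_without) / D_without exceeds
#' \code{diameterBound}; flagged leaves are removed and the loop repeats
#' until no leaf exceeds the bound.
#'
#' @param tree an ape \code{phylo} with branch lengths and >= 4 leaves.
#' @param cfg a \code{\link{treeQCConfig}}.
#' @return List with \code{flagged} (character vector, flagging order) and
#'   \code{tree} (the pruned \code{phylo}). Pruning stops with a warning
#'   rather than reducing the tree below 3 leaves.
#' @export
flagOutlierLeaves <- function(tree, cfg = treeQCConfig()) {
  if (length(tree$tip.label) < 4L) stop("need at least 4 leaves")
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  flagged <- character(0)
  repeat {
    if (length(tree$tip.label) < 3L) break
    d <- ape::cophenetic.phylo(tree)
    D <- max(d)
    if (D <= 0) break
    ratios <- vapply(seq_along(tree$tip.label), function(i) {
      Dm <- max(d[-i, -i])
      if (Dm <= 0) Inf else (D - Dm) / Dm
    }, numeric(1))
    i <- which.max(ratios)
    if (!(ratios[i] > cfg$diameterBound)) break
    if (length(tree$tip.label) - 1L < 3L) {
      warning("stopped pruning: removing another leaf would leave fewer than 3")
      break
    }
    flagged <- c(flagged, tree$tip.label[i])
    tree <- ape::drop.tip(tree, tree$tip.label[i])
  }
  list(flagged = flagged, tree = tree)
}

#' Contract low-support branches into polytomies
#'
#' Every internal edge whose support value is less than or equal to
#' \code{supportCutoff} is spliced out: the child node's descendants are
#' reattached to its parent and the contracted edge's length is added to the
#' child edges, preserving tip depths. Edges with unknown (absent or
#' non-numeric) support are retained. The leaf set never changes and the
#' operation is idempotent.
#'
#' @param tree an ape \code{phylo}; support is read from internal node
#'   labels (see \code{\link{edgeSupport}}).
#' @param cfg a \code{\link{treeQCConfig}}.
#' @return The contracted \code{phylo}.
#' @export
collapseLowSupport <- function(tree, cfg = treeQCConfig()) {
  if (is.null(tree$node.label)) return(tree)
  repeat {
    ntip <- length(tree$tip.label)
    sup <- edgeSupport(tree)
    root <- ntip + 1L
    idx <- which(!is.na(sup) & sup <= cfg$supportCutoff & tree$edge[, 2L] != root)
    if (!length(idx)) break
    e <- idx[1L]
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    kids <- which(tree$edge[, 1L] == ch)
    tree$edge[kids, 1L] <- p
    if (!is.null(tree$edge.length))
      tree$edge.length[kids] <- tree$edge.length[kids] + tree$edge.length[e]
    tree$edge <- tree$edge[-e, , drop = FALSE]
    if (!is.null(tree$edge.length)) tree$edge.length <- tree$edge.length[-e]
    tree$node.label <- tree$node.label[-(ch - ntip)]
    tree$edge[tree$edge > ch] <- tree$edge[tree$edge > ch] - 1L
    tree$Nnode <- tree$Nnode - 1L
  }
  ape::reorder.phylo(tree, "cladewise")
}

## --- bipartition utilities -------------------------------------------------

## Canonical key of a split: the side NOT containing the alphabetically
## first taxon of the universe, sorted and pasted.
.splitKey <- function(side, taxaSet) {
  ref <- min(taxaSet)
  if (ref %in% side) side <- setdiff(taxaSet, side)
  paste(sort(side), collapse = "\r")
}

## All nontrivial splits of a tree, keyed canonically. Returns a named list
## of character vectors (the canonical side).
.treeSplits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  out <- list()
  if (n < 4L) return(out)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  for (cl in pp) {
    side <- labs[cl]
    k <- length(side)
    if (k < 2L || k > n - 2L) next
    key <- .splitKey(side, tips)
    if (is.null(out[[key]]))
      out[[key]] <- sort(side)   # display side: the clade as encountered
  }
  out
}

## Two splits (given as one side each) on the same taxon universe are
## compatible iff one of the four intersections is empty.
.splitsCompatible <- function(a, b, taxaSet) {
  a2 <- setdiff(taxaSet, a); b2 <- setdiff(taxaSet, b)
  length(intersect(a, b)) == 0L || length(intersect(a, b2)) == 0L ||
    length(intersect(a2, b)) == 0L || length(intersect(a2, b2)) == 0L
}

#' Clock and concordance statistics for one gene tree
#'
#' Computes the root-to-tip variance (sample variance of root-to-tip path
#' lengths after rooting), the tree length (sum of branch lengths), the
#' taxon count, and the concordance with a species tree: the fraction of
#' internal bipartitions of the species tree, pruned to the taxa shared
#' with the gene tree, that also occur in the gene tree.
#'
#' @param tree an ape \code{phylo} gene tree with branch lengths.
#' @param speciesTree an ape \code{phylo} species tree; pass \code{NULL} to
#'   skip concordance (reported as \code{NA}).
#' @param cfg a \code{\link{treeQCConfig}}; controls rooting (midpoint by
#'   default).
#' @return One-row data.frame: \code{locus_id}, \code{rtt_variance},
#'   \code{tree_length}, \code{n_taxa}, \code{concordance}.
#' @param locusId identifier recorded in the output row.
#' @export
clockStats <- function(tree, speciesTree = NULL, cfg = treeQCConfig(),
                       locusId = "locus") {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 leaves")
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  rooted <- if (cfg$rooting == "outgroup") {
    og <- intersect(cfg$outgroup, tree$tip.label)
    if (!length(og)) stop("no outgroup tips present in the tree")
    ape::root(tree, outgroup = og, resolve.root = TRUE)
  } else if (cfg$rooting == "given" || ntip == 2L) {
    if (cfg$rooting == "given" && !ape::is.rooted(tree))
      stop("rooting = 'given' requires a rooted tree")
    tree
  } else {
    phangorn::midpoint(tree)
  }
  depths <- ape::node.depth.edgelength(rooted)[seq_len(ntip)]
  rtt <- stats::var(depths)
  conc <- NA_real_
  if (!is.null(speciesTree)) {
    shared <- intersect(tree$tip.label, speciesTree$tip.label)
    if (length(shared) < 2L)
      stop("concordance undefined: fewer than 2 taxa shared with the species tree")
    spP <- ape::keep.tip(speciesTree, shared)
    gnP <- ape::keep.tip(tree, shared)
    spS <- .treeSplits(spP)
    conc <- if (length(spS) == 0L) NA_real_ else {
      gnS <- .treeSplits(gnP)
      mean(names(spS) %in% names(gnS))
    }
  }
  data.frame(locus_id = locusId, rtt_variance = rtt,
             tree_length = sum(tree$edge.length), n_taxa = ntip,
             concordance = conc, stringsAsFactors = FALSE)
}

#' Select clock-like, informative loci
#'
#' Applies the four selection rules jointly: concordance strictly above
#' \code{minConcordance}, root-to-tip variance strictly below
#' \code{maxRttVariance}, tree length strictly above \code{minTreeLength},
#' and taxon count at least \code{minTaxa}.
#'
#' @param stats data.frame of rows from \code{\link{clockStats}}.
#' @param criteria a \code{\link{clockCriteria}}.
#' @return List with \code{retained} (character vector of locus ids) and
#'   \code{report} (per-locus data.frame with logical columns for each rule
#'   and \code{failed}, a comma-separated list of failed rules).
#' @export
selectClockLoci <- function(stats, criteria = clockCriteria()) {
  if (nrow(stats) == 0L)
    return(list(retained = character(0),
                report = cbind(stats, failed = character(0))))
  okConc <- stats$concordance > criteria$minConcordance
  okRtt <- stats$rtt_variance < criteria$maxRttVariance
  okLen <- stats$tree_length > criteria$minTreeLength
  okTaxa <- stats$n_taxa >= criteria$minTaxa
  ok <- okConc & okRtt & okLen & okTaxa
  ok[is.na(ok)] <- FALSE
  failed <- vapply(seq_len(nrow(stats)), function(i) {
    f <- c(if (!isTRUE(okConc[i])) "concordance",
           if (!isTRUE(okRtt[i])) "rtt_variance",
           if (!isTRUE(okLen[i])) "tree_length",
           if (!isTRUE(okTaxa[i])) "n_taxa")
    paste(f, collapse = ",")
  }, character(1))
  report <- cbind(stats,
                  pass_concordance = okConc, pass_rtt = okRtt,
                  pass_length = okLen, pass_taxa = okTaxa,
                  retained = ok, failed = failed)
  list(retained = stats$locus_id[ok], report = report)
}

#' Gene-tree concordance summaries per species-tree bipartition
#'
#' For every internal bipartition of the species tree, counts the gene trees
#' that support it, conflict with it, or are uninformative about it. A gene
#' tree supports a bipartition when the bipartition, restricted to the taxa
#' shared with that gene tree, still has at least two taxa on each side and
#' occurs among the gene tree's bipartitions; it conflicts when the gene
#' tree contains a bipartition on the same restricted taxon set that is
#' incompatible with it; otherwise (including unresolved polytomies) it is
#' uninformative.
#'
#' @param geneTrees list of ape \code{phylo} gene trees.
#' @param speciesTree an ape \code{phylo}, binary on its leaf set.
#' @return data.frame with one row per internal species-tree bipartition:
#'   \code{node_id} (canonical clade label), \code{n_concord},
#'   \code{n_conflict}, \code{n_uninformative}; the three counts sum to the
#'   number of gene trees.
#' @export
concordancePies <- function(geneTrees, speciesTree) {
  spS <- .treeSplits(speciesTree)
  spTips <- speciesTree$tip.label
  if (length(spS) == 0L)
    return(data.frame(node_id = character(0), n_concord = integer(0),
                      n_conflict = integer(0), n_uninformative = integer(0),
                      stringsAsFactors = FALSE))
  ## gene splits and shared taxa are independent of the bipartition: cache
  geneInfo <- lapply(geneTrees, function(g) {
    shared <- intersect(g$tip.label, spTips)
    gP <- if (length(shared) >= 4L) ape::keep.tip(g, shared) else NULL
    list(shared = shared,
         splits = if (is.null(gP)) list() else .treeSplits(gP))
  })
  rows <- lapply(names(spS), function(key) {
    side <- spS[[key]]
    nC <- 0L; nX <- 0L; nU <- 0L
    for (gi in geneInfo) {
      sideR <- intersect(side, gi$shared)
      otherR <- setdiff(gi$shared, sideR)
      if (length(sideR) < 2L || length(otherR) < 2L) {
        nU <- nU + 1L
        next
      }
      keyR <- .splitKey(sideR, gi$shared)
      if (keyR %in% names(gi$splits)) {
        nC <- nC + 1L
      } else {
        conflict <- any(vapply(gi$splits, function(gs)
          !.splitsCompatible(sideR, gs, gi$shared), logical(1)))
        if (conflict) nX <- nX + 1L else nU <- nU + 1L
      }
    }
    data.frame(node_id = paste(side, collapse = "|"),
               n_concord = nC, n_conflict = nX, n_uninformative = nU,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
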