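#' Configuration for gap-threshold trimming optimization
#'
#' @param thresholds strictly increasing gap-threshold grid in [0, 1].
#'   Default is 0 to 1 in steps of 0.1.
#' @param maxDataLoss maximum tolerated fraction of non-gap residues lost to
#'   trimming before a locus is discarded (default 0.30).
#' @param lossMetric \code{"residues"} (default) measures data loss as the
#'   fraction of non-gap characters removed; \code{"columns"} as the
#'   fraction of alignment columns removed.
#' @return A validated list of class \code{trimConfig}.
#' @export
trimConfig <- function(thresholds = seq(0, 1, by = 0.1), maxDataLoss = 0.30,
                       lossMetric = c("residues", "columns")) {
  lossMetric <- match.arg(lossMetric)
  if (length(thresholds) == 0L) stop("empty threshold list")
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must be in [0, 1]")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (maxDataLoss < 0 || maxDataLoss > 1) stop("maxDataLoss must be in [0, 1]")
  structure(list(thresholds = thresholds, maxDataLoss = maxDataLoss,
                 lossMetric = lossMetric), class = "trimConfig")
}

## Numeric slack for threshold comparisons: a column whose non-gap fraction
## equals the threshold up to floating error is kept (>= semantics).
.GT_EPS <- 1e-9

#' Trim alignment columns at a gap threshold
#'
#' Keeps exactly the columns whose fraction of non-gap characters (gap is
#' \code{-}; \code{?} and \code{N} count as present) is at least \code{gt},
#' the conventional gap-threshold semantics. Row order and taxa are
#' preserved; \code{gt = 0} keeps all columns and \code{gt = 1} keeps only
#' gap-free columns.
#'
#' @param aln a \linkS4class{GappedAlignment}.
#' @param gt gap threshold in [0, 1].
#' @return The trimmed \linkS4class{GappedAlignment}.
#' @export
trimAtThreshold <- function(aln, gt) {
  if (gt < 0 || gt > 1) stop("gt must be in [0, 1]")
  m <- as.matrix(aln)
  if (ncol(m) == 0L || nrow(m) == 0L) return(aln)
  nonGap <- colMeans(m != "-")
  keep <- nonGap >= gt - .GT_EPS
  GappedAlignment(locusId(aln), m[, keep, drop = FALSE])
}

#' Fraction of data lost by trimming
#'
#' By default, one minus the ratio of non-gap residue counts
#' (trimmed / original); \code{?} and \code{N} count as present residues.
#' The column metric is one minus the ratio of column counts.
#'
#' @param original the untrimmed \linkS4class{GappedAlignment}.
#' @param trimmed an alignment derived from \code{original} by column
#'   removal.
#' @param metric \code{"residues"} (default) or \code{"columns"}.
#' @return Data-loss fraction in [0, 1]; 0 for identical alignments.
#' @export
dataLoss <- function(original, trimmed, metric = c("residues", "columns")) {
  metric <- match.arg(metric)
  if (metric == "columns") {
    if (alnWidth(original) == 0L) stop("data loss undefined: original has no columns")
    return(1 - alnWidth(trimmed) / alnWidth(original))
  }
  res0 <- sum(as.matrix(original) != "-")
  if (res0 == 0L) stop("data loss undefined: original has no non-gap residues")
  res1 <- sum(as.matrix(trimmed) != "-")
  1 - res1 / res0
}

#' Optimize the gap threshold for one alignment
#'
#' Sweeps every threshold in the grid, scores each trimmed alignment by its
#' proportion of parsimony-informative characters (P_PIC), and selects,
#' among thresholds whose data loss does not exceed \code{maxDataLoss}, the
#' one maximizing P_PIC. Ties are broken by the lowest threshold (retaining
#' more sequence length). The locus is discarded when no threshold keeps
#' data loss within bounds, or when the best attainable P_PIC is 0.
#'
#' @param aln a \linkS4class{GappedAlignment}; parsimony-informative sites
#'   require at least 4 sequences.
#' @param cfg a \code{\link{trimConfig}}.
#' @return A \linkS4class{TrimResult} carrying the full per-threshold curve.
#' @examples
#' aln <- GappedAlignment("l", c(a = "AAA-", b = "AAC-", c = "C-A-", d = "C-CA"))
#' res <- optimizeTrim(aln, trimConfig(thresholds = c(0.3, 0.6)))
#' chosenGt(res)   # 0.6
#' verdict(res)    # "keep"
#' @export
optimizeTrim <- function(aln, cfg = trimConfig()) {
  if (!inherits(cfg, "trimConfig")) stop("cfg must come from trimConfig()")
  m <- as.matrix(aln)
  L <- ncol(m)
  ## Per-column invariants: informativeness of a column does not depend on
  ## which other columns survive, so one pass suffices for the whole sweep.
  flags <- .columnFlags(m)
  nonGap <- if (L) colMeans(m != "-") else numeric(0)
  residCol <- if (L) colSums(m != "-") else numeric(0)
  totalResid <- sum(residCol)
  curve <- do.call(rbind, lapply(cfg$thresholds, function(gt) {
    keep <- nonGap >= gt - .GT_EPS
    nCol <- sum(keep)
    loss <- if (cfg$lossMetric == "columns") {
      if (L == 0L) 0 else 1 - nCol / L
    } else {
      if (totalResid == 0L) 0 else 1 - sum(residCol[keep]) / totalResid
    }
    data.frame(gt = gt,
               p_pic = if (nCol > 0L) sum(flags$informative[keep]) / nCol else 0,
               data_loss = loss,
               n_col = nCol)
  }))
  feasible <- curve$data_loss <= cfg$maxDataLoss + .GT_EPS
  if (any(feasible)) {
    sub <- curve[feasible, , drop = FALSE]
    best <- sub[which.max(sub$p_pic), ]   # which.max -> first max -> lowest gt
    keepIt <- best$p_pic > 0
    chosen <- if (keepIt) best$gt else NA_real_
    trimmed <- trimAtThreshold(aln, best$gt)
    loss <- best$data_loss
  } else {
    keepIt <- FALSE
    chosen <- NA_real_
    trimmed <- aln
    loss <- 0
  }
  new("TrimResult", locusId = locusId(aln), chosenGt = chosen,
      trimmed = trimmed, dataLoss = loss, curve = curve,
      verdict = if (keepIt) "keep" else "discard")
}
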