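#' Is an alignment column parsimony-informative?
#'
#' A column is parsimony-informative when, counting only unambiguous
#' nucleotide states (A, C, G, T), at least two distinct states each occur
#' in at least two sequences. Gaps, \code{?}, \code{N} and IUPAC partial
#' ambiguities do not count as states.
#'
#' @param column character vector of single residues (case-insensitive).
#' @return \code{TRUE} or \code{FALSE}.
#' @examples
#' isParsimonyInformative(c("A", "A", "C", "C"))  # TRUE
#' isParsimonyInformative(c("A", "C", "G", "T"))  # FALSE
#' @export
isParsimonyInformative <- function(column) {
  cnt <- table(factor(toupper(column), levels = .DNA_STATES))
  sum(cnt >= 2L) >= 2L
}

## Vectorised per-column machinery shared by alignmentSummary, the trim
## optimizer and the simulator. Returns a list of per-column logical flags.
.columnFlags <- function(m) {
  L <- ncol(m)
  if (L == 0L || nrow(m) == 0L)
    return(list(informative = logical(L), variable = logical(L)))
  cnt <- vapply(.DNA_STATES, function(b) colSums(m == b), numeric(L))
  if (L == 1L) cnt <- matrix(cnt, nrow = 1L)
  list(informative = rowSums(cnt >= 2L) >= 2L,
       variable = rowSums(cnt >= 1L) >= 2L)
}

#' Per-alignment summary statistics
#'
#' Computes the alignment length, the number and proportion of
#' parsimony-informative columns (P_PIC), the number of variable columns and
#' the missing-data fraction, in the style of standard alignment summary
#' tools.
#'
#' @param aln a \linkS4class{GappedAlignment}.
#' @param ambiguousAsMissing if \code{TRUE}, IUPAC partial ambiguity codes
#'   (R, Y, S, W, ...) are counted as missing in \code{missing_frac} in
#'   addition to the default missing set \{-, ?, N\}. They are never counted
#'   as states either way.
#' @return A one-row data.frame with columns \code{locus_id}, \code{length},
#'   \code{n_taxa}, \code{n_pic}, \code{p_pic}, \code{n_variable},
#'   \code{missing_frac} and \code{degenerate} (TRUE for zero-length or
#'   empty alignments).
#' @examples
#' aln <- GappedAlignment("l", c(a = "AAA", b = "ACA", c = "CGA", d = "CTC"))
#' alignmentSummary(aln)$p_pic  # 1/3
#' @export
alignmentSummary <- function(aln, ambiguousAsMissing = FALSE) {
  m <- as.matrix(aln)
  L <- ncol(m); nt <- nrow(m)
  flags <- .columnFlags(m)
  nPic <- sum(flags$informative)
  nVar <- sum(flags$variable)
  missSet <- .MISSING_CHARS
  if (ambiguousAsMissing) missSet <- c(missSet, .IUPAC_PARTIAL)
  missFrac <- if (L > 0L && nt > 0L) mean(m %in% missSet) else 0
  data.frame(
    locus_id = locusId(aln),
    length = L,
    n_taxa = nt,
    n_pic = nPic,
    p_pic = if (L > 0L) nPic / L else 0,
    n_variable = nVar,
    missing_frac = missFrac,
    degenerate = L == 0L || nt == 0L,
    stringsAsFactors = FALSE)
}

#' Summarize alignment statistics over locus classes
#'
#' Aggregates per-locus statistics into per-class means and sample standard
#' deviations of alignment length, P_PIC (in percent) and missing data
#' (in percent), plus an overall row, in the layout of the usual
#' region-class summary tables.
#'
#' @param stats data.frame of per-locus rows as returned by
#'   \code{\link{alignmentSummary}} (row-bound).
#' @param groups optional named character vector mapping \code{locus_id} to a
#'   class label; unlisted loci are grouped as \code{"unclassified"}. When
#'   \code{NULL} all loci form a single class.
#' @return data.frame with one row per class plus an \code{"all"} row:
#'   columns \code{class}, \code{n_loci}, \code{mean_length},
#'   \code{sd_length}, \code{mean_p_pic_pct}, \code{sd_p_pic_pct},
#'   \code{mean_missing_pct}, \code{sd_missing_pct},
#'   \code{single_member} (TRUE when the class has one locus, whose SDs are
#'   reported as 0).
#' @export
summarizeAlignments <- function(stats, groups = NULL) {
  if (!is.data.frame(stats) || nrow(stats) == 0L)
    stop("empty statistics table")
  cls <- if (is.null(groups)) rep("all_loci", nrow(stats)) else {
    g <- groups[stats$locus_id]
    g[is.na(g)] <- "unclassified"
    unname(g)
  }
  oneClass <- function(idx, label) {
    s <- stats[idx, , drop = FALSE]
    sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    data.frame(
      class = label,
      n_loci = nrow(s),
      mean_length = mean(s$length),
      sd_length = sd0(s$length),
      mean_p_pic_pct = mean(100 * s$p_pic),
      sd_p_pic_pct = sd0(100 * s$p_pic),
      mean_missing_pct = mean(100 * s$missing_frac),
      sd_missing_pct = sd0(100 * s$missing_frac),
      single_member = nrow(s) == 1L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(cls)),
                               function(cl) oneClass(which(cls == cl), cl)))
  rbind(out, oneClass(seq_len(nrow(stats)), "all"))
}
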