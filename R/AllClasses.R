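#' @import methods
#' @importFrom stats var sd lm pf setNames t.test rnorm runif rbeta rlnorm
#' @importFrom utils read.delim write.table
NULL

## Characters treated as missing data in summary statistics. IUPAC partial
## ambiguities (R, Y, S, W, K, M, B, D, H, V) are excluded from state counts
## but are NOT missing under the default convention.
.MISSING_CHARS <- c("-", "?", "N")
.IUPAC_PARTIAL <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.DNA_STATES <- c("A", "C", "G", "T")

#' GappedAlignment: one per-locus multiple sequence alignment
#'
#' A rectangular, gapped DNA alignment for a single locus. Rows are
#' accessions, columns are alignment positions. Residues are stored
#' upper-case over the alphabet A, C, G, T, IUPAC ambiguity codes, N,
#' \code{-} (gap) and \code{?} (unknown).
#'
#' @slot locusId single character identifier for the locus.
#' @slot seqs character matrix of single characters with unique, non-empty
#'   rownames (the accession identifiers). May have zero rows or columns.
#'
#' @examples
#' aln <- GappedAlignment("loc1", c(acc1 = "ACG-", acc2 = "AC?T"))
#' nTaxa(aln)
#' alnWidth(aln)
#' @export
setClass("GappedAlignment",
  representation(locusId = "character", seqs = "matrix"))

setValidity("GappedAlignment", function(object) {
  m <- object@seqs
  if (length(object@locusId) != 1L || is.na(object@locusId))
    return("locusId must be a single non-NA string")
  if (!is.character(m))
    return("seqs must be a character matrix")
  if (nrow(m) > 0L) {
    if (is.null(rownames(m)) || any(rownames(m) == "") || anyNA(rownames(m)))
      return("all rows must be named by accession")
    if (anyDuplicated(rownames(m)))
      return(sprintf("duplicate accession label: %s",
                     rownames(m)[duplicated(rownames(m))][1L]))
  }
  if (length(m) && any(nchar(m) != 1L))
    return("seqs must hold single characters")
  TRUE
})

#' Construct a GappedAlignment
#'
#' @param locusId locus identifier.
#' @param seqs either a named character vector of equal-length sequence
#'   strings, or a character matrix of single characters with rownames.
#' @return A \linkS4class{GappedAlignment}.
#' @export
GappedAlignment <- function(locusId, seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else if (length(seqs) == 0L) {
    m <- matrix(character(0), nrow = 0L, ncol = 0L)
  } else {
    w <- nchar(seqs)
    if (length(unique(w)) > 1L) {
      bad <- names(seqs)[which(w != w[1L])[1L]]
      stop(sprintf("malformed alignment '%s': row '%s' has length %d, expected %d",
                   locusId, bad, w[w != w[1L]][1L], w[1L]))
    }
    m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
    rownames(m) <- names(seqs)
  }
  if (length(m)) m[] <- toupper(m)
  new("GappedAlignment", locusId = as.character(locusId), seqs = m)
}

#' @describeIn GappedAlignment locus identifier accessor
#' @param x,object a \code{GappedAlignment}.
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))

#' @rdname GappedAlignment-class
#' @export
setMethod("locusId", "GappedAlignment", function(x) x@locusId)

#' @describeIn GappedAlignment accession identifiers, in input order
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname GappedAlignment-class
#' @export
setMethod("taxa", "GappedAlignment", function(x) rownames(x@seqs) %||% character(0))

#' @describeIn GappedAlignment number of rows (accessions)
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname GappedAlignment-class
#' @export
setMethod("nTaxa", "GappedAlignment", function(x) nrow(x@seqs))

#' @describeIn GappedAlignment number of alignment columns (bp)
#' @export
setGeneric("alnWidth", function(x) standardGeneric("alnWidth"))

#' @rdname GappedAlignment-class
#' @export
setMethod("alnWidth", "GappedAlignment", function(x) ncol(x@seqs))

#' @rdname GappedAlignment-class
#' @export
setMethod("as.matrix", "GappedAlignment", function(x) x@seqs)

setMethod("show", "GappedAlignment", function(object) {
  cat(sprintf("GappedAlignment '%s': %d taxa x %d columns\n",
              object@locusId, nrow(object@seqs), ncol(object@seqs)))
  if (nrow(object@seqs)) {
    shown <- utils::head(rownames(object@seqs), 4L)
    for (t in shown) {
      s <- paste(object@seqs[t, seq_len(min(50L, ncol(object@seqs)))], collapse = "")
      cat(sprintf("  %-15s %s%s\n", t, s, if (ncol(object@seqs) > 50L) "..." else ""))
    }
    if (nrow(object@seqs) > 4L) cat(sprintf("  ... %d more\n", nrow(object@seqs) - 4L))
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' RecoveryMatrix: per-accession, per-locus sequence recovery
#'
#' Records how much of each target locus was recovered for each accession,
#' together with per-locus target (reference) lengths, per-accession sample
#' metadata (collection year, tissue source) and optional read counts.
#'
#' @slot recovered numeric matrix, accessions x loci, of recovered lengths
#'   (bp); zero means the locus was not recovered for that accession.
#' @slot targetLength named numeric vector of per-locus reference lengths
#'   (bp), all positive, names matching \code{colnames(recovered)}.
#' @slot meta data.frame with one row per accession: columns
#'   \code{accession}, and optionally \code{collection_year} and
#'   \code{source} (one of \code{herbarium}, \code{dna_bank}, \code{silica}).
#' @slot reads data.frame with one row per accession: columns
#'   \code{accession}, \code{reads_total}, \code{reads_on_target}; may have
#'   zero rows when read counts are unknown.
#'
#' @examples
#' rec <- matrix(c(100, 0, 50, 100), 2, 2,
#'               dimnames = list(c("a1", "a2"), c("l1", "l2")))
#' m <- RecoveryMatrix(rec, c(l1 = 100, l2 = 100))
#' captureSuccess(50, 100)
#' @export
setClass("RecoveryMatrix",
  representation(recovered = "matrix", targetLength = "numeric",
                 meta = "data.frame", reads = "data.frame"))

setValidity("RecoveryMatrix", function(object) {
  r <- object@recovered
  if (!is.numeric(r)) return("recovered must be numeric")
  if (length(r) && any(r < 0)) return("recovered_length must be >= 0")
  if (ncol(r) != length(object@targetLength))
    return("one target length per locus is required")
  if (any(object@targetLength <= 0)) return("target_length must be > 0")
  if (!is.null(colnames(r)) &&
      !identical(colnames(r), names(object@targetLength)))
    return("targetLength names must match locus columns")
  if (nrow(object@meta) && !identical(object@meta$accession, rownames(r)))
    return("meta rows must match accessions")
  if (nrow(object@reads)) {
    if (!all(c("reads_total", "reads_on_target") %in% names(object@reads)))
      return("reads needs reads_total and reads_on_target")
    ok <- with(object@reads, reads_on_target <= reads_total)
    if (!all(ok, na.rm = TRUE)) return("reads_on_target must be <= reads_total")
  }
  TRUE
})

#' Construct a RecoveryMatrix
#'
#' @param recovered accessions x loci numeric matrix of recovered lengths (bp).
#' @param targetLength named numeric vector of per-locus target lengths (bp).
#' @param meta optional per-accession metadata data.frame (columns
#'   \code{accession}, \code{collection_year}, \code{source}).
#' @param reads optional per-accession read-count data.frame (columns
#'   \code{accession}, \code{reads_total}, \code{reads_on_target}).
#' @return A \linkS4class{RecoveryMatrix}.
#' @export
RecoveryMatrix <- function(recovered, targetLength, meta = NULL, reads = NULL) {
  if (is.null(colnames(recovered)))
    colnames(recovered) <- names(targetLength)
  targetLength <- targetLength[colnames(recovered)]
  if (is.null(meta))
    meta <- data.frame(accession = rownames(recovered) %||% character(0),
                       stringsAsFactors = FALSE)
  if (is.null(reads))
    reads <- data.frame(accession = character(0), reads_total = numeric(0),
                        reads_on_target = numeric(0), stringsAsFactors = FALSE)
  new("RecoveryMatrix", recovered = recovered,
      targetLength = targetLength, meta = meta, reads = reads)
}

#' @describeIn RecoveryMatrix recovered-length matrix accessor
#' @param x,object a \code{RecoveryMatrix}.
#' @export
setGeneric("recovered", function(x) standardGeneric("recovered"))

#' @rdname RecoveryMatrix-class
#' @export
setMethod("recovered", "RecoveryMatrix", function(x) x@recovered)

#' @describeIn RecoveryMatrix per-locus target lengths (bp)
#' @export
setGeneric("targetLength", function(x) standardGeneric("targetLength"))

#' @rdname RecoveryMatrix-class
#' @export
setMethod("targetLength", "RecoveryMatrix", function(x) x@targetLength)

#' @describeIn RecoveryMatrix per-accession metadata
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname RecoveryMatrix-class
#' @export
setMethod("sampleMeta", "RecoveryMatrix", function(x) x@meta)

#' @describeIn RecoveryMatrix per-accession read counts (may be empty)
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname RecoveryMatrix-class
#' @export
setMethod("readCounts", "RecoveryMatrix", function(x) x@reads)

setMethod("show", "RecoveryMatrix", function(object) {
  cat(sprintf("RecoveryMatrix: %d accessions x %d loci\n",
              nrow(object@recovered), ncol(object@recovered)))
  nz <- mean(object@recovered > 0)
  cat(sprintf("  non-empty cells: %.1f%%; target lengths %d-%d bp\n",
              100 * nz, as.integer(min(object@targetLength)),
              as.integer(max(object@targetLength))))
  if ("source" %in% names(object@meta))
    cat("  sources:", paste(sprintf("%s=%d", names(table(object@meta$source)),
                                    table(object@meta$source)), collapse = ", "), "\n")
})

#' TrimResult: outcome of gap-threshold optimization for one locus
#'
#' @slot locusId locus identifier.
#' @slot chosenGt selected gap threshold, or \code{NA} when the locus is
#'   discarded.
#' @slot trimmed the \linkS4class{GappedAlignment} trimmed at the selected
#'   (or best feasible) threshold.
#' @slot dataLoss fraction of non-gap residues removed at the selected
#'   threshold.
#' @slot curve data.frame with one row per swept threshold: \code{gt},
#'   \code{p_pic}, \code{data_loss}, \code{n_col}.
#' @slot verdict \code{"keep"} or \code{"discard"}.
#' @export
setClass("TrimResult",
  representation(locusId = "character", chosenGt = "numeric",
                 trimmed = "GappedAlignment", dataLoss = "numeric",
                 curve = "data.frame", verdict = "character"))

setValidity("TrimResult", function(object) {
  if (!object@verdict %in% c("keep", "discard"))
    return("verdict must be keep or discard")
  if (object@verdict == "keep" && is.na(object@chosenGt))
    return("kept locus must have a chosen threshold")
  if (!all(c("gt", "p_pic", "data_loss", "n_col") %in% names(object@curve)))
    return("curve must have gt, p_pic, data_loss, n_col")
  TRUE
})

setMethod("show", "TrimResult", function(object) {
  cat(sprintf("TrimResult '%s': verdict=%s, gt=%s, data loss=%.3f, %d columns kept\n",
              object@locusId, object@verdict,
              ifelse(is.na(object@chosenGt), "none", format(object@chosenGt)),
              object@dataLoss, alnWidth(object@trimmed)))
})

#' @describeIn TrimResult selected gap threshold (NA when discarded)
#' @param x,object a \code{TrimResult}.
#' @export
setGeneric("chosenGt", function(x) standardGeneric("chosenGt"))

#' @rdname TrimResult-class
#' @export
setMethod("chosenGt", "TrimResult", function(x) x@chosenGt)

#' @describeIn TrimResult keep/discard verdict
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname TrimResult-class
#' @export
setMethod("verdict", "TrimResult", function(x) x@verdict)

#' @describeIn TrimResult trimmed alignment at the selected threshold
#' @export
setGeneric("trimmedAlignment", function(x) standardGeneric("trimmedAlignment"))

#' @rdname TrimResult-class
#' @export
setMethod("trimmedAlignment", "TrimResult", function(x) x@trimmed)

#' @describeIn TrimResult per-threshold sweep curve
#' @export
setGeneric("trimCurve", function(x) standardGeneric("trimCurve"))

#' @rdname TrimResult-class
#' @export
setMethod("trimCurve", "TrimResult", function(x) x@curve)

#' SimDataset: a synthetic Hyb-Seq dataset with planted ground truth
#'
#' @slot alignments named list of \linkS4class{GappedAlignment}, one per locus.
#' @slot geneTrees named list of ape \code{phylo} gene trees.
#' @slot speciesTree ape \code{phylo} species tree.
#' @slot recovery the \linkS4class{RecoveryMatrix} implied by the simulated
#'   degradation process.
#' @slot truth list of planted features: rogue taxa, clock-violating loci,
#'   low-coverage accessions, per-accession expected recovery fractions,
#'   per-column informativeness.
#' @slot spec the generator settings used (echo of \code{\link{simSpec}}).
#' @export
setClass("SimDataset",
  representation(alignments = "list", geneTrees = "list",
                 speciesTree = "ANY", recovery = "RecoveryMatrix",
                 truth = "list", spec = "list"))

setValidity("SimDataset", function(object) {
  if (length(object@alignments) &&
      !identical(names(object@alignments), names(object@geneTrees)))
    return("alignments and gene trees must share locus names")
  tr <- object@truth
  accs <- rownames(recovered(object@recovery))
  loci <- names(object@geneTrees)
  if (length(tr$rogue_taxa) && !all(tr$rogue_taxa %in% accs))
    return("truth rogue taxa must be dataset accessions")
  if (length(tr$clock_violating_loci) && !all(tr$clock_violating_loci %in% loci))
    return("truth clock violators must be dataset loci")
  TRUE
})

setMethod("show", "SimDataset", function(object) {
  cat(sprintf("SimDataset: %d taxa, %d loci (seed %s)\n",
              nrow(recovered(object@recovery)), length(object@geneTrees),
              format(object@spec$seed)))
  cat(sprintf("  planted: %d rogue taxa, %d clock-violating loci, %d low-coverage accessions\n",
              length(object@truth$rogue_taxa),
              length(object@truth$clock_violating_loci),
              length(object@truth$low_coverage_accessions)))
})
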