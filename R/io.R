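#' Read a per-locus alignment from FASTA
#'
#' Reads a gapped DNA alignment. Sequences are upper-cased on read and the
#' input order of taxa is preserved. The full record description line is used
#' as the accession label.
#'
#' @param path path to a FASTA file.
#' @param locusId locus identifier; defaults to the file name without
#'   extension.
#' @return A \linkS4class{GappedAlignment}. An empty file yields an alignment
#'   with zero taxa and zero columns.
#' @details Ragged rows raise a malformed-alignment error naming the first
#'   offending taxon; duplicated labels raise a duplicate-label error.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACG-", ">b", "AC?T"), fa)
#' readAlignment(fa)
#' @export
readAlignment <- function(path, locusId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (file.size(path) == 0L)
    return(GappedAlignment(locusId, character(0)))
  ss <- Biostrings::readBStringSet(path)
  labs <- names(ss)
  if (anyDuplicated(labs))
    stop(sprintf("duplicate taxon label '%s' in %s",
                 labs[duplicated(labs)][1L], path))
  w <- Biostrings::width(ss)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1L])[1L]
    stop(sprintf("malformed alignment '%s': taxon '%s' has %d columns, expected %d",
                 locusId, labs[bad], w[bad], w[1L]))
  }
  seqs <- stats::setNames(as.character(ss), labs)
  GappedAlignment(locusId, seqs)
}

#' Write a GappedAlignment to FASTA
#'
#' @param aln a \linkS4class{GappedAlignment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  m <- as.matrix(aln)
  seqs <- apply(m, 1L, paste, collapse = "")
  if (nTaxa(aln) == 0L) {
    file.create(path)
  } else {
    ss <- Biostrings::BStringSet(seqs)
    names(ss) <- taxa(aln)
    Biostrings::writeXStringSet(ss, path, width = 80L)
  }
  invisible(path)
}

#' Read a newick tree with integer support labels
#'
#' Wraps \code{ape::read.tree} with stricter error reporting. Internal node
#' labels in the dialect written by common maximum-likelihood tools are
#' interpreted as integer support values on a 0-100 scale; labels that are
#' absent or non-numeric are treated as unknown support (\code{NA}), which is
#' distinct from support 0. Branch lengths default to 0 when the newick
#' string carries none.
#'
#' @param path path to a newick file (first tree is read).
#' @return An ape \code{phylo} object. Support values, when present, are in
#'   \code{$node.label} (character; see \code{\link{edgeSupport}}).
#' @export
readTree <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  .checkNewick(txt, path)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop(sprintf("could not parse newick in %s", path))
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

## Balanced-parenthesis pre-check so parse errors report a character offset.
.checkNewick <- function(txt, path = "<text>") {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error in %s: unbalanced ')' at character %d",
                     path, i))
    }
  }
  if (depth != 0L)
    stop(sprintf("newick parse error in %s: %d unclosed '(' (string ends at character %d)",
                 path, depth, length(chars)))
  if (!grepl(";", txt, fixed = TRUE))
    stop(sprintf("newick parse error in %s: missing terminating ';'", path))
  invisible(TRUE)
}

#' Write a tree to newick
#'
#' @param tree an ape \code{phylo} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Per-edge support values of a tree
#'
#' Maps internal node labels onto the edges leading to those nodes. Edges to
#' tips, and internal edges without a numeric label, have \code{NA} support
#' (unknown, distinct from 0).
#'
#' @param tree an ape \code{phylo} object.
#' @return Numeric vector with one entry per row of \code{tree$edge}.
#' @export
edgeSupport <- function(tree) {
  ntip <- length(tree$tip.label)
  sup <- rep(NA_real_, nrow(tree$edge))
  if (is.null(tree$node.label)) return(sup)
  lab <- suppressWarnings(as.numeric(tree$node.label))
  child <- tree$edge[, 2L]
  internal <- child > ntip
  sup[internal] <- lab[child[internal] - ntip]
  sup
}

#' Read a recovery table
#'
#' Reads a per-accession, per-locus recovery table from TSV, in either long
#' form (columns \code{accession}, \code{locus}, \code{recovered_length},
#' optionally \code{target_length}) or wide form (first column
#' \code{accession}, remaining columns one locus each). Absent
#' (accession, locus) pairs become recovered length 0.
#'
#' @param path path to the TSV file.
#' @param format \code{"long"} or \code{"wide"}.
#' @param targets per-locus target lengths: a named numeric vector, or the
#'   path of a two-column TSV (\code{locus}, \code{target_length}). Required
#'   for wide form and for long form without a \code{target_length} column.
#' @param meta optional per-accession metadata: a data.frame or TSV path with
#'   columns \code{accession}, and optionally \code{collection_year},
#'   \code{source}, \code{reads_total}, \code{reads_on_target}.
#' @return A \linkS4class{RecoveryMatrix}.
#' @export
readRecoveryTable <- function(path, format = c("long", "wide"),
                              targets = NULL, meta = NULL) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(targets) && length(targets) == 1L) {
    tt <- utils::read.delim(targets, stringsAsFactors = FALSE)
    targets <- stats::setNames(tt$target_length, tt$locus)
  }
  if (format == "long") {
    need <- c("accession", "locus", "recovered_length")
    if (!all(need %in% names(tab)))
      stop("long-form table needs columns accession, locus, recovered_length")
    if (any(tab$recovered_length < 0))
      stop(sprintf("negative recovered_length for accession '%s', locus '%s'",
                   tab$accession[tab$recovered_length < 0][1L],
                   tab$locus[tab$recovered_length < 0][1L]))
    if ("target_length" %in% names(tab)) {
      tl <- tapply(tab$target_length, tab$locus, function(v) v[1L])
      targets2 <- stats::setNames(as.numeric(tl), names(tl))
      if (is.null(targets)) targets <- targets2
    }
    if (is.null(targets))
      stop("target lengths required: supply 'targets' or a target_length column")
    accs <- unique(tab$accession)
    loci <- names(targets)
    unknown <- setdiff(unique(tab$locus), loci)
    if (length(unknown))
      stop(sprintf("unknown locus in cells: %s", unknown[1L]))
    rec <- matrix(0, length(accs), length(loci),
                  dimnames = list(accs, loci))
    rec[cbind(match(tab$accession, accs), match(tab$locus, loci))] <-
      as.numeric(tab$recovered_length)
  } else {
    accs <- tab[[1L]]
    loci <- names(tab)[-1L]
    rec <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(rec) <- "double"
    rownames(rec) <- accs
    if (any(rec < 0))
      stop(sprintf("negative recovered_length for accession '%s'",
                   accs[which(rowSums(rec < 0) > 0)[1L]]))
    if (is.null(targets))
      stop("wide-form tables require 'targets'")
    if (!all(loci %in% names(targets)))
      stop(sprintf("unknown locus in cells: %s",
                   setdiff(loci, names(targets))[1L]))
    targets <- targets[loci]
  }
  metaDf <- NULL; readsDf <- NULL
  if (!is.null(meta)) {
    if (is.character(meta) && length(meta) == 1L)
      meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
    meta <- meta[match(rownames(rec), meta$accession), , drop = FALSE]
    rownames(meta) <- NULL
    keep <- intersect(c("accession", "collection_year", "source"), names(meta))
    metaDf <- meta[, keep, drop = FALSE]
    if (all(c("reads_total", "reads_on_target") %in% names(meta)))
      readsDf <- meta[, c("accession", "reads_total", "reads_on_target")]
  }
  RecoveryMatrix(rec, targets, meta = metaDf, reads = readsDf)
}

#' Write a RecoveryMatrix as a long-form TSV
#'
#' Writes one row per (accession, locus) pair with a \code{target_length}
#' column, so the file round-trips through
#' \code{\link{readRecoveryTable}}. Zero cells are written explicitly.
#'
#' @param m a \linkS4class{RecoveryMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRecoveryTable <- function(m, path) {
  rec <- recovered(m)
  long <- data.frame(
    accession = rep(rownames(rec), times = ncol(rec)),
    locus = rep(colnames(rec), each = nrow(rec)),
    recovered_length = as.vector(rec),
    target_length = rep(targetLength(m), each = nrow(rec)),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
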