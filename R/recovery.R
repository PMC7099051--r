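#' Capture success of one (accession, locus) cell
#'
#' The proportion of the target reference sequence recovered, capped at 1.
#' Over-recovery (assembled sequence longer than the reference) triggers a
#' warning and is capped.
#'
#' @param recoveredLength recovered sequence length (bp), >= 0.
#' @param targetLen target reference length (bp), > 0.
#' @return Fraction in [0, 1].
#' @examples
#' captureSuccess(28, 100)  # 0.28
#' @export
captureSuccess <- function(recoveredLength, targetLen) {
  if (any(targetLen <= 0)) stop("target_length must be > 0")
  if (any(recoveredLength < 0)) stop("recovered_length must be >= 0")
  over <- recoveredLength > targetLen
  if (any(over))
    warning(sprintf("%d cell(s) recovered more than the target length; capped at 1",
                    sum(over)))
  pmin(recoveredLength / targetLen, 1)
}

## Shared scorer: rec is an entity x item matrix of recovered lengths, frac
## the matching matrix of capped capture-success fractions.
.scoreEntities <- function(rec, frac) {
  m <- ncol(rec)
  t(vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]; f <- frac[i, ]
    nz <- r > 0
    k <- sum(nz)
    repr <- if (m > 0L) k / m else 0
    comp <- if (k > 0L) mean(f[nz]) else 0
    even <- if (k <= 1L) {
      if (k == 1L && m == 1L) 1 else 0
    } else {
      ## evenness of recovery relative to the targets: full recovery of
      ## heterogeneous-length loci is perfectly even
      p <- f[nz] / sum(f[nz])
      -sum(p * log(p)) / log(m)
    }
    c(representativeness = repr, completeness = comp, evenness = even,
      score = repr * comp * even)
  }, numeric(4)))
}

#' Composite coverage scores
#'
#' For each accession (or each locus, on the transposed view) computes
#' \itemize{
#'   \item representativeness r: fraction of loci with any sequence
#'     recovered;
#'   \item completeness c: mean capture success over the recovered loci
#'     only (absence is already penalized by r);
#'   \item evenness e: Shannon-based (Pielou) evenness of the recovered
#'     lengths, \eqn{H'/\log m} with \eqn{H' = -\sum p_i \log p_i} over the
#'     nonzero recovered fractions \eqn{p_i}; e is 0 when at most one locus
#'     is recovered, and defined as 1 in the degenerate one-locus matrix
#'     when that locus is recovered;
#'   \item score: the product r c e.
#' }
#'
#' @param m a \linkS4class{RecoveryMatrix}.
#' @param axis \code{"accessions"} (default) scores each accession across
#'   loci; \code{"loci"} scores each locus across accessions (the transposed
#'   view of the same definition).
#' @param completenessDenominator \code{"recovered"} (default) averages
#'   capture success over recovered loci only; \code{"all"} uses total
#'   recovered length over total target length, double-counting absence.
#' @return data.frame with columns \code{entity_id},
#'   \code{representativeness}, \code{completeness}, \code{evenness},
#'   \code{score}.
#' @examples
#' rec <- matrix(c(50, 50, 0, 0), 1, 4,
#'               dimnames = list("a1", paste0("l", 1:4)))
#' coverageScores(RecoveryMatrix(rec, setNames(rep(100, 4), paste0("l", 1:4))))
#' @export
coverageScores <- function(m, axis = c("accessions", "loci"),
                           completenessDenominator = c("recovered", "all")) {
  axis <- match.arg(axis)
  completenessDenominator <- match.arg(completenessDenominator)
  rec <- recovered(m)
  if (length(rec) == 0L)
    return(data.frame(entity_id = character(0), representativeness = numeric(0),
                      completeness = numeric(0), evenness = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  frac <- suppressWarnings(
    sweep(rec, 2L, targetLength(m), function(r, t) pmin(r / t, 1)))
  if (axis == "loci") {
    rec <- t(rec); frac <- t(frac)
  }
  sc <- .scoreEntities(rec, frac)
  if (completenessDenominator == "all") {
    ## total capped recovered length over total target length, per entity
    comp <- if (axis == "accessions") {
      capped <- sweep(rec, 2L, targetLength(m), pmin)
      rowSums(capped) / sum(targetLength(m))
    } else {
      tl <- targetLength(m)[rownames(rec)]
      capped <- sweep(rec, 1L, tl, pmin)
      rowSums(capped) / (tl * ncol(rec))
    }
    sc[, "completeness"] <- comp
    sc[, "score"] <- sc[, "representativeness"] * comp * sc[, "evenness"]
  }
  data.frame(entity_id = rownames(rec), sc, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter entities by coverage score
#'
#' @param scores data.frame from \code{\link{coverageScores}}.
#' @param cutoff inclusive minimum score (default 0.5).
#' @return Character vector of retained identifiers, original order
#'   preserved.
#' @export
filterByScore <- function(scores, cutoff = 0.5) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  scores$entity_id[scores$score >= cutoff]
}

#' Specimen-age and tissue-source effects on capture success
#'
#' Fits an ordinary least-squares regression of per-accession mean capture
#' success on collection year for herbarium accessions, and a Welch
#' two-sample t contrast of capture success between the DNA-bank/silica
#' group and the herbarium group (positive t means the non-herbarium group
#' is higher).
#'
#' @param m a \linkS4class{RecoveryMatrix} whose metadata carry
#'   \code{collection_year} and \code{source}.
#' @return List of class \code{effectReport} with elements \code{slope}
#'   (success fraction per year), \code{f_stat}, \code{df} (residual),
#'   \code{r_squared}, \code{p_value}, and, when both source groups are
#'   non-empty, \code{t_stat}, \code{welch_df}, \code{t_p_value}. Per-
#'   accession mean capture success is the mean over all loci of the capped
#'   recovered/target ratio (zeros included).
#' @export
ageEffectReport <- function(m) {
  meta <- sampleMeta(m)
  if (!all(c("collection_year", "source") %in% names(meta)))
    stop("metadata must provide collection_year and source")
  rec <- recovered(m)
  frac <- sweep(rec, 2L, targetLength(m), function(r, t) pmin(r / t, 1))
  y <- rowMeans(frac)
  herb <- meta$source == "herbarium" & !is.na(meta$collection_year)
  if (sum(herb) < 3L)
    stop("need at least 3 herbarium accessions with a collection year")
  fit <- stats::lm(y[herb] ~ meta$collection_year[herb])
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  out <- if (is.null(fstat)) {
    ## degenerate regressor (e.g. all years equal): no slope to test
    list(slope = NA_real_, f_stat = NA_real_,
         df = as.integer(sum(herb) - 2L), r_squared = NA_real_,
         p_value = NA_real_)
  } else {
    list(slope = unname(stats::coef(fit)[2L]),
         f_stat = fstat[1L],
         df = as.integer(fstat[3L]),
         r_squared = sm$r.squared,
         p_value = stats::pf(fstat[1L], fstat[2L], fstat[3L],
                             lower.tail = FALSE))
  }
  other <- meta$source %in% c("dna_bank", "silica")
  if (any(other) && any(meta$source == "herbarium")) {
    tt <- stats::t.test(y[other], y[meta$source == "herbarium"])
    out$t_stat <- unname(tt$statistic)
    out$welch_df <- unname(tt$parameter)
    out$t_p_value <- tt$p.value
  } else {
    warning("one source group is empty; t contrast omitted")
  }
  class(out) <- "effectReport"
  out
}

#' @export
print.effectReport <- function(x, ...) {
  cat(sprintf("Age effect (herbarium OLS): slope = %.3g per year, F = %.3g, DF = %d, R^2 = %.3f, p = %.3g\n",
              x$slope, x$f_stat, x$df, x$r_squared, x$p_value))
  if (!is.null(x$t_stat))
    cat(sprintf("Source contrast (Welch): t = %.3g, DF = %.1f, p = %.3g\n",
                x$t_stat, x$welch_df, x$t_p_value))
  invisible(x)
}
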