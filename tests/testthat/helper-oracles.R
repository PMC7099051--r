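# Independent brute-force oracles, deliberately written in a different style
# from the package internals so the two routes can disagree.

# Parsimony informativeness by explicit state-pair enumeration.
oraclePic <- function(column) {
  counts <- integer(0)
  for (s in c("A", "C", "G", "T"))
    counts[s] <- sum(toupper(column) == s)
  states2 <- names(counts)[counts >= 2]
  length(states2) >= 2
}

# Per-column sweep of an alignment matrix.
oracleAlnStats <- function(m) {
  L <- ncol(m)
  pic <- logical(L)
  for (j in seq_len(L)) pic[j] <- oraclePic(m[, j])
  list(n_pic = sum(pic), p_pic = if (L > 0) sum(pic) / L else 0)
}

# trimAl-style column keep rule, evaluated column by column.
oracleTrimCols <- function(m, gt) {
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m)))
    keep[j] <- sum(m[, j] != "-") / nrow(m) >= gt - 1e-9
  keep
}

# Exhaustive re-evaluation of the threshold sweep.
oracleOptimize <- function(m, thresholds, maxLoss) {
  total <- sum(m != "-")
  best <- NULL
  for (gt in thresholds) {
    keep <- oracleTrimCols(m, gt)
    tm <- m[, keep, drop = FALSE]
    loss <- 1 - sum(tm != "-") / total
    ppic <- oracleAlnStats(tm)$p_pic
    if (loss <= maxLoss + 1e-9) {
      if (is.null(best) || ppic > best$p_pic + 1e-12)
        best <- list(gt = gt, p_pic = ppic, loss = loss)
    }
  }
  if (is.null(best) || best$p_pic == 0)
    list(chosen = NA_real_, verdict = "discard")
  else
    list(chosen = best$gt, verdict = "keep")
}

# Leaf-to-leaf path length by walking parent chains in the edge matrix.
oracleDiameter <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2]] <- tree$edge[k, 1]
    elen[tree$edge[k, 2]] <- tree$edge.length[k]
  }
  pathToRoot <- function(i) {
    nodes <- i; d <- c(0)
    while (parent[i] != 0) {
      d <- c(d, d[length(d)] + elen[i])
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    stats::setNames(d, nodes)
  }
  best <- 0
  for (i in seq_len(ntip - 1)) {
    pi <- pathToRoot(i)
    for (j in seq.int(i + 1, ntip)) {
      pj <- pathToRoot(j)
      common <- intersect(names(pi), names(pj))
      mrcaDepth <- min(pi[common])  # distance from i up to shallowest shared node
      dij <- min(pi[common]) + min(pj[common])
      best <- max(best, dij)
    }
  }
  best
}

# Random gapped alignment with controllable informativeness.
randomAlignment <- function(ntaxa, ncols, gapProb = 0.2, id = "rand") {
  chars <- c("A", "C", "G", "T", "-", "N", "?")
  probs <- c(rep((1 - gapProb - 0.06) / 4, 4), gapProb, 0.03, 0.03)
  m <- matrix(sample(chars, ntaxa * ncols, replace = TRUE, prob = probs),
              nrow = ntaxa)
  rownames(m) <- paste0("t", seq_len(ntaxa))
  GappedAlignment(id, m)
}

randomTree <- function(ntip) {
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}
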