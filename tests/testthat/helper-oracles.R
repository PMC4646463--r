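# Independent oracles used by the tests. These deliberately re-derive the
# quantities with naive, direct code (tables, loops, enumeration) so they do
# not share a code path with the package implementation they check.

# Exact per-time posterior of `target` by exhaustive enumeration of all
# hidden trajectories, conditioning on the evidence observed up to each time
# point (the quantity a forward likelihood-weighting sampler estimates; at
# t = T it equals the conditional on the complete evidence). The joint
# probability is computed by direct CPT lookups, independently of
# jointLogProb().
enumPosterior <- function(model, evidence, target) {
  struct <- modelStructure(model)
  mols <- molecules(struct)
  obs <- stateMatrix(evidence)[mols, , drop = FALSE]
  stim <- stimAssignment(evidence)
  ctxLev <- struct@contextLevels
  ctxIdx <- match(seriesContext(evidence), ctxLev)
  TT <- ncol(obs)
  tr <- transitionCPTs(model); ini <- initialCPTs(model)

  nodeProb <- function(nm, tab, prevStates, myState) {
    # direct mixed-radix lookup, first parent fastest
    idx <- 1L; mult <- 1L
    for (p in tab$parents) {
      v <- if (p == "context") ctxIdx
      else if (p %in% names(stim)) stim[[p]] + 1L
      else prevStates[[p]] + 2L
      k <- match(p, tab$parents)
      idx <- idx + (v - 1L) * mult
      mult <- mult * tab$cards[k]
    }
    tab$prob[idx, myState + 2L]
  }

  jointP <- function(st) {  # st: molecules x t matrix of states
    p <- 1
    for (nm in mols)
      p <- p * nodeProb(nm, ini[[nm]], NULL, st[nm, 1])
    if (ncol(st) >= 2) for (t in 2:ncol(st)) {
      prev <- as.list(st[, t - 1]); names(prev) <- mols
      for (nm in mols)
        p <- p * nodeProb(nm, tr[[nm]], prev, st[nm, t])
    }
    p
  }

  out <- matrix(0, nrow = TT, ncol = 3)
  for (tt in seq_len(TT)) {
    sub <- obs[, seq_len(tt), drop = FALSE]
    cells <- which(is.na(sub), arr.ind = TRUE)
    grid <- expand.grid(rep(list(c(-1L, 0L, 1L)), nrow(cells)))
    for (g in seq_len(nrow(grid))) {
      st <- sub
      st[cells] <- as.integer(unlist(grid[g, ]))
      out[tt, st[target, tt] + 2] <- out[tt, st[target, tt] + 2] + jointP(st)
    }
    out[tt, ] <- out[tt, ] / sum(out[tt, ])
  }
  out
}

# Naive MIT family score: plug-in MI via table(), penalty via qchisq, no
# shared code with the package.
naiveScore <- function(childVec, prevMat, parents, alpha) {
  if (length(parents) == 0) return(0)
  parents <- sort(parents)
  cfg <- apply(prevMat[, parents, drop = FALSE], 1, paste, collapse = "|")
  tab <- table(factor(childVec), factor(cfg))
  N <- sum(tab)
  p <- tab / N
  mi <- 0
  pr <- rowSums(p); pc <- colSums(p)
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
  pen <- 0
  for (j in seq_along(parents))
    pen <- pen + qchisq(1 - alpha, df = (3 - 1) * (3 - 1) * 3^(j - 1))
  2 * N * mi - pen
}

# Brute-force optimal parent set by scanning every subset (bitmask), same
# tie-break convention (smaller set first, then lexicographic).
naiveBestParents <- function(childVec, prevMat, candidates, alpha,
                             maxParents) {
  candidates <- sort(candidates)
  best <- character(0); bestScore <- 0
  n <- length(candidates)
  ord <- order(vapply(0:(2^n - 1), function(m)
    sum(bitwAnd(m, 2^(0:(n - 1))) > 0), numeric(1)))
  for (m in (0:(2^n - 1))[ord]) {
    ss <- candidates[bitwAnd(m, 2^(0:(n - 1))) > 0]
    if (length(ss) == 0 || length(ss) > maxParents) next
    sc <- naiveScore(childVec, prevMat, ss, alpha)
    if (sc > bestScore + 1e-12) { best <- ss; bestScore <- sc }
  }
  best
}

# Slice-pair matrices of a series set, for feeding the naive oracles.
slicePairs <- function(seriesSet) {
  prev <- NULL; cur <- NULL
  for (s in seriesSet) {
    st <- stateMatrix(s)
    prev <- rbind(prev, t(st[, -ncol(st), drop = FALSE]))
    cur <- rbind(cur, t(st[, -1, drop = FALSE]))
  }
  list(prev = prev, cur = cur)
}

# Random small trinary dataset as a series set (for oracle-equivalence
# sweeps).
randomSeriesSet <- function(nNodes, nSeries, T, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(nNodes)]
  lapply(seq_len(nSeries), function(i) {
    m <- matrix(sample(c(-1L, 0L, 1L), nNodes * T, replace = TRUE),
                nrow = nNodes, dimnames = list(nodes, NULL))
    trinarySeries(m, "cyt_protein", "control")
  })
}
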