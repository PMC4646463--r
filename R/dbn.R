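#' @include AllClasses.R
NULL

# Conditioning layout of a node's CPT: molecule parents (sorted) first, then
# stimulation parents (sorted), then the context node. The first factor
# varies fastest in the row index (.cfgIndex).
.nodeParentInfo <- function(structure, node, initial = FALSE) {
  mol <- if (initial) character(0) else sort(structure@parentSets[[node]])
  stim <- sort(names(structure@stimTargets)[vapply(structure@stimTargets,
                function(t) node %in% t, logical(1))])
  ctx <- structure@useContext
  parents <- c(mol, stim, if (ctx) "context")
  cards <- c(rep(3L, length(mol)), rep(2L, length(stim)), if (ctx) 3L)
  list(mol = mol, stim = stim, ctx = ctx, parents = parents,
       cards = as.integer(cards))
}

.checkSeriesSet <- function(seriesSet, structure) {
  for (s in seriesSet) {
    if (!identical(sort(rownames(s@states)), sort(structure@molecules)))
      stop("inconsistent node sets across series", call. = FALSE)
    if (anyNA(s@states))
      stop("series contain unobserved entries; use predictPosterior()",
           call. = FALSE)
  }
  invisible(TRUE)
}

# Per-series fixed-parent values, as 1-based indices.
.fixedIdx <- function(series, structure) {
  stim <- vapply(names(structure@stimTargets), function(sn) {
    v <- series@stim[[sn]]
    if (is.null(v)) stop(sprintf("series lacks stimulation node %s", sn),
                         call. = FALSE)
    as.integer(v) + 1L
  }, integer(1))
  ctx <- match(series@context, structure@contextLevels)
  list(stim = stim, ctx = ctx)
}

#' Accumulate transition counts under a given structure
#'
#' Scans every consecutive slice pair (t-1, t) of every series and counts,
#' for each molecule, how often each child state follows each configuration
#' of its parents (molecule parents at t-1 plus the series' fixed
#' stimulation/context values). Time-0 states are accumulated separately for
#' the initial-slice distributions.
#'
#' @param seriesSet list of fully observed \linkS4class{TrinarySeries}
#'   sharing the structure's molecule set.
#' @param structure a \linkS4class{DBNStructure}.
#' @return a \linkS4class{TransitionCounts}.
#' @examples
#' m <- uniformModel(c("A", "B"))
#' s <- sampleTimeSeries(m, "control", "cyt_protein", T = 14, seed = 1)
#' collectTransitions(list(s), modelStructure(m))
#' @export
collectTransitions <- function(seriesSet, structure) {
  if (inherits(seriesSet, "TrinarySeries")) seriesSet <- list(seriesSet)
  .checkSeriesSet(seriesSet, structure)
  mols <- structure@molecules
  info <- lapply(stats::setNames(mols, mols), .nodeParentInfo,
                 structure = structure)
  infoInit <- lapply(stats::setNames(mols, mols), .nodeParentInfo,
                     structure = structure, initial = TRUE)
  counts <- lapply(info, function(z)
    list(parents = z$parents, cards = z$cards,
         counts = matrix(0L, nrow = prod(c(z$cards, 1L)), ncol = 3L)))
  init <- lapply(infoInit, function(z)
    list(parents = z$parents, cards = z$cards,
         counts = matrix(0L, nrow = prod(c(z$cards, 1L)), ncol = 3L)))
  nTrans <- 0L
  for (s in seriesSet) {
    st <- .stateToIdx(s@states[mols, , drop = FALSE])
    fx <- .fixedIdx(s, structure)
    T <- ncol(st)
    for (nm in mols) {
      z <- info[[nm]]
      fixed <- c(fx$stim[z$stim], if (z$ctx) fx$ctx)
      # initial slice
      zi <- infoInit[[nm]]
      ci <- .cfgIndex(matrix(fixed, nrow = 1L), zi$cards)
      init[[nm]]$counts[ci, st[nm, 1L]] <-
        init[[nm]]$counts[ci, st[nm, 1L]] + 1L
      if (T < 2L) next
      prev <- t(st[z$mol, -T, drop = FALSE])        # (T-1) x |mol parents|
      vals <- cbind(prev, matrix(rep(fixed, each = T - 1L), nrow = T - 1L))
      cfg <- .cfgIndex(vals, z$cards)
      child <- st[nm, -1L]
      nb <- nrow(counts[[nm]]$counts)
      add <- tabulate((child - 1L) * nb + cfg, nbins = nb * 3L)
      counts[[nm]]$counts <- counts[[nm]]$counts + matrix(add, nrow = nb)
    }
    nTrans <- nTrans + max(ncol(st) - 1L, 0L)
  }
  new("TransitionCounts", nodeCounts = counts, initialCounts = init,
      nTransitions = nTrans, nSeries = length(seriesSet))
}

#' Estimate conditional probability tables from counts
#'
#' Maximum a posteriori estimate under a symmetric Dirichlet prior: a
#' pseudo-count (default 1, as in the original analysis) is added to every
#' cell, so unseen parent configurations fall back to the uniform
#' distribution and all probabilities are strictly positive.
#'
#' @param counts a \linkS4class{TransitionCounts}.
#' @param structure the \linkS4class{DBNStructure} the counts were collected
#'   under.
#' @param pseudo positive pseudo-count added to each cell.
#' @return a \linkS4class{DBNModel}.
#' @examples
#' m <- uniformModel(c("A", "B"))
#' s <- sampleTimeSeries(m, "control", "cyt_protein", T = 14, seed = 1)
#' fit <- learnParameters(collectTransitions(list(s), modelStructure(m)),
#'                        modelStructure(m))
#' @export
learnParameters <- function(counts, structure, pseudo = 1) {
  stopifnot(pseudo > 0)
  smooth <- function(tab) {
    p <- tab$counts + pseudo
    list(parents = tab$parents, cards = tab$cards, prob = p / rowSums(p))
  }
  new("DBNModel", structure = structure,
      transition = lapply(counts@nodeCounts, smooth),
      initial = lapply(counts@initialCounts, smooth))
}

#' Log joint probability of a fully observed series
#'
#' Evaluates the first-order-Markov factorization: the log initial
#' probability of the time-0 slice (nodes independent given the fixed
#' parents) plus the log transition probability of every node at every
#' subsequent slice given its parents at the previous slice.
#'
#' @param model a \linkS4class{DBNModel}.
#' @param series a fully observed \linkS4class{TrinarySeries}.
#' @return a scalar log-probability (<= 0).
#' @export
jointLogProb <- function(model, series) {
  structure <- model@structure
  if (anyNA(series@states))
    stop("series contains unobserved entries; use predictPosterior()",
         call. = FALSE)
  .checkSeriesSet(list(series), structure)
  mols <- structure@molecules
  st <- .stateToIdx(series@states[mols, , drop = FALSE])
  fx <- .fixedIdx(series, structure)
  T <- ncol(st)
  lp <- 0
  for (nm in mols) {
    zi <- .nodeParentInfo(structure, nm, initial = TRUE)
    fixedI <- c(fx$stim[zi$stim], if (zi$ctx) fx$ctx)
    ci <- .cfgIndex(matrix(fixedI, nrow = 1L), zi$cards)
    lp <- lp + log(model@initial[[nm]]$prob[ci, st[nm, 1L]])
    if (T < 2L) next
    z <- .nodeParentInfo(structure, nm)
    fixed <- c(fx$stim[z$stim], if (z$ctx) fx$ctx)
    prev <- t(st[z$mol, -T, drop = FALSE])
    cfg <- .cfgIndex(cbind(prev,
                           matrix(rep(fixed, each = T - 1L), nrow = T - 1L)),
                     z$cards)
    lp <- lp + sum(log(model@transition[[nm]]$prob[cbind(cfg, st[nm, -1L])]))
  }
  lp
}

# Vectorised ancestral sampling of many series at once.
# stimIdx: nSeries x nStim matrix (1-based), ctxIdx: nSeries vector.
# Returns integer array [nSeries, nMolecules, T] of state indices 1..3.
.forwardSampleArray <- function(model, stimIdx, ctxIdx, T) {
  structure <- model@structure
  colnames(stimIdx) <- names(structure@stimTargets)
  mols <- structure@molecules
  nS <- length(ctxIdx)
  out <- array(1L, dim = c(nS, length(mols), T),
               dimnames = list(NULL, mols, NULL))
  for (j in seq_along(mols)) {
    nm <- mols[j]
    zi <- .nodeParentInfo(structure, nm, initial = TRUE)
    fixed <- cbind(stimIdx[, zi$stim, drop = FALSE],
                   if (zi$ctx) ctxIdx)
    ci <- .cfgIndex(fixed, zi$cards)
    out[, j, 1L] <- .sampleRows(model@initial[[nm]]$prob[ci, , drop = FALSE])
  }
  if (T < 2L) return(out)
  info <- lapply(mols, .nodeParentInfo, structure = structure)
  fixedCfg <- lapply(info, function(z)
    cbind(stimIdx[, z$stim, drop = FALSE], if (z$ctx) ctxIdx))
  for (t in 2:T) {
    prevSlice <- out[, , t - 1L, drop = FALSE]
    dim(prevSlice) <- dim(out)[1:2]
    colnames(prevSlice) <- mols
    for (j in seq_along(mols)) {
      z <- info[[j]]
      vals <- cbind(prevSlice[, z$mol, drop = FALSE], fixedCfg[[j]])
      cfg <- .cfgIndex(vals, z$cards)
      out[, j, t] <- .sampleRows(
        model@transition[[mols[j]]]$prob[cfg, , drop = FALSE])
    }
  }
  out
}

#' Forward-sample one trinary time series from a DBN
#'
#' Ancestral sampling slice by slice: the time-0 slice is drawn from the
#' initial distributions, each later slice from the transition tables given
#' the previous slice and the fixed stimulation/context values.
#'
#' @param model a \linkS4class{DBNModel}.
#' @param condition condition label (parsed by \code{\link{conditionToStim}})
#'   or a named 0/1 stimulation vector.
#' @param context context level of the series.
#' @param T number of time points (>= 1).
#' @param seed optional integer seed; identical seeds give identical series.
#' @return a \linkS4class{TrinarySeries}.
#' @examples
#' m <- uniformModel(c("A", "B"))
#' sampleTimeSeries(m, "EGF", "cyt_protein", T = 5, seed = 7)
#' @export
sampleTimeSeries <- function(model, condition = "control",
                             context = "cyt_protein", T = 14L, seed = NULL) {
  res <- forwardSampleSet(model,
    assignments = list(list(condition = condition, context = context)),
    T = T, seed = seed)
  res[[1]]
}

#' Forward-sample a set of series with given design assignments
#'
#' @param model a \linkS4class{DBNModel}.
#' @param assignments list of \code{list(condition=, context=)} entries, one
#'   per series to sample (condition may also be a named 0/1 stim vector).
#' @param T number of time points per series (>= 1).
#' @param seed optional integer seed.
#' @return list of \linkS4class{TrinarySeries}.
#' @export
forwardSampleSet <- function(model, assignments, T = 14L, seed = NULL) {
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  structure <- model@structure
  stimNodes <- names(structure@stimTargets)
  conds <- lapply(assignments, function(a) {
    stim <- if (is.character(a$condition)) conditionToStim(a$condition)
            else a$condition
    label <- if (is.character(a$condition)) a$condition else "custom"
    list(stim = stim, ctx = a$context, label = label)
  })
  stimIdx <- do.call(rbind, lapply(conds, function(cn) {
    v <- vapply(stimNodes, function(sn)
      as.integer(cn$stim[[sn]]) + 1L, integer(1))
    if (length(v) == 0L) integer(0) else v
  }))
  if (is.null(stimIdx))
    stimIdx <- matrix(integer(0), nrow = length(conds), ncol = 0L)
  ctxIdx <- vapply(conds, function(cn)
    match(cn$ctx, structure@contextLevels), integer(1))
  if (anyNA(ctxIdx)) stop("unknown context level", call. = FALSE)
  arr <- .withSeed(seed, .forwardSampleArray(model, stimIdx, ctxIdx, T))
  lapply(seq_along(conds), function(i) {
    m <- matrix(.idxToState(arr[i, , ]), nrow = dim(arr)[2])
    rownames(m) <- structure@molecules
    trinarySeries(m, context = conds[[i]]$ctx,
                  condition = conds[[i]]$label,
                  stim = vapply(conds[[i]]$stim, as.integer, integer(1)))
  })
}
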