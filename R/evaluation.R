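#' @include score.R inference.R
NULL

#' Leave-one-series-out validation of DBN predictions
#'
#' Reproduces the cross-validation design of the study: each of the input
#' series is left out in turn, a DBN (structure plus parameters) is learned
#' on the remaining series, the target molecules are hidden in the held-out
#' series and predicted over the full time course with
#' \code{\link{predictPosterior}}, and the most probable states are compared
#' with the held-out observations. All time points (including time 0, which
#' the initial-slice model predicts) enter the accuracy denominator.
#'
#' @param seriesSet list of fully observed \linkS4class{TrinarySeries}
#'   (nine in the study design).
#' @param cfg a \code{\link{scoreConfig}}.
#' @param prior a \code{\link{priorKnowledge}}.
#' @param targets molecules to predict (default: the study's key molecules
#'   GLI1, CREB, JUN, p70S6K).
#' @param N particles for the importance sampler.
#' @param seed integer seed (per-fold substreams are derived from it).
#' @param pseudo Dirichlet pseudo-count for parameter learning.
#' @param includeT0 include the first time point in the accuracy
#'   denominator (default TRUE; configurable).
#' @return \code{data.frame} with one row per fold x target (plus a pooled
#'   \code{"(all)"} row per fold): fold, context, condition, target,
#'   accuracy.
#' @export
looValidate <- function(seriesSet, cfg = scoreConfig(),
                        prior = priorKnowledge("strong"),
                        targets = c("GLI1", "CREB", "JUN", "p70S6K"),
                        N = 1000L, seed = NULL, pseudo = 1,
                        includeT0 = TRUE) {
  if (length(seriesSet) < 2L)
    stop("need at least 2 series for cross-validation", call. = FALSE)
  mols <- rownames(stateMatrix(seriesSet[[1]]))
  if (!all(targets %in% mols))
    stop("target(s) absent from the node set: ",
         paste(setdiff(targets, mols), collapse = ", "), call. = FALSE)
  rows <- list()
  for (i in seq_along(seriesSet)) {
    train <- seriesSet[-i]
    held <- seriesSet[[i]]
    model <- fitDBN(train, cfg, prior, pseudo = pseudo)
    hidden <- stateMatrix(held)
    hidden[targets, ] <- NA
    ev <- trinarySeries(hidden, seriesContext(held),
                        seriesCondition(held), stimAssignment(held))
    post <- predictPosterior(model, ev, targets = targets, N = N,
                             seed = if (is.null(seed)) NULL
                                    else .childSeed(seed, i))
    calls <- mapState(post)
    tt <- if (includeT0) seq_len(nTimePoints(held)) else
      seq_len(nTimePoints(held))[-1]
    truth <- stateMatrix(held)[targets, tt, drop = FALSE]
    acc <- rowMeans(calls[targets, tt, drop = FALSE] == truth)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = i, context = seriesContext(held),
      condition = seriesCondition(held),
      target = c(targets, "(all)"),
      accuracy = c(acc, mean(calls[targets, tt, drop = FALSE] == truth)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Parametric bootstrap of edge confidence
#'
#' Fits a DBN to the complete data, then \code{B} times forward-samples a
#' dataset of identical shape (same number of series, lengths and
#' context/stimulation assignments), re-learns the structure on each
#' replicate with the same settings, and reports the relative frequency
#' with which every learnable molecule edge is recovered. Fixed wiring
#' (context, stimulation) is excluded.
#'
#' @param seriesSet list of fully observed \linkS4class{TrinarySeries}.
#' @param cfg a \code{\link{scoreConfig}}.
#' @param prior a \code{\link{priorKnowledge}} (the bootstrap re-learning
#'   uses the same prior regime as the original fit).
#' @param B number of bootstrap datasets (default 100).
#' @param seed integer seed.
#' @param pseudo Dirichlet pseudo-count.
#' @return \code{data.frame} (EdgeFrequencyTable) with columns \code{from},
#'   \code{to}, \code{freq}; attribute \code{B}; edges of the full-data fit
#'   are always included (frequency possibly 0).
#' @export
parametricBootstrap <- function(seriesSet, cfg = scoreConfig(),
                                prior = priorKnowledge("strong"),
                                B = 100L, seed = NULL, pseudo = 1) {
  stopifnot(B >= 1)
  model <- fitDBN(seriesSet, cfg, prior, pseudo = pseudo)
  T <- unique(vapply(seriesSet, nTimePoints, integer(1)))
  if (length(T) != 1L)
    stop("bootstrap requires series of equal length", call. = FALSE)
  assignments <- lapply(seriesSet, function(s)
    list(condition = stimAssignment(s), context = seriesContext(s)))
  counts <- new.env(parent = emptyenv())
  bump <- function(key) assign(key, (if (exists(key, counts))
    get(key, counts) else 0L) + 1L, counts)
  for (e in seq_len(nrow(edgeList(model)))) {
    ee <- edgeList(model)[e, ]
    assign(paste0(ee$from, "\t", ee$to), 0L, counts)
  }
  for (b in seq_len(B)) {
    sampled <- forwardSampleSet(model, assignments, T = T,
                                seed = if (is.null(seed)) NULL
                                       else .childSeed(seed, b))
    sb <- learnStructure(sampled, cfg, prior)
    el <- edgeList(sb)
    for (e in seq_len(nrow(el))) bump(paste0(el$from[e], "\t", el$to[e]))
  }
  keys <- ls(counts)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[`, character(1), 1L),
    to = vapply(parts, `[`, character(1), 2L),
    freq = vapply(keys, function(k) get(k, counts), numeric(1)) / B,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out <- out[order(-out$freq, out$from, out$to), ]
  attr(out, "B") <- as.integer(B)
  out
}

#' Edges above a bootstrap-confidence cutoff
#'
#' @param freqs an edge-frequency table from
#'   \code{\link{parametricBootstrap}}.
#' @param cutoff report edges with frequency strictly above this value
#'   (default 0.5, as in the study).
#' @return \code{data.frame} sorted by decreasing frequency with a
#'   \code{self_loop} flag (self-loops are typically dropped from graph
#'   displays).
#' @examples
#' f <- data.frame(from = c("a", "c"), to = c("b", "d"),
#'                 freq = c(0.97, 0.45))
#' stableEdges(f)
#' @export
stableEdges <- function(freqs, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  out <- freqs[freqs$freq > cutoff, , drop = FALSE]
  out <- out[order(-out$freq, out$from, out$to), , drop = FALSE]
  out$self_loop <- out$from == out$to
  rownames(out) <- NULL
  out
}
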