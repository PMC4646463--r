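#' @include dbn.R
NULL

#' Structure-search configuration
#'
#' @param alpha type-I error rate of the independence test behind the score
#'   penalty (expected proportion of false-positive edges); the penalty per
#'   parent is the (1 - alpha) chi-square quantile at the appropriate
#'   degrees of freedom. Default 0.10.
#' @param maxParents cap on the learnable in-degree per molecule. With
#'   trinary nodes, 3^4 parent configurations already exceed the number of
#'   transitions available in study-shaped data, so the default is 4.
#' @param selfLoops whether X(t-1) -> X(t) self-edges are candidate edges.
#' @return an object of class \code{ScoreConfig}.
#' @export
scoreConfig <- function(alpha = 0.10, maxParents = 4L, selfLoops = TRUE) {
  stopifnot(alpha > 0, alpha < 1, maxParents >= 0)
  structure(list(alpha = alpha, maxParents = as.integer(maxParents),
                 selfLoops = isTRUE(selfLoops)), class = "ScoreConfig")
}

#' Default literature prior network
#'
#' Reads the packaged (editable) edge-list fixture approximating the
#' published EGFR/SHH literature network.
#'
#' @param file optional path to an alternative SIF-like file
#'   (\code{parent<TAB>-><TAB>child} per line, \code{#} comments allowed).
#' @return \code{data.frame} with columns \code{from}, \code{to}.
#' @export
defaultLiteratureEdges <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "literature_edges.sif",
                        package = "dbnCrosstalk", mustWork = TRUE)
  ln <- trimws(readLines(file))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, character(1), 1L),
             to = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Background-knowledge settings for structure learning
#'
#' Three regimes: \code{"strong"} restricts each node's candidate parents to
#' its literature parents; \code{"weak"} allows all molecule parents but
#' relaxes the score penalty of literature edges by raising their type-I
#' error rate by \code{weakFactor}; \code{"none"} is fully data-driven.
#'
#' @param mode one of \code{"strong"}, \code{"weak"}, \code{"none"}.
#' @param edges literature edge list (\code{data.frame} with \code{from},
#'   \code{to}); default is the packaged fixture.
#' @param weakFactor multiplier (> 1) applied to alpha for literature edges
#'   in weak mode (default 2, clamped so the effective rate stays below 1).
#' @return an object of class \code{PriorKnowledge}.
#' @export
priorKnowledge <- function(mode = c("strong", "weak", "none"),
                           edges = defaultLiteratureEdges(),
                           weakFactor = 2) {
  mode <- match.arg(mode)
  stopifnot(weakFactor >= 1)
  edges <- as.data.frame(edges)[, c("from", "to")]
  structure(list(mode = mode, edges = edges, weakFactor = weakFactor),
            class = "PriorKnowledge")
}

# Slice-pair view of a series set, the sufficient input for scoring:
# child states at t paired with all molecule states at t-1.
.sliceData <- function(seriesSet) {
  if (inherits(seriesSet, "TrinarySeries")) seriesSet <- list(seriesSet)
  if (!is.null(seriesSet$prev)) return(seriesSet)    # already built
  mols <- sort(rownames(stateMatrix(seriesSet[[1]])))
  prev <- list(); cur <- list()
  for (s in seriesSet) {
    st <- stateMatrix(s)
    if (!identical(sort(rownames(st)), mols))
      stop("inconsistent node sets across series", call. = FALSE)
    if (anyNA(st)) stop("series contain unobserved entries", call. = FALSE)
    T <- ncol(st)
    if (T < 2L) next
    idx <- .stateToIdx(st[mols, , drop = FALSE])
    prev[[length(prev) + 1L]] <- t(idx[, -T, drop = FALSE])
    cur[[length(cur) + 1L]] <- t(idx[, -1L, drop = FALSE])
  }
  if (!length(prev)) stop("need at least one series with >= 2 time points",
                          call. = FALSE)
  list(prev = do.call(rbind, prev), cur = do.call(rbind, cur), mols = mols)
}

#' Plug-in mutual information of a contingency table (in nats)
#'
#' Empirical mutual information between the row and column variables of a
#' count table, with the convention 0 log 0 = 0.
#'
#' @param counts non-negative count matrix (e.g. child states x parent
#'   configurations).
#' @return mutual information in nats (>= 0).
#' @examples
#' mutualInformation(matrix(c(4, 0, 0, 4), 2))  # ln 2
#' @export
mutualInformation <- function(counts) {
  counts <- as.matrix(counts)
  N <- sum(counts)
  if (N < 1) stop("empty contingency table", call. = FALSE)
  p <- counts / N
  e <- outer(rowSums(p), colSums(p))
  nz <- p > 0
  max(sum(p[nz] * log(p[nz] / e[nz])), 0)
}

.entropyCounts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Ordered penalty terms for a candidate parent vector (already ordered):
# df_j = (r_child - 1)(r_j - 1) * prod_{k<j} r_k with all molecule
# cardinalities 3, so df_j = 4 * 3^(j-1).
.mitPenalty <- function(child, orderedParents, cfg, prior) {
  k <- length(orderedParents)
  if (k == 0L) return(0)
  alpha <- rep(cfg$alpha, k)
  if (prior$mode == "weak" && nrow(prior$edges)) {
    isLit <- paste(orderedParents, child) %in%
      paste(prior$edges$from, prior$edges$to)
    alpha[isLit] <- pmin(cfg$alpha * prior$weakFactor, 1)
  }
  sum(stats::qchisq(1 - alpha, df = 4 * 3^(seq_len(k) - 1)))
}

.miFromIdx <- function(childIdx, cfgIdx, nCfg) {
  tab <- tabulate((cfgIdx - 1L) * 3L + childIdx, nbins = 3L * nCfg)
  mutualInformation(matrix(tab, nrow = 3L))
}

#' MIT family score of a candidate parent set
#'
#' The mutual-information-test score of the family (child; parents):
#' \code{2 N MI(child(t); parents(t-1))} minus, per parent, the
#' \code{(1 - alpha)} chi-square quantile at degrees of freedom
#' \code{(r_child - 1)(r_j - 1) prod_(k<j) r_k}, parents ordered by
#' decreasing cardinality with name-lexicographic tie-break so the score is
#' a well-defined function of the set. In weak-prior mode, literature edges
#' use the relaxed rate \code{weakFactor * alpha}. The empty parent set
#' scores 0.
#'
#' @param child molecule name.
#' @param parents character vector of candidate molecule parents (at t-1).
#' @param data list of fully observed \linkS4class{TrinarySeries}.
#' @param cfg a \code{\link{scoreConfig}}.
#' @param prior a \code{\link{priorKnowledge}}.
#' @return scalar score.
#' @export
mitFamilyScore <- function(child, parents, data, cfg = scoreConfig(),
                           prior = priorKnowledge("none")) {
  if (length(parents) > cfg$maxParents)
    stop("more parents than cfg$maxParents", call. = FALSE)
  sd <- .sliceData(data)
  if (length(parents) == 0L) return(0)
  parents <- sort(unique(parents))       # equal cardinality: name order
  stopifnot(child %in% sd$mols, all(parents %in% sd$mols))
  N <- nrow(sd$prev)
  nCfg <- 3L^length(parents)
  cfgIdx <- .cfgIndex(sd$prev[, parents, drop = FALSE],
                      rep(3L, length(parents)))
  mi <- .miFromIdx(sd$cur[, child], cfgIdx, nCfg)
  2 * N * mi - .mitPenalty(child, parents, cfg, prior)
}

#' Optimal parent set of one molecule under the MIT score
#'
#' Exhaustive enumeration over all candidate subsets up to
#' \code{cfg$maxParents}, with a sound bound-based pruning of subset sizes
#' whose minimal attainable penalty already exceeds \code{2 N H(child)} (the
#' upper bound of the mutual-information term). Ties are broken toward the
#' smaller set, then lexicographically, so the result equals brute-force
#' enumeration.
#'
#' @param child molecule name.
#' @param candidates character vector of allowed parents.
#' @param data list of fully observed \linkS4class{TrinarySeries}.
#' @param cfg a \code{\link{scoreConfig}}.
#' @param prior a \code{\link{priorKnowledge}}.
#' @return character vector (possibly empty) of selected parents.
#' @export
optimalParents <- function(child, candidates, data, cfg = scoreConfig(),
                           prior = priorKnowledge("none")) {
  sd <- .sliceData(data)
  candidates <- sort(unique(candidates))
  best <- character(0); bestScore <- 0
  if (!length(candidates)) return(best)
  N <- nrow(sd$prev)
  childIdx <- sd$cur[, child]
  childCounts <- tabulate(childIdx, nbins = 3L)
  bound <- 2 * N * .entropyCounts(childCounts)
  maxK <- min(cfg$maxParents, length(candidates))
  if (maxK == 0L) return(best)
  # per-position chi-square penalties, precomputed (d.f. = 4 * 3^(j-1))
  dfs <- 4 * 3^(seq_len(maxK) - 1)
  qStd <- stats::qchisq(1 - cfg$alpha, df = dfs)
  weak <- prior$mode == "weak"
  qLit <- if (weak)
    stats::qchisq(1 - min(cfg$alpha * prior$weakFactor, 1), df = dfs)
  else qStd
  isLit <- if (weak && nrow(prior$edges))
    candidates %in% prior$edges$from[prior$edges$to == child]
  else rep(FALSE, length(candidates))
  names(isLit) <- candidates
  prev0 <- sd$prev[, candidates, drop = FALSE] - 1L   # 0-based states
  for (k in seq_len(maxK)) {
    if (sum(pmin(qStd, qLit)[seq_len(k)]) > bound) break
    mult <- 3^(seq_len(k) - 1)
    nCfg <- 3L^k
    subsets <- utils::combn(seq_along(candidates), k, simplify = FALSE)
    for (si in subsets) {
      cfgIdx <- 1L + as.integer(prev0[, si, drop = FALSE] %*% mult)
      tab <- tabulate((cfgIdx - 1L) * 3L + childIdx, nbins = 3L * nCfg)
      cs <- tabulate(cfgIdx, nbins = nCfg)
      nz <- which(tab > 0L)
      i <- (nz - 1L) %% 3L + 1L
      j <- (nz - 1L) %/% 3L + 1L
      mi <- sum(tab[nz] / N *
                  log(as.numeric(tab[nz]) * N /
                        (childCounts[i] * cs[j])))
      pen <- sum(ifelse(isLit[si], qLit[seq_len(k)], qStd[seq_len(k)]))
      sc <- 2 * N * max(mi, 0) - pen
      if (sc > bestScore + 1e-12) { best <- candidates[si]; bestScore <- sc }
    }
  }
  best
}

#' Learn the DBN structure from discretized series
#'
#' Installs the fixed wiring (context node parenting every molecule;
#' stimulation nodes parenting their known targets) and learns each
#' molecule's optimal t-1 parent set independently with
#' \code{\link{optimalParents}} -- valid because every learnable edge
#' crosses time slices, so acyclicity of the unrolled graph is automatic
#' and the decomposable score is maximised per family.
#'
#' @param seriesSet list of fully observed \linkS4class{TrinarySeries}.
#' @param cfg a \code{\link{scoreConfig}}.
#' @param prior a \code{\link{priorKnowledge}}; in strong mode candidates
#'   are restricted to literature parents (plus the self-loop when allowed).
#' @param stimTargets fixed intervention wiring.
#' @param contextLevels context-node levels.
#' @return a \linkS4class{DBNStructure} with \code{useContext = TRUE}.
#' @examples
#' s <- simulateStudySeries(plantedStudyModel(0.9), T = 14, seed = 1,
#'                          includeControls = FALSE)
#' learnStructure(s, scoreConfig(), priorKnowledge("strong"))
#' @export
learnStructure <- function(seriesSet, cfg = scoreConfig(),
                           prior = priorKnowledge("strong"),
                           stimTargets = NULL, contextLevels = CONTEXT_LEVELS) {
  sd <- .sliceData(seriesSet)
  mols <- sd$mols
  if (is.null(stimTargets)) stimTargets <- defaultStimTargets(mols)
  ps <- list()
  for (nm in mols) {
    cand <- if (prior$mode == "strong") {
      prior$edges$from[prior$edges$to == nm]
    } else mols
    cand <- intersect(cand, mols)
    cand <- if (cfg$selfLoops) union(cand, nm) else setdiff(cand, nm)
    ps[[nm]] <- optimalParents(nm, cand, sd, cfg, prior)
  }
  dbnStructure(mols, parentSets = ps, stimTargets = stimTargets,
               contextLevels = contextLevels, useContext = TRUE)
}

#' Learn structure and parameters in one call
#'
#' @inheritParams learnStructure
#' @param pseudo Dirichlet pseudo-count for parameter smoothing.
#' @return a \linkS4class{DBNModel}.
#' @export
fitDBN <- function(seriesSet, cfg = scoreConfig(),
                   prior = priorKnowledge("strong"), pseudo = 1,
                   stimTargets = NULL, contextLevels = CONTEXT_LEVELS) {
  struct <- learnStructure(seriesSet, cfg, prior, stimTargets,
                           contextLevels)
  learnParameters(collectTransitions(seriesSet, struct), struct,
                  pseudo = pseudo)
}
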