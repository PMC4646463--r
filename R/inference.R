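#' @include dbn.R
NULL

#' Posterior prediction of hidden molecules by likelihood weighting
#'
#' Sequential importance sampling over the time course: \code{N} particles
#' are drawn from the initial distributions at time 0 (observed nodes
#' clamped to the evidence and their probability folded into the likelihood
#' weight); at every later step whole particles are multinomially resampled
#' proportional to the current weights, unobserved nodes are sampled from
#' their conditional tables given the resampled previous slice, and the
#' weights are rebuilt from the likelihood of the step's observed nodes.
#' The posterior of a hidden node at time t is the weight-normalised
#' frequency of its sampled states at t.
#'
#' Pseudo-count smoothing makes every observation possible under a learned
#' model, so a complete weight collapse signals an inconsistent model and
#' raises an error rather than being renormalised away.
#'
#' @param model a \linkS4class{DBNModel} with learned parameters.
#' @param evidence a \linkS4class{TrinarySeries} whose hidden entries (the
#'   prediction targets) are \code{NA}; stimulation and context are always
#'   observed.
#' @param targets molecules to report posteriors for; default: all molecules
#'   that are fully hidden in \code{evidence}. Targets must be unobserved.
#' @param N number of particles (default 1000).
#' @param seed optional integer seed.
#' @return a \linkS4class{PosteriorTable} (targets x time x 3 states).
#' @examples
#' m <- plantedStudyModel(0.9)
#' ev <- sampleTimeSeries(m, "EGF", "cyt_protein", T = 6, seed = 1)
#' hid <- stateMatrix(ev); hid["CREB", ] <- NA
#' ev2 <- trinarySeries(hid, "cyt_protein", "EGF")
#' predictPosterior(m, ev2, N = 500, seed = 2)
#' @export
predictPosterior <- function(model, evidence, targets = NULL, N = 1000L,
                             seed = NULL) {
  stopifnot(N >= 1)
  structure <- model@structure
  mols <- structure@molecules
  st <- stateMatrix(evidence)[mols, , drop = FALSE]
  T <- ncol(st)
  if (is.null(targets)) targets <- mols[rowSums(!is.na(st)) == 0L]
  if (!length(targets)) stop("no hidden molecules to predict",
                             call. = FALSE)
  if (!all(targets %in% mols))
    stop("target(s) absent from the model's node set: ",
         paste(setdiff(targets, mols), collapse = ", "), call. = FALSE)
  if (any(!is.na(st[targets, , drop = FALSE])))
    stop("targets must be unobserved in the evidence", call. = FALSE)
  obsIdx <- .stateToIdx(st)                     # NA where hidden
  fx <- .fixedIdx(evidence, structure)
  infoI <- lapply(stats::setNames(mols, mols), .nodeParentInfo,
                  structure = structure, initial = TRUE)
  info <- lapply(stats::setNames(mols, mols), .nodeParentInfo,
                 structure = structure)
  post <- array(NA_real_, dim = c(length(targets), T, 3L),
                dimnames = list(targets, colnames(st), c("-1", "0", "1")))
  .withSeed(seed, {
    cur <- matrix(1L, nrow = N, ncol = length(mols),
                  dimnames = list(NULL, mols))
    w <- rep(1, N)
    for (j in seq_along(mols)) {
      z <- infoI[[j]]
      ci <- .cfgIndex(matrix(c(fx$stim[z$stim], if (z$ctx) fx$ctx),
                             nrow = 1L), z$cards)
      p <- model@initial[[mols[j]]]$prob[ci, ]
      o <- obsIdx[mols[j], 1L]
      if (!is.na(o)) { cur[, j] <- o; w <- w * p[o] }
      else cur[, j] <- .sampleRows(matrix(p, nrow = N, ncol = 3L,
                                          byrow = TRUE))
    }
    if (all(w == 0))
      stop("particle weights degenerated at time 1", call. = FALSE)
    for (tg in targets)
      post[tg, 1L, ] <- vapply(1:3, function(v)
        sum(w * (cur[, tg] == v)), numeric(1)) / sum(w)
    fixedCfg <- lapply(info, function(z) c(fx$stim[z$stim],
                                           if (z$ctx) fx$ctx))
    if (T >= 2L) for (t in 2:T) {
      idx <- sample.int(N, N, replace = TRUE, prob = w)
      prev <- cur[idx, , drop = FALSE]
      w <- rep(1, N)
      for (j in seq_along(mols)) {
        z <- info[[j]]
        vals <- cbind(prev[, z$mol, drop = FALSE],
                      matrix(rep(fixedCfg[[j]], each = N), nrow = N))
        cfg <- .cfgIndex(vals, z$cards)
        pr <- model@transition[[mols[j]]]$prob[cfg, , drop = FALSE]
        o <- obsIdx[mols[j], t]
        if (!is.na(o)) { cur[, j] <- o; w <- w * pr[, o] }
        else cur[, j] <- .sampleRows(pr)
      }
      if (all(w == 0))
        stop(sprintf("particle weights degenerated at time %d", t),
             call. = FALSE)
      for (tg in targets)
        post[tg, t, ] <- vapply(1:3, function(v)
          sum(w * (cur[, tg] == v)), numeric(1)) / sum(w)
    }
  })
  new("PosteriorTable", probs = post)
}

#' Most probable state per target and time point
#'
#' Argmax of the posterior state distribution. Ties that include the
#' no-change state (and exact three-way ties) resolve to 0; a remaining
#' two-way tie between -1 and +1 resolves to the state with the larger
#' prior marginal when one is supplied, else to 0.
#'
#' @param posterior a \linkS4class{PosteriorTable}.
#' @param priorMarginal optional length-3 probability vector (states
#'   -1, 0, 1) used to break up-vs-down ties.
#' @param tol numerical tolerance for tie detection.
#' @return integer matrix (targets x time) of trinary calls.
#' @examples
#' p <- array(c(0.2, 0.5, 0.3), c(1, 1, 3),
#'            dimnames = list("A", "t1", c("-1", "0", "1")))
#' mapState(new("PosteriorTable", probs = p))
#' @export
mapState <- function(posterior, priorMarginal = NULL, tol = 1e-9) {
  p <- posterior@probs
  out <- matrix(0L, nrow = dim(p)[1], ncol = dim(p)[2],
                dimnames = dimnames(p)[1:2])
  for (i in seq_len(dim(p)[1])) for (t in seq_len(dim(p)[2])) {
    v <- p[i, t, ]
    tied <- which(v >= max(v) - tol)
    out[i, t] <- if (length(tied) == 1L) .idxToState(tied)
      else if (2L %in% tied || length(tied) == 3L) 0L
      else if (!is.null(priorMarginal) &&
               abs(priorMarginal[1] - priorMarginal[3]) > tol) {
        if (priorMarginal[3] > priorMarginal[1]) 1L else -1L
      } else 0L
  }
  out
}
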