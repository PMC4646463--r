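#' @include dbn.R
NULL

#' Default molecule node set
#'
#' The 13 signalling molecules of the default model, read from the editable
#' fixture \code{inst/extdata/molecule_nodes.txt}. The measured panel is not
#' uniquely determined by published text, so the set ships as a replaceable
#' fixture, not hard-coded truth.
#'
#' @param file optional path to an alternative node list (one name per line,
#'   \code{#} comments allowed).
#' @return character vector of molecule names.
#' @export
defaultMoleculeNodes <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "molecule_nodes.txt",
                        package = "dbnCrosstalk", mustWork = TRUE)
  x <- trimws(readLines(file))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Specify a ground-truth DBN for simulation
#'
#' Describes a generating model: directed edges between molecules (parent at
#' t-1, child at t), each with a sign (+1 activation, -1 inhibition) and a
#' strength -- the probability mass placed on the parent-determined child
#' state. Stimulation nodes are wired to their known targets and raise the
#' activation probability of those targets when switched on.
#'
#' @param nodes molecule names.
#' @param edges \code{data.frame} with columns \code{from}, \code{to} and
#'   optionally \code{sign} (+1/-1, default +1) and \code{strength} (default
#'   \code{edgeStrength}). \code{NULL} means no edges.
#' @param edgeStrength default per-edge strength in [0, 1]; also used for the
#'   stimulation-node influence on its targets.
#' @param stimTargets named list stimulation node -> targets.
#' @param contextLevels context levels recorded on simulated series (the
#'   generator shares CPTs across contexts; context is metadata here).
#' @param zeroBias probability mass on the no-change state for parentless
#'   nodes and for the time-0 distributions (default 1/3 = uniform). Values
#'   above 1/3 emulate datasets where most molecule/time cells are not
#'   differential, as in real perturbation screens.
#' @return an object of class \code{GroundTruthSpec}.
#' @examples
#' groundTruthSpec(c("A", "B"), data.frame(from = "A", to = "B"),
#'                 edgeStrength = 0.7)
#' @export
groundTruthSpec <- function(nodes = defaultMoleculeNodes(), edges = NULL,
                            edgeStrength = 0.8,
                            stimTargets = defaultStimTargets(nodes),
                            contextLevels = CONTEXT_LEVELS,
                            zeroBias = 1 / 3) {
  stopifnot(zeroBias > 0, zeroBias < 1)
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0))
  edges <- as.data.frame(edges)
  if (is.null(edges$sign)) edges$sign <- rep(1L, nrow(edges))
  if (is.null(edges$strength)) edges$strength <- rep(edgeStrength,
                                                     nrow(edges))
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(bad))
    stop("unknown node(s) in edges: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(edges$strength < 0 | edges$strength > 1) ||
      edgeStrength < 0 || edgeStrength > 1)
    stop("edge strengths must lie in [0, 1]", call. = FALSE)
  if (!all(unlist(stimTargets) %in% nodes))
    stop("stimulation targets must be molecule nodes", call. = FALSE)
  structure(list(nodes = nodes, edges = edges, edgeStrength = edgeStrength,
                 stimTargets = stimTargets, contextLevels = contextLevels,
                 zeroBias = zeroBias),
            class = "GroundTruthSpec")
}

#' Build a generating DBN model from a ground-truth specification
#'
#' Constructs CPTs by a monotone sign rule: for each parent configuration the
#' child's target state is the sign of the signed sum of its molecule-parent
#' states plus active stimulation parents (+1 each). The target state
#' receives the child's strength (mean of its incoming edge strengths), the
#' two remaining states split the rest equally. Molecules without parents
#' are uniform over \{-1, 0, 1\}; time-0 distributions are uniform unless
#' overridden.
#'
#' @param spec a \code{\link{groundTruthSpec}}.
#' @param initial optional named list of length-3 numeric vectors (state
#'   order -1, 0, 1) overriding the time-0 distribution of selected nodes.
#' @return a \linkS4class{DBNModel} with context shared (context is series
#'   metadata, not a CPT dimension, in generating models).
#' @examples
#' sp <- groundTruthSpec(c("A", "B"), data.frame(from = "A", to = "B"),
#'                       edgeStrength = 0.7)
#' makeGroundTruthModel(sp)
#' @export
makeGroundTruthModel <- function(spec, initial = NULL) {
  stopifnot(inherits(spec, "GroundTruthSpec"))
  ps <- split(spec$edges$from, factor(spec$edges$to, levels = spec$nodes))
  struct <- dbnStructure(spec$nodes, parentSets = ps,
                         stimTargets = spec$stimTargets,
                         contextLevels = spec$contextLevels,
                         useContext = FALSE)
  zb <- if (is.null(spec$zeroBias)) 1 / 3 else spec$zeroBias
  rest <- c((1 - zb) / 2, zb, (1 - zb) / 2)
  trans <- list(); init <- list()
  for (nm in spec$nodes) {
    z <- .nodeParentInfo(struct, nm)
    ed <- spec$edges[spec$edges$to == nm, , drop = FALSE]
    sgn <- stats::setNames(ed$sign, ed$from)[z$mol]
    w <- if (length(z$mol) + length(z$stim) > 0)
      mean(c(ed$strength, rep(spec$edgeStrength, length(z$stim))))
    else NA_real_
    grid <- .cfgGrid(z$cards)
    nCfg <- nrow(grid)
    prob <- matrix(rest, nrow = nCfg, ncol = 3L, byrow = TRUE)
    if (!is.na(w)) {
      nMol <- length(z$mol)
      molStates <- grid[, seq_len(nMol), drop = FALSE] - 2L
      stimOn <- grid[, nMol + seq_along(z$stim), drop = FALSE] - 1L
      score <- as.vector(molStates %*% sgn) + rowSums(stimOn)
      target <- sign(score) + 2L
      prob[] <- (1 - w) / 2
      prob[cbind(seq_len(nCfg), target)] <- w
    }
    trans[[nm]] <- list(parents = z$parents, cards = z$cards, prob = prob)
    zi <- .nodeParentInfo(struct, nm, initial = TRUE)
    p0 <- if (!is.null(initial[[nm]])) {
      v <- as.numeric(initial[[nm]]); v / sum(v)
    } else rest
    init[[nm]] <- list(parents = zi$parents, cards = zi$cards,
                       prob = matrix(p0, nrow = prod(c(zi$cards, 1L)),
                                     ncol = 3L, byrow = TRUE))
  }
  new("DBNModel", structure = struct, transition = trans, initial = init)
}

#' Edgeless uniform model (every node i.i.d. uniform at all times)
#'
#' @param nodes molecule names.
#' @return a \linkS4class{DBNModel}.
#' @export
uniformModel <- function(nodes) {
  makeGroundTruthModel(groundTruthSpec(nodes, edges = NULL))
}

#' Planted signalling cascade used in recovery experiments
#'
#' A single-parent-per-child cascade drawn from the default literature
#' network: the EGFR branch (EGFR -> ERK/AKT/p38 -> CREB/JUN/p70S6K -> RPS6)
#' and the hedgehog branch (SHH -> PTCH1 -> GLI2 -> GLI1 -> HHIP).
#'
#' @param nodes molecule names (must contain the cascade members).
#' @return \code{data.frame} of planted directed edges.
#' @export
plantedStudyEdges <- function(nodes = defaultMoleculeNodes()) {
  e <- data.frame(
    from = c("EGFR", "EGFR", "EGFR", "ERK", "p38", "AKT", "p70S6K",
             "SHH", "PTCH1", "GLI2", "GLI1"),
    to = c("ERK", "AKT", "p38", "CREB", "JUN", "p70S6K", "RPS6",
           "PTCH1", "GLI2", "GLI1", "HHIP"),
    stringsAsFactors = FALSE)
  miss <- setdiff(unique(c(e$from, e$to)), nodes)
  if (length(miss))
    stop("node set lacks cascade members: ", paste(miss, collapse = ", "),
         call. = FALSE)
  e
}

#' Planted cascade with graded edge strengths
#'
#' The same cascade as \code{\link{plantedStudyEdges}} with heterogeneous
#' strengths: receptor-proximal edges are tight (0.8), distal effector and
#' transcriptional edges noisier (0.55-0.65). This places part of the
#' signal near the MIT detectability threshold, the regime in which
#' background knowledge has value in structure learning.
#'
#' @param nodes molecule names (must contain the cascade members).
#' @return \code{data.frame} of planted edges with a \code{strength} column.
#' @export
gradedStudyEdges <- function(nodes = defaultMoleculeNodes()) {
  e <- plantedStudyEdges(nodes)
  e$strength <- c(0.8, 0.8, 0.8, 0.55, 0.55, 0.55, 0.65, 0.8, 0.65, 0.55,
                  0.65)
  e
}

#' Ground-truth model with the planted study cascade
#'
#' @param edgeStrength strength of every planted edge (default 0.8).
#' @param nodes molecule names.
#' @return a \linkS4class{DBNModel}.
#' @export
plantedStudyModel <- function(edgeStrength = 0.8,
                              nodes = defaultMoleculeNodes()) {
  makeGroundTruthModel(groundTruthSpec(nodes,
                                       edges = plantedStudyEdges(nodes),
                                       edgeStrength = edgeStrength))
}

#' Simulate the study design: nine stimulated series plus paired controls
#'
#' Samples the full experimental layout: protein measurements in cytoplasm
#' and nucleus under EGF, SHH and EGF+SHH, and transcript measurements under
#' EGF, GLI and EGF+GLI (GLI induction replacing SHH stimulation), each over
#' \code{T} time points -- nine stimulated series. Controls (all stimulation
#' nodes off) are all-zero state series by construction, because trinary
#' states are differential calls against that very control.
#'
#' @param model generating \linkS4class{DBNModel}.
#' @param T time points per series.
#' @param seed integer seed.
#' @param includeControls append one zero-state control series per context.
#' @return list of \linkS4class{TrinarySeries} (9, or 12 with controls).
#' @examples
#' length(simulateStudySeries(plantedStudyModel(), T = 14, seed = 1))
#' @export
simulateStudySeries <- function(model, T = 14L, seed = NULL,
                                includeControls = TRUE) {
  design <- list(
    list(condition = "EGF", context = "cyt_protein"),
    list(condition = "SHH", context = "cyt_protein"),
    list(condition = "EGF+SHH", context = "cyt_protein"),
    list(condition = "EGF", context = "nuc_protein"),
    list(condition = "SHH", context = "nuc_protein"),
    list(condition = "EGF+SHH", context = "nuc_protein"),
    list(condition = "EGF", context = "transcript"),
    list(condition = "GLI", context = "transcript"),
    list(condition = "EGF+GLI", context = "transcript"))
  out <- forwardSampleSet(model, design, T = T, seed = seed)
  if (includeControls) {
    mols <- molecules(model)
    for (ctx in unique(vapply(design, `[[`, character(1), "context"))) {
      z <- matrix(0L, nrow = length(mols), ncol = T,
                  dimnames = list(mols, NULL))
      out <- c(out, list(trinarySeries(z, context = ctx,
                                       condition = "control")))
    }
  }
  out
}

#' Replicate-noise model for expression emulation
#'
#' @param sigma0 baseline log-scale standard deviation (> 0).
#' @param trendSlope mean-variance trend coefficient: residual s.d. decreases
#'   log-linearly in the molecule's baseline mean.
#' @param techRho within-biological-replicate correlation of technical
#'   replicates, in [0, 1).
#' @param effectSize log-fold-change magnitude mapped onto states of +/-1.
#' @param nBio,nTech numbers of biological and technical replicates.
#' @return an object of class \code{NoiseModel}.
#' @export
noiseModel <- function(sigma0 = 0.25, trendSlope = 0.15, techRho = 0.7,
                       effectSize = 1.5, nBio = 3L, nTech = 3L) {
  stopifnot(sigma0 > 0, techRho >= 0, techRho < 1, effectSize > 0,
            nBio >= 1, nTech >= 1)
  structure(list(sigma0 = sigma0, trendSlope = trendSlope,
                 techRho = techRho, effectSize = effectSize,
                 nBio = as.integer(nBio), nTech = as.integer(nTech)),
            class = "NoiseModel")
}

#' Emulate replicate-level expression data from trinary series
#'
#' Inverts the discretization: every molecule/context/condition/time cell is
#' expanded into \code{nBio x nTech} log-intensities equal to the molecule's
#' baseline plus \code{state x effectSize}, with biological noise (s.d. from
#' a log-linear mean-variance trend) shared within a biological replicate
#' and technical noise on top, giving within-replicate correlation
#' \code{techRho}. Transcript-context rows also get small detection
#' p-values (expressed probes).
#'
#' @param seriesSet list of \linkS4class{TrinarySeries}; must contain a
#'   control-condition series for every context that has a stimulated
#'   series.
#' @param noise a \code{\link{noiseModel}}.
#' @param seed integer seed.
#' @param nAntibodies antibodies emitted per molecule (protein contexts).
#' @param nBackgroundProbes extra transcript probes with no differential
#'   signal (state 0 in every condition), named \code{bg001}, ... Real
#'   expression arrays measure far more genes than the modelled molecules;
#'   these probes anchor quantile normalization the way the unchanged bulk
#'   of the genome does on a real platform. Default 0.
#' @param baselineRange range of per-molecule baseline log-intensities.
#' @return \code{data.frame} (ExpressionTable) with columns molecule,
#'   antibody, context, condition, time, bio_rep, tech_rep, value,
#'   detection_p.
#' @examples
#' s <- simulateStudySeries(plantedStudyModel(), T = 4, seed = 1)
#' head(emulateExpression(s, noiseModel(), seed = 2))
#' @export
emulateExpression <- function(seriesSet, noise = noiseModel(), seed = NULL,
                              nAntibodies = 1L, nBackgroundProbes = 0L,
                              baselineRange = c(6, 10)) {
  conds <- vapply(seriesSet, seriesCondition, character(1))
  ctxs <- vapply(seriesSet, seriesContext, character(1))
  for (ctx in unique(ctxs[conds != "control"]))
    if (!any(conds == "control" & ctxs == ctx))
      stop("missing control series for context ", ctx, call. = FALSE)
  mols <- molecules(seriesSet[[1]])
  bg <- if (nBackgroundProbes > 0)
    sprintf("bg%03d", seq_len(nBackgroundProbes)) else character(0)
  .withSeed(seed, {
    baseline <- stats::setNames(
      stats::runif(length(mols) + length(bg), baselineRange[1],
                   baselineRange[2]), c(mols, bg))
    sdMol <- noise$sigma0 *
      exp(-noise$trendSlope * (baseline - mean(baselineRange)))
    out <- vector("list", length(seriesSet))
    for (i in seq_along(seriesSet)) {
      s <- seriesSet[[i]]
      T <- nTimePoints(s)
      isTx <- seriesContext(s) == "transcript"
      nAb <- if (isTx) 1L else as.integer(nAntibodies)
      feats <- if (isTx) c(mols, bg) else mols
      g <- expand.grid(tech_rep = seq_len(noise$nTech),
                       bio_rep = seq_len(noise$nBio),
                       time = seq_len(T), antibody = seq_len(nAb),
                       molecule = feats, stringsAsFactors = FALSE)
      stm <- rbind(stateMatrix(s),
                   matrix(0L, nrow = length(feats) - nrow(stateMatrix(s)),
                          ncol = T))
      rownames(stm) <- c(rownames(stateMatrix(s)),
                         setdiff(feats, rownames(stateMatrix(s))))
      st <- stm[cbind(match(g$molecule, rownames(stm)), g$time)]
      mu <- baseline[g$molecule] + st * noise$effectSize
      sdv <- sdMol[g$molecule]
      nBioCell <- nrow(g) / noise$nTech
      bnoise <- rep(stats::rnorm(nBioCell, 0,
                                 sqrt(noise$techRho) *
                                   sdv[seq(1, nrow(g), by = noise$nTech)]),
                    each = noise$nTech)
      tnoise <- stats::rnorm(nrow(g), 0, sqrt(1 - noise$techRho) * sdv)
      out[[i]] <- data.frame(
        molecule = g$molecule,
        antibody = paste0(g$molecule, "_ab", g$antibody),
        context = seriesContext(s), condition = seriesCondition(s),
        time = g$time, bio_rep = g$bio_rep, tech_rep = g$tech_rep,
        value = as.numeric(mu + bnoise + tnoise),
        detection_p = if (isTx) stats::runif(nrow(g), 0, 0.005)
          else NA_real_,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
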