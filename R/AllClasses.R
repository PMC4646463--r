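#' @include AllGenerics.R
NULL

CONTEXT_LEVELS <- c("cyt_protein", "nuc_protein", "transcript")
STIM_NODES <- c("EGF_stim", "SHH_stim", "GLI_stim")

#' TrinarySeries: one discretized perturbation time course
#'
#' Holds the trinary differential states (-1 = significantly down, 0 = no
#' significant change, +1 = significantly up, relative to the matched control)
#' of every molecule over a time course measured in one biological context
#' (cytoplasmic protein, nuclear protein or transcript) under one stimulation
#' condition. Entries may be \code{NA} to mark hidden/unobserved values when
#' the object is used as inference evidence.
#'
#' @slot states integer matrix, molecules x time points, entries in
#'   \{-1, 0, 1\} or \code{NA}.
#' @slot context one of \code{"cyt_protein"}, \code{"nuc_protein"},
#'   \code{"transcript"}.
#' @slot condition free-text condition label (e.g. \code{"EGF+SHH"}).
#' @slot stim named 0/1 integer vector over the stimulation (intervention)
#'   nodes, constant over the whole series.
#' @export
setClass("TrinarySeries",
  representation(states = "matrix", context = "character",
                 condition = "character", stim = "integer"))

setValidity("TrinarySeries", function(object) {
  s <- object@states
  if (is.null(rownames(s))) return("states must have molecule rownames")
  ok <- s[!is.na(s)] %in% c(-1L, 0L, 1L)
  if (!all(ok)) return("states must lie in {-1, 0, 1} (or NA for hidden)")
  if (length(object@context) != 1L || !object@context %in% CONTEXT_LEVELS)
    return(sprintf("context must be one of %s",
                   paste(CONTEXT_LEVELS, collapse = ", ")))
  if (is.null(names(object@stim)) || !all(object@stim %in% c(0L, 1L)))
    return("stim must be a named 0/1 vector")
  TRUE
})

#' Construct a TrinarySeries
#'
#' @param states numeric/integer matrix (molecules x time) with entries in
#'   \{-1, 0, 1\} or \code{NA}; rownames are molecule identifiers.
#' @param context biological context of the measurements.
#' @param condition condition label; stimulation values are derived from it
#'   when \code{stim} is missing (\code{"EGF+SHH"} sets EGF_stim and SHH_stim).
#' @param stim optional named 0/1 vector over stimulation nodes.
#' @return a \linkS4class{TrinarySeries}.
#' @examples
#' m <- matrix(0L, 2, 4, dimnames = list(c("EGFR", "ERK"), NULL))
#' trinarySeries(m, "cyt_protein", "EGF")
#' @export
trinarySeries <- function(states, context, condition = "control",
                          stim = NULL) {
  storage.mode(states) <- "integer"
  if (is.null(colnames(states)))
    colnames(states) <- paste0("t", seq_len(ncol(states)))
  if (is.null(stim)) stim <- conditionToStim(condition)
  stim <- vapply(stim, as.integer, integer(1))
  new("TrinarySeries", states = states, context = context,
      condition = condition, stim = stim)
}

#' Map a condition label to stimulation-node values
#'
#' Conditions are parsed by component: any of \code{EGF}, \code{SHH},
#' \code{GLI} present in the label (separated by \code{+}) switches the
#' corresponding intervention node on; \code{"control"} switches all off.
#'
#' @param condition character label such as \code{"EGF+SHH"} or \code{"GLI"}.
#' @return named integer 0/1 vector over \code{EGF_stim}, \code{SHH_stim},
#'   \code{GLI_stim}.
#' @examples
#' conditionToStim("EGF+GLI")
#' @export
conditionToStim <- function(condition) {
  parts <- strsplit(condition, "+", fixed = TRUE)[[1]]
  c(EGF_stim = as.integer("EGF" %in% parts),
    SHH_stim = as.integer("SHH" %in% parts),
    GLI_stim = as.integer("GLI" %in% parts))
}

#' @rdname accessors
#' @export
setMethod("stateMatrix", "TrinarySeries", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("seriesContext", "TrinarySeries", function(x) x@context)
#' @rdname accessors
#' @export
setMethod("seriesCondition", "TrinarySeries", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("stimAssignment", "TrinarySeries", function(x) x@stim)
#' @rdname accessors
#' @export
setMethod("nTimePoints", "TrinarySeries", function(x) ncol(x@states))
#' @rdname accessors
#' @export
setMethod("molecules", "TrinarySeries", function(x) rownames(x@states))

setMethod("show", "TrinarySeries", function(object) {
  cat(sprintf("TrinarySeries: %d molecules x %d time points\n",
              nrow(object@states), ncol(object@states)))
  cat(sprintf("  context: %s | condition: %s | stim: %s\n", object@context,
              object@condition,
              paste(names(object@stim), object@stim, sep = "=",
                    collapse = " ")))
  if (anyNA(object@states))
    cat(sprintf("  hidden entries: %d\n", sum(is.na(object@states))))
})

#' DBNStructure: the graph of a first-order dynamic Bayesian network
#'
#' All learnable edges run from slice t-1 to slice t between molecule nodes
#' (self-loops allowed). Fixed wiring encodes the experimental design:
#' intervention nodes parent their known targets, and an optional 3-level
#' context node parents every molecule.
#'
#' @slot molecules character vector of molecule node names.
#' @slot parentSets named list: per molecule, its molecule parents at t-1.
#' @slot stimTargets named list: stimulation node -> target molecules.
#' @slot contextLevels the levels of the context node.
#' @slot useContext whether the context node parents every molecule.
#' @export
setClass("DBNStructure",
  representation(molecules = "character", parentSets = "list",
                 stimTargets = "list", contextLevels = "character",
                 useContext = "logical"))

setValidity("DBNStructure", function(object) {
  m <- object@molecules
  if (anyDuplicated(m)) return("duplicate molecule names")
  if (!identical(sort(names(object@parentSets)), sort(m)))
    return("parentSets must have one entry per molecule")
  bad <- unlist(object@parentSets)[!unlist(object@parentSets) %in% m]
  if (length(bad)) return(paste("unknown parent node(s):",
                                paste(unique(bad), collapse = ", ")))
  badT <- unlist(object@stimTargets)[!unlist(object@stimTargets) %in% m]
  if (length(badT)) return(paste("unknown stimulation target(s):",
                                 paste(unique(badT), collapse = ", ")))
  if (any(names(object@stimTargets) %in% m))
    return("stimulation nodes cannot also be molecules")
  TRUE
})

#' Construct a DBNStructure
#'
#' @param molecules molecule node names.
#' @param parentSets named list of molecule parent sets (at t-1); missing
#'   molecules get an empty parent set.
#' @param stimTargets named list mapping stimulation nodes to their target
#'   molecules. The default wires \code{EGF_stim -> EGFR},
#'   \code{SHH_stim -> PTCH1, HHIP} and \code{GLI_stim -> GLI1}, restricted
#'   to targets actually present in \code{molecules}.
#' @param contextLevels levels of the context node.
#' @param useContext if \code{TRUE} the context node parents every molecule,
#'   so conditional probabilities are context-specific.
#' @return a \linkS4class{DBNStructure}.
#' @export
dbnStructure <- function(molecules, parentSets = list(),
                         stimTargets = defaultStimTargets(molecules),
                         contextLevels = CONTEXT_LEVELS,
                         useContext = TRUE) {
  ps <- stats::setNames(vector("list", length(molecules)), molecules)
  for (nm in molecules) ps[[nm]] <- sort(unique(as.character(
    if (nm %in% names(parentSets)) parentSets[[nm]] else character(0))))
  new("DBNStructure", molecules = molecules, parentSets = ps,
      stimTargets = stimTargets, contextLevels = contextLevels,
      useContext = isTRUE(useContext))
}

#' Default intervention wiring of the study design
#'
#' @param molecules molecule names used to drop targets that are absent.
#' @return named list stimulation node -> targets.
#' @export
defaultStimTargets <- function(molecules) {
  full <- list(EGF_stim = "EGFR", SHH_stim = c("PTCH1", "HHIP"),
               GLI_stim = "GLI1")
  lapply(full, function(t) intersect(t, molecules))
}

#' @rdname accessors
#' @export
setMethod("molecules", "DBNStructure", function(x) x@molecules)
#' @rdname accessors
#' @export
setMethod("parentSets", "DBNStructure", function(x) x@parentSets)

#' @rdname accessors
#' @export
setMethod("edgeList", "DBNStructure", function(x) {
  from <- unlist(x@parentSets, use.names = FALSE)
  to <- rep(names(x@parentSets), lengths(x@parentSets))
  data.frame(from = as.character(from), to = as.character(to),
             stringsAsFactors = FALSE)
})

setMethod("show", "DBNStructure", function(object) {
  e <- edgeList(object)
  cat(sprintf("DBNStructure: %d molecules, %d learnable edge(s)\n",
              length(object@molecules), nrow(e)))
  cat(sprintf("  fixed wiring: %s%s\n",
              paste(vapply(names(object@stimTargets), function(s)
                sprintf("%s->{%s}", s,
                        paste(object@stimTargets[[s]], collapse = ",")),
                character(1)), collapse = " "),
              if (object@useContext) " context->all" else ""))
})

#' DBNModel: structure plus conditional probability tables
#'
#' Parameters follow the factorization of a first-order DBN: each molecule at
#' time t has a categorical distribution over \{-1,0,1\} conditional on its
#' parent configuration (molecule parents at t-1, plus fixed stimulation and
#' context parents); nodes are independent at time 0 given the fixed parents.
#'
#' @slot structure the \linkS4class{DBNStructure}.
#' @slot transition per molecule, a list with elements \code{parents}
#'   (conditioning variables, molecule parents first, then stimulation nodes,
#'   then optionally \code{"context"}), \code{cards} (their cardinalities)
#'   and \code{prob} (matrix, parent configurations x 3 child states).
#' @slot initial same layout for the time-0 distributions (conditioning on
#'   fixed parents only).
#' @export
setClass("DBNModel",
  representation(structure = "DBNStructure", transition = "list",
                 initial = "list"))

setValidity("DBNModel", function(object) {
  m <- molecules(object@structure)
  if (!identical(sort(names(object@transition)), sort(m)))
    return("transition must have one CPT per molecule")
  for (nm in m) {
    for (part in list(object@transition[[nm]], object@initial[[nm]])) {
      p <- part$prob
      if (ncol(p) != 3L) return("CPTs must have 3 child states")
      if (nrow(p) != prod(c(part$cards, 1)))
        return("CPT row count must match parent cardinalities")
      if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
        return(sprintf("CPT rows of %s must be distributions", nm))
    }
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("modelStructure", "DBNModel", function(x) x@structure)
#' @rdname accessors
#' @export
setMethod("transitionCPTs", "DBNModel", function(x) x@transition)
#' @rdname accessors
#' @export
setMethod("initialCPTs", "DBNModel", function(x) x@initial)
#' @rdname accessors
#' @export
setMethod("molecules", "DBNModel", function(x) molecules(x@structure))
#' @rdname accessors
#' @export
setMethod("parentSets", "DBNModel", function(x) parentSets(x@structure))
#' @rdname accessors
#' @export
setMethod("edgeList", "DBNModel", function(x) edgeList(x@structure))

setMethod("show", "DBNModel", function(object) {
  show(object@structure)
  ncfg <- sum(vapply(object@transition, function(z) nrow(z$prob), numeric(1)))
  cat(sprintf("  parameters: %d transition rows over %d molecules\n",
              ncfg, length(object@transition)))
})

#' TransitionCounts: sufficient statistics of a DBN given a structure
#'
#' @slot nodeCounts per molecule: \code{parents}, \code{cards} and
#'   \code{counts} (parent configurations x 3 child states).
#' @slot initialCounts same layout for time-0 states (fixed parents only).
#' @slot nTransitions total number of (t-1, t) slice pairs accumulated.
#' @slot nSeries number of input series.
#' @export
setClass("TransitionCounts",
  representation(nodeCounts = "list", initialCounts = "list",
                 nTransitions = "integer", nSeries = "integer"))

setMethod("show", "TransitionCounts", function(object) {
  cat(sprintf(
    "TransitionCounts: %d molecules, %d transitions from %d series\n",
    length(object@nodeCounts), object@nTransitions, object@nSeries))
})

#' PosteriorTable: per-target, per-time posterior state distributions
#'
#' @slot probs 3D array target x time x state (states -1, 0, 1); each
#'   target/time distribution sums to 1.
#' @export
setClass("PosteriorTable", representation(probs = "array"))

setValidity("PosteriorTable", function(object) {
  s <- apply(object@probs, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-9)) return("posterior vectors must sum to 1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("posteriorArray", "PosteriorTable", function(x) x@probs)

setMethod("show", "PosteriorTable", function(object) {
  d <- dim(object@probs)
  cat(sprintf("PosteriorTable: %d target(s) x %d time points\n", d[1], d[2]))
})

#' Convert a PosteriorTable to a long data.frame
#'
#' @param x a \linkS4class{PosteriorTable}.
#' @param row.names,optional unused, for S3 compatibility.
#' @param ... unused.
#' @return data.frame with columns node, time, p_down, p_none, p_up,
#'   map_call.
#' @export
as.data.frame.PosteriorTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  p <- x@probs
  calls <- mapState(x)
  out <- expand.grid(node = dimnames(p)[[1]], time = seq_len(dim(p)[2]),
                     stringsAsFactors = FALSE)
  out$p_down <- as.vector(p[, , 1])
  out$p_none <- as.vector(p[, , 2])
  out$p_up <- as.vector(p[, , 3])
  out$map_call <- as.vector(calls)
  out
}
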