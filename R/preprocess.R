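#' @include AllClasses.R
NULL

#' Discretization settings
#'
#' @param fdrThreshold Benjamini-Hochberg FDR cutoff separating calls of
#'   +/-1 from 0 (default 0.05).
#' @param detectionPThreshold detection p-value filter for transcript
#'   probes (default 0.01; transcript context only).
#' @param robust use the robust empirical-Bayes variance estimate (outlier
#'   variances down-weighted).
#' @param quantileNormalize quantile-normalize transcript intensities.
#' @return an object of class \code{PreprocessConfig}.
#' @export
preprocessConfig <- function(fdrThreshold = 0.05,
                             detectionPThreshold = 0.01, robust = TRUE,
                             quantileNormalize = TRUE) {
  stopifnot(fdrThreshold > 0, fdrThreshold < 1,
            detectionPThreshold > 0, detectionPThreshold < 1)
  structure(list(fdrThreshold = fdrThreshold,
                 detectionPThreshold = detectionPThreshold,
                 robust = isTRUE(robust),
                 quantileNormalize = isTRUE(quantileNormalize)),
            class = "PreprocessConfig")
}

.checkExpressionTable <- function(table) {
  need <- c("molecule", "antibody", "context", "condition", "time",
            "bio_rep", "tech_rep", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("expression table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Wide feature x sample view of one data type (protein: both compartments
# together, as compartment is part of the "group" factor; transcript alone).
.prepMatrix <- function(table, datatype,
                        config = preprocessConfig()) {
  .checkExpressionTable(table)
  ctxs <- if (datatype == "protein") c("cyt_protein", "nuc_protein")
          else "transcript"
  sub <- table[table$context %in% ctxs, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  sampKey <- paste(sub$context, sub$condition, sub$time, sub$bio_rep,
                   sub$tech_rep, sep = "|")
  samples <- unique(data.frame(key = sampKey, context = sub$context,
                               condition = sub$condition, time = sub$time,
                               bio_rep = sub$bio_rep,
                               tech_rep = sub$tech_rep,
                               stringsAsFactors = FALSE))
  samples <- samples[order(samples$key), , drop = FALSE]
  feats <- unique(sub[, c("antibody", "molecule")])
  y <- matrix(NA_real_, nrow = nrow(feats), ncol = nrow(samples),
              dimnames = list(feats$antibody, samples$key))
  y[cbind(match(sub$antibody, feats$antibody),
          match(sampKey, samples$key))] <- sub$value
  if (datatype == "transcript") {
    if (!is.null(sub$detection_p) && any(!is.na(sub$detection_p))) {
      med <- tapply(sub$detection_p, sub$antibody, stats::median,
                    na.rm = TRUE)
      keep <- names(med)[!is.na(med) & med < config$detectionPThreshold]
      feats <- feats[feats$antibody %in% keep, , drop = FALSE]
      y <- y[feats$antibody, , drop = FALSE]
      if (!nrow(y)) stop("no transcript probe passes the detection filter",
                         call. = FALSE)
    }
    if (config$quantileNormalize)
      y <- limma::normalizeBetweenArrays(y, method = "quantile")
  }
  group <- factor(paste(samples$context, samples$condition, samples$time,
                        sep = "."))
  replicate <- factor(samples$bio_rep)
  design <- if (nlevels(replicate) > 1L)
    stats::model.matrix(~ 0 + group + replicate)
  else stats::model.matrix(~ 0 + group)
  block <- factor(paste(group, samples$bio_rep))
  list(y = y, feats = feats, samples = samples, group = group,
       design = design, block = block, datatype = datatype)
}

.techBlocks <- function(samples) {
  tab <- table(paste(samples$context, samples$condition, samples$time,
                     samples$bio_rep))
  min(tab)
}

#' Within-technical-replicate correlation per molecule
#'
#' Estimates, for every molecule, the consensus correlation between
#' technical replicates within a biological replicate, via the mixed
#' linear model of \code{limma::duplicateCorrelation} applied to the
#' molecule's antibody measurements (pooled across groups).
#'
#' @param table replicate-level expression \code{data.frame} (columns
#'   molecule, antibody, context, condition, time, bio_rep, tech_rep,
#'   value).
#' @return named numeric vector of per-molecule correlations in (-1, 1).
#' @export
estimateTechCorrelation <- function(table) {
  .checkExpressionTable(table)
  mols <- unique(table$molecule)
  out <- stats::setNames(numeric(length(mols)), mols)
  for (m in mols) {
    sub <- table[table$molecule == m, , drop = FALSE]
    datatype <- if (any(sub$context == "transcript") &&
                    !any(sub$context != "transcript")) "transcript"
                else "protein"
    prep <- .prepMatrix(sub, datatype,
                        preprocessConfig(quantileNormalize = FALSE))
    if (is.null(prep) || .techBlocks(prep$samples) < 2L) {
      warning("molecule ", m,
              " has a single technical replicate; correlation set to 0")
      out[m] <- 0
      next
    }
    dc <- suppressWarnings(limma::duplicateCorrelation(
      prep$y, prep$design, block = prep$block))
    out[m] <- dc$consensus.correlation
  }
  out
}

#' Per-observation precision weights from the mean-variance trend
#'
#' Computes observation-level weights as the inverse predicted variance
#' from a lowess-type trend of residual standard deviation against mean
#' intensity (\code{limma::vooma}), fitted per data type on the
#' group+replicate design. With fewer than 10 distinct groups the trend is
#' not estimable and constant weights are returned with a warning.
#'
#' @param table replicate-level expression \code{data.frame}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return numeric vector of positive weights aligned with the rows of
#'   \code{table}.
#' @export
precisionWeights <- function(table, config = preprocessConfig()) {
  .checkExpressionTable(table)
  out <- rep(NA_real_, nrow(table))
  for (datatype in c("protein", "transcript")) {
    prep <- .prepMatrix(table, datatype, config)
    if (is.null(prep)) next
    rows <- which(table$context %in% (if (datatype == "protein")
      c("cyt_protein", "nuc_protein") else "transcript"))
    if (nlevels(prep$group) < 10L) {
      warning("fewer than 10 distinct groups for ", datatype,
              " data; using constant precision weights")
      out[rows] <- 1
      next
    }
    v <- limma::vooma(prep$y, prep$design)
    key <- paste(table$context[rows], table$condition[rows],
                 table$time[rows], table$bio_rep[rows],
                 table$tech_rep[rows], sep = "|")
    ij <- cbind(match(table$antibody[rows], rownames(prep$y)),
                match(key, colnames(prep$y)))
    out[rows] <- v$weights[ij]
  }
  out[is.na(out)] <- 1
  out
}

#' Moderated differential calls versus control
#'
#' Per antibody/probe, fits the weighted linear model with \code{group}
#' (context x condition x time) and \code{replicate} factors, using
#' precision weights from the mean-variance trend and the consensus
#' technical-replicate correlation; tests every stimulated group against
#' its time- and context-matched control with an (optionally robust)
#' empirical-Bayes moderated t-statistic; adjusts p-values by
#' Benjamini-Hochberg across all contrasts of the same data type; and
#' discretizes: \code{sign(logFC)} where \code{FDR < fdrThreshold}, else 0.
#'
#' @param table replicate-level expression \code{data.frame}.
#' @param config a \code{\link{preprocessConfig}}.
#' @return \code{data.frame} of differential calls: molecule, antibody,
#'   context, condition, time, log_fc, p_value, fdr, call.
#' @examples
#' s <- simulateStudySeries(plantedStudyModel(), T = 3, seed = 1)
#' tab <- emulateExpression(s, noiseModel(), seed = 2)
#' head(fitDifferentialCalls(tab))
#' @export
fitDifferentialCalls <- function(table, config = preprocessConfig()) {
  .checkExpressionTable(table)
  res <- list()
  for (datatype in c("protein", "transcript")) {
    prep <- .prepMatrix(table, datatype, config)
    if (is.null(prep)) next
    samples <- prep$samples
    glev <- levels(prep$group)
    # contrasts: every stimulated (context, condition, time) vs its control;
    # group columns are the first nlevels(group) design columns, in level
    # order, so contrasts are indexed by position.
    want <- unique(samples[samples$condition != "control",
                           c("context", "condition", "time")])
    cm <- matrix(0, nrow = ncol(prep$design), ncol = nrow(want),
                 dimnames = list(colnames(prep$design), NULL))
    for (k in seq_len(nrow(want))) {
      gStim <- paste(want$context[k], want$condition[k], want$time[k],
                     sep = ".")
      gCtrl <- paste(want$context[k], "control", want$time[k], sep = ".")
      if (!gCtrl %in% glev)
        stop("missing control group for ", gStim, call. = FALSE)
      cm[match(gStim, glev), k] <- 1
      cm[match(gCtrl, glev), k] <- -1
    }
    useCor <- .techBlocks(samples) >= 2L
    corr <- 0
    if (useCor) {
      dc <- suppressWarnings(limma::duplicateCorrelation(
        prep$y, prep$design, block = prep$block))
      corr <- dc$consensus.correlation
      if (!is.finite(corr)) { corr <- 0; useCor <- FALSE }
    }
    w <- NULL
    if (nlevels(prep$group) >= 10L)
      w <- limma::vooma(prep$y, prep$design)$weights
    fit <- limma::lmFit(prep$y, prep$design, weights = w,
                        block = if (useCor) prep$block else NULL,
                        correlation = if (useCor) corr else NULL)
    if (any(fit$df.residual <= 0))
      stop("zero residual degrees of freedom in the ", datatype,
           " linear model", call. = FALSE)
    eb <- limma::eBayes(limma::contrasts.fit(fit, cm),
                        robust = config$robust)
    nF <- nrow(prep$y); nC <- nrow(want)
    df <- data.frame(
      molecule = rep(prep$feats$molecule, times = nC),
      antibody = rep(prep$feats$antibody, times = nC),
      context = rep(want$context, each = nF),
      condition = rep(want$condition, each = nF),
      time = rep(want$time, each = nF),
      log_fc = as.vector(eb$coefficients),
      p_value = as.vector(eb$p.value),
      stringsAsFactors = FALSE)
    df$fdr <- stats::p.adjust(df$p_value, method = "BH")
    df$call <- ifelse(df$fdr < config$fdrThreshold,
                      sign(df$log_fc), 0)
    df$call <- as.integer(df$call)
    res[[datatype]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize antibody-level calls to one call per molecule
#'
#' The sign of the mean of the discretized antibody calls (phospho- and
#' total-protein antibodies weighted equally); an exact zero mean maps to
#' the conservative no-change call.
#'
#' @param calls differential-call \code{data.frame} from
#'   \code{\link{fitDifferentialCalls}}.
#' @return \code{data.frame} with one row per molecule x context x
#'   condition x time: molecule, context, condition, time, call.
#' @examples
#' summarizeAntibodies(data.frame(molecule = "EGFR", context = "cyt_protein",
#'   condition = "EGF", time = 1, call = c(1L, 1L, 0L)))
#' @export
summarizeAntibodies <- function(calls) {
  agg <- stats::aggregate(call ~ molecule + context + condition + time,
                          data = calls,
                          FUN = function(v) sign(mean(v)))
  agg$call <- as.integer(agg$call)
  agg[order(agg$context, agg$condition, agg$molecule, agg$time), ]
}

#' Assemble per-molecule calls into trinary time series
#'
#' One \linkS4class{TrinarySeries} per (context, condition) pair -- nine in
#' the study design -- with stimulation-node values derived from the
#' condition label and the context attached.
#'
#' @param summary molecule-level call \code{data.frame} from
#'   \code{\link{summarizeAntibodies}}.
#' @return list of \linkS4class{TrinarySeries}.
#' @export
assembleSeries <- function(summary) {
  mols <- sort(unique(summary$molecule))
  times <- sort(unique(summary$time))
  pairs <- unique(summary[, c("context", "condition")])
  pairs <- pairs[order(pairs$context, pairs$condition), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    sub <- summary[summary$context == pairs$context[k] &
                   summary$condition == pairs$condition[k], , drop = FALSE]
    m <- matrix(NA_integer_, nrow = length(mols), ncol = length(times),
                dimnames = list(mols, paste0("t", times)))
    m[cbind(match(sub$molecule, mols), match(sub$time, times))] <- sub$call
    if (anyNA(m)) {
      gaps <- which(is.na(m), arr.ind = TRUE)
      stop("incomplete time grid for ", pairs$context[k], "/",
           pairs$condition[k], ": missing ",
           paste(unique(paste(mols[gaps[, 1]], "t", times[gaps[, 2]],
                              sep = "")), collapse = ", "), call. = FALSE)
    }
    out[[length(out) + 1L]] <- trinarySeries(
      m, context = pairs$context[k], condition = pairs$condition[k])
  }
  out
}

#' Full discretization pipeline: expression table to trinary series
#'
#' Runs \code{\link{fitDifferentialCalls}},
#' \code{\link{summarizeAntibodies}} and \code{\link{assembleSeries}}.
#'
#' @param table replicate-level expression \code{data.frame}.
#' @param config a \code{\link{preprocessConfig}}.
#' @param molecules optional molecule subset for the assembled series
#'   (e.g. the network nodes, excluding background probes); default: all.
#' @return list with elements \code{calls}, \code{summary}, \code{series}.
#' @export
discretizeExpression <- function(table, config = preprocessConfig(),
                                 molecules = NULL) {
  calls <- fitDifferentialCalls(table, config)
  sm <- summarizeAntibodies(calls)
  if (!is.null(molecules))
    sm <- sm[sm$molecule %in% molecules, , drop = FALSE]
  list(calls = calls, summary = sm, series = assembleSeries(sm))
}
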