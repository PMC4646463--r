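#' @include io.R score.R evaluation.R synthetic.R preprocess.R
NULL

.defaultRunConfig <- function() {
  list(
    outdir = "dbn_run",
    seed = 1L,
    simulate = list(edgeStrength = 0.8, T = 14L, nAntibodies = 1L),
    preprocess = list(fdr = 0.05, detectionP = 0.01, robust = TRUE,
                      quantileNormalize = TRUE),
    score = list(alpha = 0.10, maxParents = 4L, selfLoops = TRUE),
    prior = list(mode = "strong", weakFactor = 2, edgeFile = NULL),
    predict = list(targets = c("GLI1", "CREB", "JUN", "p70S6K"),
                   n = 1000L, series = 1L),
    validate = list(n = 1000L),
    bootstrap = list(b = 100L, cutoff = 0.5))
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      .mergeConfig(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Load a pipeline run configuration
#'
#' @param file YAML (or JSON) configuration file; missing entries fall back
#'   to defaults.
#' @return nested configuration list.
#' @export
readRunConfig <- function(file = NULL) {
  cfg <- .defaultRunConfig()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file,
                                 call. = FALSE)
    cfg <- .mergeConfig(cfg, yaml::read_yaml(file))
  }
  cfg
}

.need <- function(path, stage, neededBy) {
  if (!file.exists(path))
    stop(sprintf("stage '%s' requires %s; run stage '%s' first", neededBy,
                 path, stage), call. = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Chains the stages simulate -> discretize -> learn -> predict ->
#' validate -> bootstrap on disk artifacts under \code{config$outdir}.
#' Every output carries a provenance comment (stage, seed, config hash),
#' and one global seed deterministically spawns per-stage substreams so
#' stages can be re-run independently.
#'
#' @param config configuration list (see \code{\link{readRunConfig}}) or a
#'   path to a YAML file.
#' @param stages ordered subset of
#'   \code{c("simulate","discretize","learn","predict","validate",
#'   "bootstrap")}.
#' @return (invisibly) named list of artifact paths produced.
#' @export
runPipeline <- function(config = readRunConfig(),
                        stages = c("simulate", "discretize", "learn",
                                   "predict", "validate", "bootstrap")) {
  if (is.character(config)) config <- readRunConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$outdir, f)
  seed <- as.integer(config$seed)
  sc <- scoreConfig(config$score$alpha, config$score$maxParents,
                    config$score$selfLoops)
  edges <- if (is.null(config$prior$edgeFile)) defaultLiteratureEdges()
           else defaultLiteratureEdges(config$prior$edgeFile)
  pk <- priorKnowledge(config$prior$mode, edges, config$prior$weakFactor)
  artifacts <- list()
  for (stage in stages) {
    sseed <- .childSeed(seed, match(stage, c("simulate", "discretize",
                                             "learn", "predict",
                                             "validate", "bootstrap")))
    hdr <- .provHeader(stage, seed,
                       config[setdiff(names(config), "outdir")])
    switch(stage,
      simulate = {
        model <- plantedStudyModel(config$simulate$edgeStrength)
        ser <- simulateStudySeries(model, T = config$simulate$T,
                                   seed = sseed)
        tab <- emulateExpression(ser, noiseModel(),
                                 seed = .childSeed(sseed, 1),
                                 nAntibodies = config$simulate$nAntibodies)
        writeExpressionTable(tab, pth("expression.tsv"), hdr)
        writeTrinarySeriesSet(ser, pth("truth_series.tsv"), hdr)
        artifacts$expression <- pth("expression.tsv")
      },
      discretize = {
        tab <- readExpressionTable(.need(pth("expression.tsv"), "simulate",
                                         stage))
        pc <- preprocessConfig(config$preprocess$fdr,
                               config$preprocess$detectionP,
                               config$preprocess$robust,
                               config$preprocess$quantileNormalize)
        res <- discretizeExpression(tab, pc)
        writeExpressionTable(res$calls, pth("differential_calls.tsv"), hdr)
        writeTrinarySeriesSet(res$series, pth("series.tsv"), hdr)
        artifacts$series <- pth("series.tsv")
      },
      learn = {
        ser <- readTrinarySeriesSet(.need(pth("series.tsv"), "discretize",
                                          stage))
        model <- fitDBN(ser, sc, pk)
        writeStructureSIF(modelStructure(model), pth("structure.sif"), hdr)
        writeModelJSON(model, pth("model.json"))
        artifacts$model <- pth("model.json")
      },
      predict = {
        model <- readModelJSON(.need(pth("model.json"), "learn", stage))
        ser <- readTrinarySeriesSet(.need(pth("series.tsv"), "discretize",
                                          stage))
        s <- ser[[config$predict$series]]
        hid <- stateMatrix(s)
        hid[config$predict$targets, ] <- NA
        ev <- trinarySeries(hid, seriesContext(s), seriesCondition(s),
                            stimAssignment(s))
        post <- predictPosterior(model, ev,
                                 targets = config$predict$targets,
                                 N = config$predict$n, seed = sseed)
        writeExpressionTable(as.data.frame(post), pth("posterior.tsv"),
                             hdr)
        artifacts$posterior <- pth("posterior.tsv")
      },
      validate = {
        ser <- readTrinarySeriesSet(.need(pth("series.tsv"), "discretize",
                                          stage))
        val <- looValidate(ser, sc, pk, targets = config$predict$targets,
                           N = config$validate$n, seed = sseed)
        writeExpressionTable(val, pth("validation.tsv"), hdr)
        artifacts$validation <- pth("validation.tsv")
      },
      bootstrap = {
        ser <- readTrinarySeriesSet(.need(pth("series.tsv"), "discretize",
                                          stage))
        freqs <- parametricBootstrap(ser, sc, pk, B = config$bootstrap$b,
                                     seed = sseed)
        writeExpressionTable(freqs, pth("edge_frequencies.tsv"), hdr)
        stable <- stableEdges(freqs, config$bootstrap$cutoff)
        writeExpressionTable(stable, pth("stable_edges.tsv"), hdr)
        writeEdgesDOT(stable, pth("stable_edges.dot"))
        artifacts$edge_frequencies <- pth("edge_frequencies.tsv")
      })
  }
  invisible(artifacts)
}
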