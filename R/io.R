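#' @include AllClasses.R
NULL

.provHeader <- function(stage, seed, config = NULL) {
  sprintf("# dbnCrosstalk stage=%s seed=%s config=%s", stage,
          if (is.null(seed)) "NA" else seed,
          .fnvHash(config))
}

#' Read / write replicate-level expression tables (TSV)
#'
#' Plain tab-separated files with columns molecule, antibody, context,
#' condition, time, bio_rep, tech_rep, value, detection_p; lines starting
#' with \code{#} are provenance comments.
#'
#' @param file path.
#' @param table expression \code{data.frame}.
#' @param header optional provenance comment line(s) written on top.
#' @return \code{readExpressionTable}: the \code{data.frame}.
#' @export
readExpressionTable <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname readExpressionTable
#' @export
writeExpressionTable <- function(table, file, header = NULL) {
  con <- file(file, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read / write sets of trinary series (TSV with metadata headers)
#'
#' Each series is stored as a metadata block (\code{#% key value} lines for
#' context, condition and stimulation values) followed by a molecule x time
#' state matrix; series are separated by blank lines.
#'
#' @param seriesSet list of \linkS4class{TrinarySeries}.
#' @param file path.
#' @param header optional provenance comment line(s).
#' @return \code{readTrinarySeriesSet}: list of
#'   \linkS4class{TrinarySeries}.
#' @export
writeTrinarySeriesSet <- function(seriesSet, file, header = NULL) {
  con <- file(file, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  for (s in seriesSet) {
    writeLines(sprintf("#%% context %s", seriesContext(s)), con)
    writeLines(sprintf("#%% condition %s", seriesCondition(s)), con)
    writeLines(sprintf("#%% stim %s",
                       paste(names(stimAssignment(s)), stimAssignment(s),
                             sep = "=", collapse = " ")), con)
    m <- stateMatrix(s)
    writeLines(paste(c("molecule", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con)
    writeLines("", con)
  }
  invisible(file)
}

#' @rdname writeTrinarySeriesSet
#' @export
readTrinarySeriesSet <- function(file) {
  ln <- readLines(file)
  ln <- ln[!grepl("^#($|[^%])", ln) & !grepl("^# ", ln)]
  out <- list(); meta <- list(); rows <- list(); cn <- NULL
  flush <- function() {
    if (!length(rows)) return(invisible(NULL))
    m <- do.call(rbind, lapply(rows, function(r)
      suppressWarnings(as.integer(r[-1]))))
    rownames(m) <- vapply(rows, `[`, character(1), 1L)
    colnames(m) <- cn
    stim <- NULL
    if (!is.null(meta$stim)) {
      kv <- strsplit(strsplit(meta$stim, " ")[[1]], "=")
      stim <- stats::setNames(vapply(kv, function(z) as.integer(z[2]),
                                     integer(1)),
                              vapply(kv, `[`, character(1), 1L))
    }
    out[[length(out) + 1L]] <<- trinarySeries(
      m, context = meta$context, condition = meta$condition, stim = stim)
    meta <<- list(); rows <<- list(); cn <<- NULL
    invisible(NULL)
  }
  for (l in ln) {
    if (startsWith(l, "#%")) {
      kv <- strsplit(sub("^#% *", "", l), " ")[[1]]
      meta[[kv[1]]] <- paste(kv[-1], collapse = " ")
    } else if (!nzchar(trimws(l))) {
      flush()
    } else if (startsWith(l, "molecule")) {
      cn <- strsplit(l, "\t")[[1]][-1]
    } else {
      rows[[length(rows) + 1L]] <- strsplit(l, "\t")[[1]]
    }
  }
  flush()
  out
}

#' Write a DBN structure as a SIF-like edge list
#'
#' Learnable edges as \code{parent<TAB>-><TAB>child} lines, preceded by a
#' node-metadata comment block (molecules, fixed wiring, context levels).
#'
#' @param structure a \linkS4class{DBNStructure}.
#' @param file path.
#' @param header optional provenance comment line(s).
#' @export
writeStructureSIF <- function(structure, file, header = NULL) {
  con <- file(file, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(sprintf("# molecules: %s",
                     paste(molecules(structure), collapse = " ")), con)
  for (sn in names(structure@stimTargets))
    writeLines(sprintf("# fixed: %s -> %s", sn,
                       paste(structure@stimTargets[[sn]], collapse = " ")),
               con)
  if (structure@useContext)
    writeLines(sprintf("# fixed: context -> * (levels: %s)",
                       paste(structure@contextLevels, collapse = " ")), con)
  el <- edgeList(structure)
  for (i in seq_len(nrow(el)))
    writeLines(paste(el$from[i], "->", el$to[i], sep = "\t"), con)
  invisible(file)
}

#' Serialize / restore a DBN model as JSON
#'
#' Structure and conditional probability tables keyed by node and parent
#' configuration.
#'
#' @param model a \linkS4class{DBNModel}.
#' @param file path.
#' @return \code{readModelJSON}: the restored \linkS4class{DBNModel}.
#' @export
writeModelJSON <- function(model, file) {
  s <- model@structure
  obj <- list(
    molecules = s@molecules, parentSets = s@parentSets,
    stimTargets = s@stimTargets, contextLevels = s@contextLevels,
    useContext = s@useContext,
    transition = lapply(model@transition, function(z)
      list(parents = z$parents, cards = z$cards, prob = z$prob)),
    initial = lapply(model@initial, function(z)
      list(parents = z$parents, cards = z$cards, prob = z$prob)))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  fixPS <- function(x) lapply(x, function(v) as.character(unlist(v)))
  struct <- dbnStructure(
    molecules = obj$molecules, parentSets = fixPS(obj$parentSets),
    stimTargets = fixPS(obj$stimTargets),
    contextLevels = obj$contextLevels, useContext = obj$useContext)
  fixCPT <- function(x) lapply(x, function(z)
    list(parents = as.character(unlist(z$parents)),
         cards = as.integer(unlist(z$cards)),
         prob = matrix(as.numeric(z$prob), ncol = 3L)))
  new("DBNModel", structure = struct,
      transition = fixCPT(obj$transition)[struct@molecules],
      initial = fixCPT(obj$initial)[struct@molecules])
}

#' Export stable edges as a Graphviz DOT file
#'
#' @param edges \code{data.frame} with from, to, freq (e.g. from
#'   \code{\link{stableEdges}}).
#' @param file path.
#' @param dropSelfLoops omit self-loops from the display (default TRUE).
#' @export
writeEdgesDOT <- function(edges, file, dropSelfLoops = TRUE) {
  if (dropSelfLoops) edges <- edges[edges$from != edges$to, , drop = FALSE]
  con <- file(file, "w"); on.exit(close(con))
  writeLines("digraph dbn {", con)
  for (i in seq_len(nrow(edges)))
    writeLines(sprintf('  "%s" -> "%s" [label="%.2f"];', edges$from[i],
                       edges$to[i], edges$freq[i]), con)
  writeLines("}", con)
  invisible(file)
}
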