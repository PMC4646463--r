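# Internal helpers: state coding, mixed-radix configuration indexing,
# vectorised categorical sampling, seed handling.

# Trinary states are -1/0/1 in all user-facing objects; internally they are
# indexed 1..3. Stimulation nodes are 0/1, indexed 1..2.

STATE_VALUES <- c(-1L, 0L, 1L)

.stateToIdx <- function(x) {
  idx <- x + 2L
  if (any(idx < 1L | idx > 3L, na.rm = TRUE))
    stop("trinary states must lie in {-1, 0, 1}", call. = FALSE)
  idx
}

.idxToState <- function(i) i - 2L

#' @noRd
# Mixed-radix index: values is a matrix (rows = observations, cols = factors)
# with entries in 1..cards[k]; returns 1-based configuration index where the
# FIRST column varies fastest.
.cfgIndex <- function(values, cards) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (ncol(values) == 0L) return(rep(1L, nrow(values)))
  mult <- cumprod(c(1L, cards[-length(cards)]))
  as.integer(1L + as.vector((values - 1L) %*% mult))
}

# Enumerate all configurations for the given cardinalities as a matrix
# (rows = configs in .cfgIndex order, cols = factors).
.cfgGrid <- function(cards) {
  if (length(cards) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  g <- do.call(expand.grid, lapply(cards, seq_len))
  as.matrix(g)
}

# Vectorised categorical draw: prob is an n x k matrix of row distributions;
# returns integer vector in 1..k. Rows need not be exactly normalised.
.sampleRows <- function(prob) {
  cs <- prob
  k <- ncol(prob)
  if (k > 1L) for (j in 2:k) cs[, j] <- cs[, j] + cs[, j - 1L]
  u <- stats::runif(nrow(prob)) * cs[, k]
  out <- rep(1L, nrow(prob))
  for (j in 1:(k - 1L)) out <- out + (u > cs[, j])
  as.integer(out)
}

# Derive a reproducible child seed (kept below 2^31).
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1009 + 12345) %% 2147483587L)
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Tiny FNV-1a hash for provenance headers (no external digest dependency).
.fnvHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
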