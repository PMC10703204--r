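# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seeded operations in the package go
# through this so that user-session RNG state is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and one or more stream indices,
# keeping the result in [0, 2^31 - 2]. Splitmix-style integer mixing on
# doubles (exact below 2^53) so derived streams are decorrelated.
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed)
  for (k in as.numeric(c(...))) {
    x <- (x * 69069 + k * 12345 + 1) %% 2147483647
  }
  as.integer(x)
}

# log(sum(exp(x))) with the usual max shift; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Maximal runs of TRUE in a logical vector, as a matrix with half-open
# [start, end) 0-based columns. Zero-row matrix when no TRUE present.
runs_true <- function(mask) {
  stopifnot(is.logical(mask))
  n <- length(mask)
  if (n == 0L || !any(mask)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Fill FALSE-gaps of length <= max_gap that lie strictly between TRUE runs.
close_gaps <- function(mask, max_gap) {
  if (max_gap <= 0L || !any(mask)) return(mask)
  r <- rle(mask)
  n_runs <- length(r$values)
  if (n_runs >= 3L) {
    for (i in seq(2L, n_runs - 1L)) {
      if (!r$values[i] && r$lengths[i] <= max_gap) r$values[i] <- TRUE
    }
  }
  inverse.rle(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
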