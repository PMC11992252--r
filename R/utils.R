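# Internal helpers shared across modules.

# Set the RNG seed for the calling frame only; global RNG state is restored
# when the caller exits. seed = NULL leaves the RNG untouched.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  expr <- if (has_seed) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

# Derive a deterministic child seed from a parent seed and an index
# (double arithmetic: products exceed integer range long before 2^53).
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

clip_r <- function(r, eps = 1e-6) pmin(pmax(r, -1 + eps), 1 - eps)

# Fisher z-average of correlation coefficients, back-transformed to r.
fisher_mean <- function(r, na.rm = TRUE) {
  r <- clip_r(r)
  if (na.rm) r <- r[!is.na(r)]
  if (length(r) == 0) return(NA_real_)
  tanh(mean(atanh(r)))
}

# Centered running mean over +/- half_window frames, truncated at the edges.
running_mean <- function(x, half_window) {
  n <- length(x)
  if (half_window <= 0) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_window, 1L)
  hi <- pmin(seq_len(n) + half_window, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Maximal runs of TRUE in a logical vector, as a 2-column matrix of
# inclusive 1-based [start, end] frame indices.
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# Keep only TRUE runs of at least min_len frames; returns logical mask.
filter_runs <- function(mask, min_len) {
  r <- rle(as.logical(mask))
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
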