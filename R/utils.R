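# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Centered moving average with shrinking windows at the edges, so the
# output has the same length as the input and no NA padding.
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window <= 1L || n < 3L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# The seven whistle parameters, in reporting order.
feature_names <- function() {
  c("min_freq", "max_freq", "start_freq", "end_freq",
    "freq_range", "n_inflections", "duration")
}
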