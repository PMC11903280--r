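# Internal helpers shared across modules.

# Run `expr` under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1) # materialize a RNG state so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vg <- function(..., call. = FALSE) stop(..., call. = call.)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_vg(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower || x > upper || (open_upper && x == upper)) {
    stop_vg(sprintf(
      "'%s' = %g outside allowed range [%g, %g%s", name, x, lower, upper,
      if (open_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# Local extrema with a minimum index spacing; greedy suppression keeps the
# most extreme candidates first (ties broken by earlier index).
find_peaks <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

find_troughs <- function(x, min_dist = 1L) find_peaks(-x, min_dist)
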