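# Shared fixtures built in code.

# one default noiseless walk, reused across test files
default_walk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_walk(walker_spec())
    }
    cache
  }
})

# match every detected event to the nearest same-side/kind ground-truth
# event; returns signed frame errors
event_errors <- function(events, truth_events) {
  vapply(seq_len(nrow(events)), function(j) {
    g <- truth_events$frame[truth_events$side == events$side[j] &
                              truth_events$kind == events$kind[j]]
    events$frame[j] - g[which.min(abs(g - events$frame[j]))]
  }, numeric(1))
}

# ground-truth events detectable away from the trial boundaries
interior_truth <- function(truth_events, n_frames, margin = 20L) {
  truth_events[truth_events$frame > margin &
                 truth_events$frame <= n_frames - margin, ]
}

# adjusted Rand index (independent implementation for cluster tests)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- ai * bj / n2
  max_idx <- (ai + bj) / 2
  if (max_idx == exp_idx) return(1)
  (nij - exp_idx) / (max_idx - exp_idx)
}
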