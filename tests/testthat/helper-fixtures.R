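# Shared fixtures and independent oracles for the test suite.

# Brute-force DTW oracle: exhaustive recursion over all monotone,
# boundary-anchored warping paths (no memoization — deliberately
# independent of the dynamic-programming implementation).
bf_dtw <- function(a, b) {
  n <- length(a)
  m <- length(b)
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == n && j == m) return(cost)
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    cost + best
  }
  rec(1, 1)
}

# Literal, self-contained trace of the voting stage, written directly
# from the extraction rules as an independent check on vote_d_values.
trace_vote <- function(d) {
  n_d <- length(d)
  thr <- sum(d) / n_d
  flags <- c()
  for (j in seq_len(n_d)) {
    if (j >= 3 && j <= n_d - 2) {
      win <- d[(j - 2):(j + 2)]
      if (sum(win > thr) >= 3) flags <- c(flags, j)
    } else if (d[j] > thr) {
      flags <- c(flags, j)
    }
  }
  sort(unique(c(flags, flags + 1)))
}

# Session-cached datasets so expensive simulations run once per test run.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

small_dataset <- function() {
  cached("small", generate_dataset(
    sim_config(n_participants = 2, n_trials = 2, seed = 7)))
}

# the classification study scale used by the heavier experiments
study_dataset <- function() {
  cached("study", generate_dataset(
    sim_config(n_participants = 8, n_trials = 2, seed = 42)))
}

study_segments <- function() {
  cached("study_segs", segment_recordings(study_dataset()))
}

study_segments_noext <- function() {
  cached("study_segs_noext",
         segment_recordings(study_dataset(), use_vbdtw = FALSE))
}

# full study-design-sized dataset (13 x 5)
default_dataset <- function() {
  cached("default", generate_dataset(sim_config()))
}

# fast training profile used across classification tests
fast_config <- function(family, n_channels, input_len,
                        n_classes = 14, epochs = 10) {
  classifier_config(family, input_channels = n_channels,
                    input_len = input_len, n_classes = n_classes,
                    lr = 2e-3, batch_size = 128, epochs = epochs)
}
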