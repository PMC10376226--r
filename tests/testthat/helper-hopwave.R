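# Small, fast configurations shared across test files.

tiny_config <- function(seed = 1, ...) {
  simulation_config(n_aclr = 2, n_control = 2, trials_per_limb = 1,
                    phase_durations = c(0.30, 0.20, 0.10),
                    pre_duration = 0.5, tail_duration = 0.15,
                    seed = seed, ...)
}

clean_config <- function(seed = 1, ...) {
  tiny_config(seed = seed, noise_sd = 0, line_amplitude = 0, ...)
}

# One small conditioned trial plus its events, cached per session.
cached_tiny_trial <- local({
  env <- new.env()
  function() {
    if (is.null(env$tr)) {
      tr <- generate_trial(tiny_config(seed = 11), "ACLR", "index", "A01", 1)
      env$tr <- condition_trial(tr)
      env$ev <- segment_trial(env$tr)
      env$raw <- tr
    }
    list(trial = env$tr, events = env$ev, raw = env$raw)
  }
})

# Tiny cohort pattern table (2+2 subjects, 2 trials/limb), cached.
cached_tiny_patterns <- local({
  env <- new.env()
  function() {
    if (is.null(env$cp)) {
      cfg <- simulation_config(n_aclr = 2, n_control = 2, trials_per_limb = 2,
                               phase_durations = c(0.30, 0.20, 0.10),
                               pre_duration = 0.5, tail_duration = 0.15,
                               effect_size = 2, seed = 42)
      env$cp <- cohort_patterns(generate_cohort(cfg))
    }
    env$cp
  }
})

# Independent brute-force 1-NN LOOCV oracle: plain double loop, first-index
# tie-break, trial-level holdout.
brute_knn_loocv <- function(features, labels) {
  n <- nrow(features)
  correct <- 0L
  for (i in seq_len(n)) {
    best <- Inf
    best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((features[i, ] - features[j, ])^2))
      if (d < best) {
        best <- d
        best_j <- j
      }
    }
    if (labels[best_j] == labels[i]) correct <- correct + 1L
  }
  c(correct = correct, total = n)
}

rms <- function(x) sqrt(mean(x^2))

# middle portion of a series, away from any edge transient
mid <- function(x, frac = 0.5) {
  n <- length(x)
  k <- floor(n * (1 - frac) / 2)
  x[(k + 1):(n - k)]
}
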