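#' Time-normalize an intensity map to 100 frames per hop phase
#'
#' Each hop phase (`[t0, t1)`, `[t1, t2)`, `[t2, t3]`) is resampled to
#' `frames_per_phase` frames by linear interpolation over normalized phase
#' time, endpoints inclusive, and the phases are concatenated: 300 frames per
#' band under the default.
#'
#' @param map A `hop_intensity` (or bands x time matrix).
#' @param events A `hop_events` (or list with `t0`..`t3`).
#' @param frames_per_phase Frames per phase (default 100).
#' @return A bands x (3 * frames_per_phase) matrix.
#' @export
time_normalize <- function(map, events, frames_per_phase = 100) {
  v <- if (inherits(map, "hop_intensity")) map$values else map
  ph <- list(c(events$t0, events$t1 - 1L), c(events$t1, events$t2 - 1L),
             c(events$t2, events$t3))
  if (any(vapply(ph, function(b) b[2] - b[1] + 1, numeric(1)) < 2)) {
    stop("time_normalize: degenerate phase with fewer than 2 samples",
         call. = FALSE)
  }
  if (events$t3 > ncol(v)) {
    stop("time_normalize: events exceed the record length", call. = FALSE)
  }
  grid <- seq(0, 1, length.out = frames_per_phase)
  blocks <- lapply(ph, function(b) {
    idx <- b[1]:b[2]
    L <- length(idx)
    # fractional positions of the output grid on the phase's sample axis
    pos <- 1 + grid * (L - 1)
    lo <- pmin(floor(pos), L - 1)
    w <- pos - lo
    sub <- v[, idx, drop = FALSE]
    sub[, lo, drop = FALSE] * rep(1 - w, each = nrow(v)) +
      sub[, lo + 1, drop = FALSE] * rep(w, each = nrow(v))
  })
  do.call(cbind, blocks)
}

#' Z-normalize a pattern per wavelet band
#'
#' Subtracts each band's mean over all frames and divides by its standard
#' deviation, removing baseline intensity differences between subjects. A
#' zero-variance band cannot be normalized: it is set to all zeros and a
#' warning is recorded (and emitted).
#'
#' @param mat Bands x frames matrix.
#' @return Matrix of the same shape, per-band mean 0 and SD 1; degenerate
#'   band indices in attribute `degenerate_bands`.
#' @export
z_normalize <- function(mat) {
  out <- mat
  degen <- integer(0)
  for (b in seq_len(nrow(mat))) {
    s <- sd(mat[b, ])
    if (!is.finite(s) || s == 0) {
      out[b, ] <- 0
      degen <- c(degen, b)
    } else {
      out[b, ] <- (mat[b, ] - mean(mat[b, ])) / s
    }
  }
  if (length(degen)) {
    warning(sprintf("z_normalize: zero-variance band(s) %s set to zero",
                    paste(degen, collapse = ", ")), call. = FALSE)
  }
  attr(out, "degenerate_bands") <- degen
  out
}

#' Compute the normalized wavelet pattern of one muscle in one trial
#'
#' Convenience composition: wavelet intensity of the (conditioned) channel,
#' time-normalization to 100 frames per phase, then per-band z-normalization.
#' The result is invariant to the overall EMG gain of the trial.
#'
#' @param trial A conditioned `hop_trial`.
#' @param muscle Channel name.
#' @param events A `hop_events`; segmented from the trial when `NULL`.
#' @param bank A [wavelet_bank()].
#' @param frames_per_phase Frames per phase (default 100).
#' @return A `hop_pattern`: bands x 300 matrix with attributes `muscle`,
#'   `band_freqs`, `phase_boundaries` (frame indices 0/100/200/300) and
#'   provenance labels.
#' @export
trial_pattern <- function(trial, muscle, events = NULL, bank = wavelet_bank(),
                          frames_per_phase = 100) {
  stopifnot(muscle %in% MUSCLES)
  if (is.null(events)) events <- segment_trial(trial)
  im <- wavelet_intensity(trial$signals[[muscle]], bank, trial$fs_emg, muscle)
  m <- z_normalize(time_normalize(im, events, frames_per_phase))
  structure(m, class = c("hop_pattern", "matrix"),
            muscle = muscle, band_freqs = bank$central_freqs,
            phase_boundaries = c(0, frames_per_phase, 2 * frames_per_phase,
                                 3 * frames_per_phase),
            subject_id = trial$subject_id, group = trial$group,
            limb = trial$limb, trial = trial$trial)
}

#' Normalized patterns for every muscle of every trial in a cohort
#'
#' Runs the full chain - conditioning, segmentation, wavelet intensity,
#' time- and z-normalization - over a cohort and returns one row per trial
#' and muscle, with the 14 x 300 pattern in a list-column. This tibble is the
#' input to [run_comparisons()] and [average_patterns()].
#'
#' @param cohort A `hop_cohort` (or bare list of `hop_trial`s).
#' @param bank A [wavelet_bank()].
#' @param spec A [filter_spec()].
#' @param condition Condition trials first (default TRUE).
#' @return Tibble: `subject_id`, `group`, `limb`, `trial`, `muscle`,
#'   `pattern` (list of matrices).
#' @export
cohort_patterns <- function(cohort, bank = wavelet_bank(),
                            spec = filter_spec(), condition = TRUE) {
  trials <- if (inherits(cohort, "hop_cohort")) cohort$trials else cohort
  fpp <- 100
  rows <- purrr::map(trials, function(tr) {
    if (condition) tr <- condition_trial(tr, spec)
    ev <- segment_trial(tr)
    ims <- wavelet_intensity_multi(as.matrix(tr$signals[MUSCLES]), bank,
                                   tr$fs_emg)
    pats <- lapply(seq_along(MUSCLES), function(i) {
      m <- z_normalize(time_normalize(ims[[i]], ev, fpp))
      structure(m, class = c("hop_pattern", "matrix"),
                muscle = MUSCLES[i], band_freqs = bank$central_freqs,
                phase_boundaries = c(0, fpp, 2 * fpp, 3 * fpp),
                subject_id = tr$subject_id, group = tr$group,
                limb = tr$limb, trial = tr$trial)
    })
    tibble::tibble(subject_id = tr$subject_id, group = tr$group,
                   limb = tr$limb, trial = tr$trial, muscle = MUSCLES,
                   pattern = pats)
  })
  dplyr::bind_rows(rows)
}

#' Average normalized patterns within groups
#'
#' Frame-and-band-wise arithmetic mean of patterns sharing the grouping keys
#' (for example group x limb x muscle), as used for visualization of average
#' muscle activity maps.
#'
#' @param patterns Tibble from [cohort_patterns()].
#' @param by Character vector of grouping columns (default
#'   `c("group", "limb", "muscle")`).
#' @return Tibble with the grouping keys, `n` (patterns averaged) and the
#'   mean `pattern` list-column.
#' @export
average_patterns <- function(patterns, by = c("group", "limb", "muscle")) {
  stopifnot(all(by %in% names(patterns)), nrow(patterns) > 0)
  patterns |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      pattern = list(Reduce(`+`, .data$pattern) / dplyr::n()),
      .groups = "drop"
    )
}

#' Export a pattern map to CSV
#'
#' Writes the pattern in long form - band index, band central frequency,
#' frame, hop phase, raw normalized value, and a min-max `[0, 1]` rescaled
#' display copy (all zeros for a constant pattern, by convention). Phase
#' boundaries are recoverable from the `phase` column (frames 1-100, 101-200,
#' 201-300).
#'
#' @param pattern A `hop_pattern` (or bands x frames matrix).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_map <- function(pattern, path) {
  m <- unclass(pattern)
  attrs <- attributes(pattern)
  fpp <- (attrs$phase_boundaries %||% c(0, ncol(m) / 3, 2 * ncol(m) / 3, ncol(m)))[2]
  rng <- range(m)
  scaled <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
  bf <- attrs$band_freqs %||% rep(NA_real_, nrow(m))
  df <- data.frame(
    band = rep(seq_len(nrow(m)), times = ncol(m)),
    band_hz = rep(bf, times = ncol(m)),
    frame = rep(seq_len(ncol(m)), each = nrow(m)),
    phase = rep(c("take-off", "airborne", "landing")[
      pmin(3, ((seq_len(ncol(m)) - 1) %/% fpp) + 1)], each = nrow(m)),
    value = as.vector(m),
    value_scaled = as.vector(scaled)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pattern map written by [export_map()]
#'
#' @param path CSV path.
#' @return A bands x frames matrix of the raw normalized values, with
#'   `band_freqs` attribute.
#' @export
read_map <- function(path) {
  df <- read.csv(path)
  need <- c("band", "frame", "value")
  if (!all(need %in% names(df))) {
    stop("read_map: not a pattern map file", call. = FALSE)
  }
  nb <- max(df$band)
  nf <- max(df$frame)
  m <- matrix(NA_real_, nb, nf)
  m[cbind(df$band, df$frame)] <- df$value
  attr(m, "band_freqs") <- df$band_hz[match(seq_len(nb), df$band)]
  m
}
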