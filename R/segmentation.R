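#' Detect ground contact from vertical ground reaction force
#'
#' Contact (t2) is the first sample at which the force exceeds `threshold`
#' (50 N by default) coming from below, searching after an unloaded interval
#' of at least `min_unloaded` consecutive at-or-below-threshold samples.
#'
#' @param vgrf Vertical ground reaction force, N, on the EMG clock.
#' @param threshold Contact threshold, N.
#' @param min_unloaded Minimum length (samples) of the unloaded run preceding
#'   the crossing; 1 accepts any upward crossing.
#' @return 1-based sample index of the first exceedance.
#' @examples
#' detect_t2(c(0, 0, 30, 60, 200))  # 4: the 60 N sample
#' @export
detect_t2 <- function(vgrf, threshold = 50, min_unloaded = 1L) {
  n <- length(vgrf)
  if (n < 2) stop("detect_t2: force series too short", call. = FALSE)
  up <- which(vgrf[-1] > threshold & vgrf[-n] <= threshold) + 1L
  if (length(up) == 0) {
    stop("detect_t2: no crossing of the contact threshold found", call. = FALSE)
  }
  below <- vgrf <= threshold
  for (i in up) {
    run <- 0L
    k <- i - 1L
    while (k >= 1L && below[k]) {
      run <- run + 1L
      k <- k - 1L
    }
    if (run >= min_unloaded) return(i)
  }
  stop("detect_t2: no crossing preceded by an unloaded interval", call. = FALSE)
}

#' Detect peak landing force
#'
#' Peak force (t3) is the maximum of the landing transient at or after
#' contact; the first index attains it if flat-topped. A series that never
#' falls after `t2` (monotone or flat) has no landing peak and is an error.
#'
#' @param vgrf Vertical ground reaction force, N.
#' @param t2 Contact sample index from [detect_t2()].
#' @return 1-based sample index of the landing peak.
#' @export
detect_t3 <- function(vgrf, t2) {
  n <- length(vgrf)
  stopifnot(t2 >= 1, t2 <= n)
  seg <- vgrf[t2:n]
  if (length(seg) < 3) stop("detect_t3: landing segment too short", call. = FALSE)
  i <- which.max(seg)
  if (i == length(seg) || all(seg == seg[1])) {
    stop("detect_t3: force does not fall after contact; no landing peak",
         call. = FALSE)
  }
  t2 + i - 1L
}

#' Detect take-off from ankle vertical velocity
#'
#' Take-off (t1) is the minimum of the ankle vertical velocity strictly
#' before the motion-capture image of ground contact, mapped back to the EMG
#' clock with the rounded rate ratio (24 samples per mocap frame under the
#' default rates).
#'
#' @param ankle_vz Ankle vertical velocity, m/s, on the mocap clock.
#' @param t2 Contact index on the EMG clock.
#' @param fs_emg,fs_mocap Sampling rates, Hz.
#' @return 1-based EMG-clock sample index of the velocity minimum.
#' @export
detect_t1 <- function(ankle_vz, t2, fs_emg = 3000, fs_mocap = 125) {
  ratio <- round(fs_emg / fs_mocap)
  m2 <- floor((t2 - 1) / ratio) + 1L        # last mocap sample at/before t2
  if (m2 < 2) stop("detect_t1: empty pre-contact window", call. = FALSE)
  w <- seq_len(min(m2 - 1L, length(ankle_vz)))
  m1 <- which.min(ankle_vz[w])
  as.integer((m1 - 1L) * ratio + 1L)
}

#' Detect movement onset from EMG activity and knee flexion
#'
#' Movement onset (t0) requires both channels to depart their quiet-standing
#' baselines: the EMG activity series must exceed `baseline mean +
#' k_sd * baseline SD` (plus a small relative floor guarding degenerate
#' zero-noise baselines) for a sustained run of at least `sustain_s`, and the
#' knee flexion must depart its static value by more than `k_sd` baseline SDs
#' (plus `flex_floor` degrees). Within the sustained EMG run the onset is
#' backtracked to the first sample above the statistical threshold alone, so
#' noise-free onsets are recovered exactly. The reported t0 is the later of
#' the two channel-wise onsets, on the EMG clock.
#'
#' @param activity Nonnegative EMG activity series on the EMG clock (e.g., a
#'   rectified moving-average amplitude, or a total wavelet intensity).
#' @param knee_flexion Knee flexion, degrees, on the mocap clock.
#' @param fs_emg,fs_mocap Sampling rates, Hz.
#' @param baseline_s Length of the quiet baseline window, seconds.
#' @param k_sd Threshold in baseline standard deviations (default 3).
#' @param sustain_s Minimum suprathreshold run, seconds (default 0.025).
#' @param rel_floor Relative floor as a fraction of the series maximum
#'   (default 0.02), so an all-quiet series cannot trigger.
#' @param flex_floor Absolute flexion departure floor, degrees.
#' @return 1-based EMG-clock sample index of movement onset.
#' @export
detect_t0 <- function(activity, knee_flexion, fs_emg = 3000, fs_mocap = 125,
                      baseline_s = 0.3, k_sd = 3, sustain_s = 0.025,
                      rel_floor = 0.02, flex_floor = 0.5) {
  nb <- round(baseline_s * fs_emg)
  if (nb < 2 || nb >= length(activity)) {
    stop("detect_t0: no quiet baseline window available", call. = FALSE)
  }
  mu <- mean(activity[seq_len(nb)])
  s <- sd(activity[seq_len(nb)])
  thr_run <- mu + k_sd * s + rel_floor * max(activity)
  if (!is.finite(thr_run)) stop("detect_t0: unreachable threshold", call. = FALSE)
  above <- activity > thr_run
  run_len <- round(sustain_s * fs_emg)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= run_len & starts > nb)
  if (length(ok) == 0) {
    stop("detect_t0: no sustained EMG activity onset found", call. = FALSE)
  }
  run_start <- starts[ok[1]]
  # backtrack to the departure from the statistical baseline alone
  thr_stat <- mu + k_sd * s
  i <- run_start
  while (i > nb + 1L && activity[i - 1L] > thr_stat) i <- i - 1L
  t0_emg <- i

  # knee flexion must also have departed its static baseline
  nbm <- max(2L, round(baseline_s * fs_mocap))
  if (nbm >= length(knee_flexion)) {
    stop("detect_t0: no quiet baseline window available for knee flexion",
         call. = FALSE)
  }
  mf <- mean(knee_flexion[seq_len(nbm)])
  sf <- sd(knee_flexion[seq_len(nbm)])
  dep <- which(abs(knee_flexion - mf) > k_sd * sf + flex_floor)
  dep <- dep[dep > nbm]
  if (length(dep) == 0) {
    stop("detect_t0: knee flexion never departs its static baseline",
         call. = FALSE)
  }
  ratio <- round(fs_emg / fs_mocap)
  t0_flex <- as.integer((dep[1] - 1L) * ratio + 1L)
  max(t0_emg, t0_flex)
}

# Rectified moving-average EMG activity across muscles; causal window so the
# onset is never anticipated.
emg_activity <- function(trial, window_s = 0.025) {
  amp <- rowMeans(abs(as.matrix(trial$signals[MUSCLES])))
  w <- max(1L, round(window_s * trial$fs_emg))
  as.numeric(stats::filter(c(numeric(w - 1), amp), rep(1 / w, w),
                           sides = 1)[w:(length(amp) + w - 1)])
}

#' Segment a hop trial into take-off, airborne and landing phases
#'
#' Composes the four event detectors: contact (t2) and peak force (t3) from
#' the force channel, take-off (t1) from ankle vertical velocity, and
#' movement onset (t0) from rectified EMG activity plus knee flexion. Phases
#' are the half-open intervals `[t0, t1)`, `[t1, t2)` and the closed
#' `[t2, t3]`, so frames partition the record without overlap. Event ordering
#' is enforced on every return.
#'
#' @param trial A `hop_trial` (condition it first with [condition_trial()]
#'   for real recordings).
#' @param threshold Contact force threshold, N.
#' @param ... Passed to [detect_t0()].
#' @return A `hop_events` list with `t0 < t1 < t2 < t3` (EMG-clock indices).
#' @examples
#' cfg <- simulation_config(n_aclr = 2, n_control = 2, seed = 2)
#' tr <- generate_trial(cfg, "ACLR", "index", "A01", 1)
#' ev <- segment_trial(tr)
#' unlist(ev)
#' @export
segment_trial <- function(trial, threshold = 50, ...) {
  stopifnot(inherits(trial, "hop_trial"))
  t2 <- detect_t2(trial$signals$vGRF, threshold)
  t3 <- detect_t3(trial$signals$vGRF, t2)
  t1 <- detect_t1(trial$mocap$ankle_vz, t2, trial$fs_emg, trial$fs_mocap)
  t0 <- detect_t0(emg_activity(trial), trial$mocap$knee_flexion,
                  trial$fs_emg, trial$fs_mocap, ...)
  ev <- list(t0 = t0, t1 = t1, t2 = t2, t3 = t3)
  ord <- c("t0 < t1" = t0 < t1, "t1 < t2" = t1 < t2, "t2 < t3" = t2 < t3,
           "t3 <= n" = t3 <= nrow(trial$signals))
  if (!all(ord)) {
    stop(sprintf("segment_trial: event ordering violated (%s)",
                 paste(names(ord)[!ord], collapse = ", ")), call. = FALSE)
  }
  structure(ev, class = "hop_events")
}

#' @export
print.hop_events <- function(x, ...) {
  cat(sprintf("<hop_events> t0=%d t1=%d t2=%d t3=%d\n", x$t0, x$t1, x$t2, x$t3))
  invisible(x)
}
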