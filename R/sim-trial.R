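#' Generate one synthetic hop trial with known ground truth
#'
#' Synthesizes the synchronized channels of a single one-leg hop: 7 EMG
#' channels (Gaussian-envelope bursts riding on muscle-specific band-limited
#' carriers, plus 60 Hz line contamination and white noise), vertical ground
#' reaction force on the EMG clock, and 125 Hz ankle vertical velocity and
#' knee flexion. The constructed phase-boundary events t0-t3 are returned as
#' ground truth (1-based sample indices on the EMG clock): movement onset t0,
#' take-off t1 (pre-contact ankle-velocity minimum, aligned to the mocap
#' grid), ground contact t2 (first force sample above 50 N) and peak force t3.
#'
#' Group differences are injected into burst amplitude, onset latency and
#' spectral centroid, scaled by `config$effect_size` and expressed fully in
#' the ACLR surgical limb and at `config$contra_effect` in the contralateral
#' limb. At `effect_size = 0` the two groups are statistically identical.
#'
#' @param config A [simulation_config()].
#' @param group `"ACLR"` or `"Control"`.
#' @param limb `"index"` (surgical limb for ACLR subjects) or `"contra"`.
#' @param subject_id Subject identifier string; seeds the subject's random
#'   effects so all trials of one subject share its idiosyncrasies.
#' @param trial_index Trial number within the limb (1-based).
#' @return A `hop_trial` object: a list with `signals` (tibble `time_s`, the 7
#'   muscles, `vGRF`), `mocap` (tibble `time_s`, `ankle_vz`, `knee_flexion`),
#'   identity fields, sampling rates and `truth` (list `t0`, `t1`, `t2`, `t3`).
#' @examples
#' cfg <- simulation_config(n_aclr = 2, n_control = 2, seed = 7)
#' tr <- generate_trial(cfg, "Control", "index", "C01", 1)
#' tr$truth$t2
#' @export
generate_trial <- function(config, group, limb, subject_id, trial_index = 1L) {
  validate_sim_config(config)
  group <- match.arg(group, c("ACLR", "Control"))
  limb <- match.arg(limb, c("index", "contra"))
  fs <- config$fs_emg
  fsm <- config$fs_mocap
  ratio <- round(fs / fsm)

  subj <- draw_subject_effects(config, subject_id)
  seed <- substream_seed(config$seed, string_key(subject_id),
                         match(limb, c("index", "contra")), trial_index)
  local_seed(seed, {
    # -- event timeline ------------------------------------------------------
    d <- config$phase_durations * exp(rnorm(3, 0, 0.04))
    pre_n <- round(config$pre_duration * fs)
    t0 <- pre_n + 1L
    t1_target <- t0 + round(d[1] * fs)
    m1 <- round((t1_target - 1) / ratio) + 1L           # snap t1 to mocap grid
    t1 <- as.integer((m1 - 1) * ratio + 1L)
    t2 <- as.integer(t1 + round(d[2] * fs))
    t3 <- as.integer(t2 + round(d[3] * fs))
    n <- as.integer(t3 + round(config$tail_duration * fs))
    n_mocap <- as.integer(ceiling(n / ratio))
    phase_bounds <- list(`1` = c(t0, t1 - 1L), `2` = c(t1, t2 - 1L),
                         `3` = c(t2, t3))

    lf <- if (group == "ACLR") (if (limb == "index") 1 else config$contra_effect) else 0
    params <- hop_muscle_params()
    params$shift_s <- rep(0, nrow(params))
    params <- apply_group_effect(params, config$effect_size, lf)

    # -- EMG channels --------------------------------------------------------
    tt <- (seq_len(n) - 1) / fs
    emg <- matrix(0, nrow = n, ncol = 7, dimnames = list(NULL, MUSCLES))
    for (m in MUSCLES) {
      pm <- params[params$muscle == m, ]
      se <- subj[subj$muscle == m, ]
      trial_amp <- exp(rnorm(1, 0, 0.10))
      trial_time <- rnorm(1, 0, 0.008)
      trial_cf <- rnorm(1, 0, 3)

      env <- numeric(n)
      # tonic activation: sharp 3-sample onset at t0, cosine release after t3
      tonic <- pm$tonic_mv[1] * se$amp_fac * trial_amp
      ramp <- seq(0, 1, length.out = 4)[-1]
      env[t0:(t0 + 2L)] <- tonic * ramp
      env[(t0 + 3L):t3] <- tonic
      rel <- min(n, t3 + round(0.15 * fs))
      if (rel > t3) {
        k <- seq_len(rel - t3)
        env[t3 + k] <- tonic * (1 + cos(pi * k / length(k))) / 2
      }
      for (b in seq_len(nrow(pm))) {
        pb <- phase_bounds[[as.character(pm$phase[b])]]
        centre <- pb[1] + pm$frac[b] * (pb[2] - pb[1]) +
          (pm$shift_s[b] + se$time_shift_s + trial_time) * fs
        sig_n <- pm$sigma_s[b] * fs
        lo <- max(t0, floor(centre - 3 * sig_n))
        hi <- min(n, ceiling(centre + 3 * sig_n))
        if (hi > lo) {
          i <- lo:hi
          env[i] <- env[i] +
            pm$amp_mv[b] * se$amp_fac * trial_amp * exp(-0.5 * ((i - centre) / sig_n)^2)
        }
      }
      cf <- pm$centroid_hz[1] + se$centroid_shift + trial_cf
      carrier <- band_limited_noise(n, fs, cf, 35)
      phase0 <- runif(1, 0, 2 * pi)
      emg[, m] <- env * carrier +
        config$line_amplitude * sin(2 * pi * config$line_freq * tt + phase0) +
        config$noise_sd * rnorm(n)
    }

    # -- vertical ground reaction force (zero until contact) -----------------
    vgrf <- numeric(n)
    i_land <- t2:t3
    x <- (i_land - t2) / (t3 - t2)
    vgrf[i_land] <- 55 + 345 * x^2
    imp_sd <- 0.008 * fs
    near <- max(t2, t3 - 10L * imp_sd):n
    vgrf[near] <- vgrf[near] + 1200 * exp(-0.5 * ((near - t3) / imp_sd)^2)
    if (n > t3) {
      # after the impact spike the force settles toward body weight
      k <- (t3 + 1L):n
      vgrf[k] <- vgrf[k] + 400 + 250 * (1 - exp(-(k - t3) / (0.08 * fs)))
    }
    if (config$noise_sd > 0) {
      post <- t2:n
      vgrf[post] <- vgrf[post] + 20 * config$noise_sd * rnorm(length(post))
    }

    # -- mocap channels ------------------------------------------------------
    m0 <- floor((t0 - 1) / ratio) + 1L
    m2 <- floor((t2 - 1) / ratio) + 1L
    m3 <- min(floor((t3 - 1) / ratio) + 1L, n_mocap)
    m_ap <- round((m1 + m2) / 2)

    vz <- numeric(n_mocap)
    seg <- m0:m1                                     # push-off dip, sharp min at m1
    vz[seg] <- -0.8 * ((seg - m0) / max(1, m1 - m0))^2
    seg <- m1:m_ap
    vz[seg] <- -0.8 + 3.3 * ((seg - m1) / max(1, m_ap - m1))
    seg <- m_ap:m2
    vz[seg] <- 2.5 - 3.2 * ((seg - m_ap) / max(1, m2 - m_ap))
    if (m3 > m2) {
      seg <- m2:m3
      vz[seg] <- -0.7 * (1 - (seg - m2) / (m3 - m2))
    }
    if (n_mocap > m3) vz[(m3 + 1L):n_mocap] <- 0

    flex <- rep(15, n_mocap)
    mf <- max(1L, m0 - 2L)                           # flexion departs just before t0
    seg <- mf:m1
    flex[seg] <- 15 + 45 * (seg - mf) / max(1, m1 - mf)
    seg <- m1:m2
    flex[seg] <- 60 - 20 * (seg - m1) / max(1, m2 - m1)
    if (m3 > m2) {
      seg <- m2:m3
      flex[seg] <- 40 + 35 * (seg - m2) / (m3 - m2)
    }
    if (n_mocap > m3) {
      k <- (m3 + 1L):n_mocap
      flex[k] <- 75 - 45 * (1 - exp(-(k - m3) / (0.3 * fsm)))
    }
    if (config$noise_sd > 0) {
      vz <- vz + 2 * config$noise_sd * rnorm(n_mocap)
      flex <- flex + 10 * config$noise_sd * rnorm(n_mocap)
    }

    signals <- tibble::as_tibble(as.data.frame(emg))
    signals <- dplyr::bind_cols(tibble::tibble(time_s = tt), signals,
                                tibble::tibble(vGRF = vgrf))
    mocap <- tibble::tibble(time_s = (seq_len(n_mocap) - 1) / fsm,
                            ankle_vz = vz, knee_flexion = flex)
    new_hop_trial(subject_id = subject_id, group = group, limb = limb,
                  trial = as.integer(trial_index), fs_emg = fs, fs_mocap = fsm,
                  signals = signals, mocap = mocap,
                  truth = list(t0 = t0, t1 = t1, t2 = t2, t3 = t3))
  })
}

# White noise shaped in the frequency domain by a Gaussian spectral window
# centred on the muscle's centroid; unit RMS.
band_limited_noise <- function(n, fs, centroid, spread) {
  w <- rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)                               # two-sided frequency axis
  gain <- exp(-0.5 * ((f - centroid) / spread)^2)
  gain[1] <- 0
  x <- Re(fft(fft(w) * gain, inverse = TRUE)) / n
  x / sd(x)
}

new_hop_trial <- function(subject_id, group, limb, trial, fs_emg, fs_mocap,
                          signals, mocap, truth = NULL) {
  structure(list(subject_id = subject_id, group = group, limb = limb,
                 trial = trial, fs_emg = fs_emg, fs_mocap = fs_mocap,
                 signals = signals, mocap = mocap, truth = truth),
            class = "hop_trial")
}

#' @export
print.hop_trial <- function(x, ...) {
  cat(sprintf("<hop_trial> %s %s/%s trial %d: %d EMG samples @ %g Hz, %d mocap @ %g Hz\n",
              x$subject_id, x$group, x$limb, x$trial,
              nrow(x$signals), x$fs_emg, nrow(x$mocap), x$fs_mocap))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth t0..t3: %d, %d, %d, %d\n",
                x$truth$t0, x$truth$t1, x$truth$t2, x$truth$t3))
  }
  invisible(x)
}
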