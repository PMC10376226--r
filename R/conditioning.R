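#' Filter specification for EMG conditioning
#'
#' Describes the power-line notch comb and the physiological band-pass applied
#' to every EMG channel before wavelet analysis: 60 Hz and all of its
#' harmonics up to the band edge are notched out, then the signal is
#' restricted to 7-700 Hz.
#'
#' @param line_freq Power-line frequency in Hz (default 60).
#' @param n_harmonics Number of harmonics to notch, or `NULL` (default) for
#'   every integer multiple of `line_freq` up to `band_high`.
#' @param notch_bandwidth Nominal notch width in Hz; tones at least this far
#'   from a harmonic are attenuated by less than 1 dB.
#' @param band_low,band_high Pass-band edges in Hz (defaults 7 and 700).
#' @param order Effective Butterworth magnitude order of each band edge.
#' @return An object of class `hop_filter_spec`.
#' @export
filter_spec <- function(line_freq = 60, n_harmonics = NULL,
                        notch_bandwidth = 4, band_low = 7, band_high = 700,
                        order = 4) {
  stopifnot(line_freq > 0, band_low > 0, band_low < band_high,
            notch_bandwidth > 0, order >= 1)
  structure(list(line_freq = line_freq, n_harmonics = n_harmonics,
                 notch_bandwidth = notch_bandwidth, band_low = band_low,
                 band_high = band_high, order = order),
            class = "hop_filter_spec")
}

notch_harmonics <- function(spec) {
  n_h <- spec$n_harmonics %||% floor(spec$band_high / spec$line_freq)
  spec$line_freq * seq_len(n_h)
}

# Zero-phase filtering realized in the frequency domain: the signal is
# reflect-padded (one warm-up length each side), tapered to zero over the
# outer half of the pads, transformed, multiplied by a real nonnegative gain,
# and transformed back. Real gains give exactly zero phase; tapered reflection
# padding suppresses both circular wrap-around and spectral leakage.
apply_gain_filter <- function(x, fs, gain_fun, pad_s = 0.5) {
  n <- length(x)
  if (n < 8) stop("signal too short to filter", call. = FALSE)
  p <- min(n - 1, round(pad_s * fs))
  nfft <- stats::nextn(n + 2 * p, c(2, 3, 5))
  f <- seq(0, fs, length.out = nfft + 1)[seq_len(nfft)]
  f <- pmin(f, fs - f)
  g <- gain_fun(f)
  # handle the constant component exactly: filter the demeaned signal and add
  # the mean back through the DC gain
  mu <- mean(x)
  xp <- pad_reflect_taper(x - mu, p, nfft)
  y <- Re(fft(fft(xp) * g, inverse = TRUE)) / nfft
  y[(p + 1):(p + n)] + mu * g[1]
}

# Reflect-pad by p samples each side, cosine-taper the outer half of each pad
# to zero, and zero-extend to the transform length.
pad_reflect_taper <- function(x, p, nfft) {
  n <- length(x)
  xp <- c(rev(x[2:(p + 1)]), x, rev(x[(n - p):(n - 1)]))
  h <- floor(p / 2)
  if (h > 1) {
    taper <- (1 - cos(pi * seq_len(h) / h)) / 2
    xp[seq_len(h)] <- xp[seq_len(h)] * taper
    xp[length(xp) - seq_len(h) + 1] <- xp[length(xp) - seq_len(h) + 1] * taper
  }
  c(xp, numeric(nfft - length(xp)))
}

gain_notch <- function(spec) {
  harm <- notch_harmonics(spec)
  sig <- spec$notch_bandwidth / 4
  function(f) {
    g <- rep(1, length(f))
    for (h in harm) g <- g * (1 - exp(-0.5 * ((f - h) / sig)^2))
    g
  }
}

gain_bandpass <- function(spec) {
  k <- 2 * spec$order
  function(f) {
    hp <- ifelse(f > 0, 1 / sqrt(1 + (spec$band_low / pmax(f, 1e-12))^k), 0)
    lp <- 1 / sqrt(1 + (f / spec$band_high)^k)
    hp * lp
  }
}

#' Notch out the power-line frequency and its harmonics
#'
#' Zero-phase removal of `line_freq` and every harmonic below the band edge.
#' Attenuation at each harmonic exceeds 30 dB while tones at least
#' `notch_bandwidth` away are attenuated by less than 1 dB.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  harm <- notch_harmonics(spec)
  if (fs <= 2 * max(harm)) {
    stop("notch_filter: sampling rate must exceed twice the highest notched harmonic",
         call. = FALSE)
  }
  apply_gain_filter(x, fs, gain_notch(spec))
}

#' Band-pass EMG to the physiological band
#'
#' Zero-phase restriction to `band_low`-`band_high` Hz (7-700 Hz by default).
#' DC and slow drift are rejected; mid-band components pass within 1 dB.
#'
#' @inheritParams notch_filter
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (spec$band_high >= fs / 2) {
    stop("bandpass_filter: band_high must be below the Nyquist frequency",
         call. = FALSE)
  }
  apply_gain_filter(x, fs, gain_bandpass(spec))
}

#' Condition every EMG channel of a trial
#'
#' Applies the notch comb first, then the band-pass, to each of the 7 EMG
#' channels. Force and motion-capture channels are untouched.
#'
#' @param trial A `hop_trial`.
#' @param spec A [filter_spec()].
#' @return The trial with conditioned EMG channels.
#' @examples
#' cfg <- simulation_config(n_aclr = 2, n_control = 2, seed = 1)
#' tr <- condition_trial(generate_trial(cfg, "Control", "index", "C01", 1))
#' @export
condition_trial <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "hop_trial"))
  fs <- trial$fs_emg
  if (spec$band_high >= fs / 2) {
    stop("condition_trial: band_high must be below the Nyquist frequency",
         call. = FALSE)
  }
  # the two zero-phase stages are real gains, so their cascade is the product
  n <- nrow(trial$signals)
  p <- min(n - 1, round(0.5 * fs))
  nfft <- stats::nextn(n + 2 * p, c(2, 3, 5))
  f <- seq(0, fs, length.out = nfft + 1)[seq_len(nfft)]
  f <- pmin(f, fs - f)
  g <- gain_notch(spec)(f) * gain_bandpass(spec)(f)
  mus <- vapply(MUSCLES, function(m) mean(trial$signals[[m]]), numeric(1))
  Xp <- vapply(seq_along(MUSCLES), function(i) {
    pad_reflect_taper(trial$signals[[MUSCLES[i]]] - mus[i], p, nfft)
  }, numeric(nfft))
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * g, inverse = TRUE)) / nfft
  for (i in seq_along(MUSCLES)) {
    trial$signals[[MUSCLES[i]]] <- Y[(p + 1):(p + n), i] + mus[i] * g[1]
  }
  trial
}
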