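#' Simulation configuration for synthetic hop cohorts
#'
#' Bundles every tunable of the synthetic hop-trial generator. Defaults mirror
#' the acquisition protocol the package targets: 7 EMG channels at 3000 Hz,
#' motion capture at 125 Hz, 60 Hz line contamination, 11 ACLR and 12 control
#' subjects with 3 trials per limb, and hop distance standardized to 65% of
#' each subject's maximum.
#'
#' @param n_aclr,n_control Subjects per group (each >= 2).
#' @param trials_per_limb Hop trials recorded per limb (default 3).
#' @param muscles Channel names; fixed set of 7 (GM, GL, TA, VM, RF, BF, ST).
#' @param fs_emg EMG / force sampling rate in Hz (default 3000).
#' @param fs_mocap Motion-capture sampling rate in Hz (default 125).
#' @param line_freq Power-line frequency in Hz (default 60).
#' @param line_amplitude Amplitude of the additive line interference, mV.
#' @param noise_sd Standard deviation of white baseline noise, mV.
#' @param effect_size Dimensionless >= 0; scales the injected ACLR-vs-control
#'   differences in burst intensity, onset latency and spectral centroid.
#' @param contra_effect Fraction (0-1) of the surgical-limb effect expressed in
#'   the ACLR contralateral limb; 0.9 by default so ACLR limbs are nearly
#'   bilaterally symmetric while both differ from controls.
#' @param phase_durations Nominal durations in seconds of the take-off,
#'   airborne and landing phases.
#' @param pre_duration Quiet-standing baseline before movement onset, seconds.
#' @param tail_duration Recording kept after peak landing force, seconds.
#' @param missing_trial_rate Probability in `[0, 1)` that any one trial is
#'   dropped, emulating per-trial exclusions.
#' @param hop_distance_fraction Fraction of maximum hop distance used for the
#'   standardized trials (default 0.65).
#' @param outcome_link List with `intercept`, `slope`, `noise_sd`, `weak_hop`:
#'   the linear link from thigh-girth deficit (cm) to the summed knee
#'   degeneration (WORM-type) score, its residual noise, and a weak secondary
#'   link from hop-ratio deficit. Defaults (-8.3, -20.8, 8, 0.3) let
#'   regression-recovery tests target a known slope.
#' @param seed Master integer seed; per-trial substreams are derived from it.
#'
#' @return An object of class `hop_sim_config` (a named list).
#' @examples
#' cfg <- simulation_config(n_aclr = 2, n_control = 2, seed = 1)
#' cfg$fs_emg
#' @export
simulation_config <- function(n_aclr = 11,
                              n_control = 12,
                              trials_per_limb = 3,
                              muscles = c("GM", "GL", "TA", "VM", "RF", "BF", "ST"),
                              fs_emg = 3000,
                              fs_mocap = 125,
                              line_freq = 60,
                              line_amplitude = 0.05,
                              noise_sd = 0.03,
                              effect_size = 1,
                              contra_effect = 0.9,
                              phase_durations = c(0.45, 0.30, 0.15),
                              pre_duration = 0.6,
                              tail_duration = 0.2,
                              missing_trial_rate = 0,
                              hop_distance_fraction = 0.65,
                              outcome_link = list(intercept = -8.3, slope = -20.8,
                                                  noise_sd = 8, weak_hop = 0.3),
                              seed = 1L) {
  cfg <- list(
    n_aclr = as.integer(n_aclr), n_control = as.integer(n_control),
    trials_per_limb = as.integer(trials_per_limb), muscles = muscles,
    fs_emg = fs_emg, fs_mocap = fs_mocap, line_freq = line_freq,
    line_amplitude = line_amplitude, noise_sd = noise_sd,
    effect_size = effect_size, contra_effect = contra_effect,
    phase_durations = phase_durations, pre_duration = pre_duration,
    tail_duration = tail_duration, missing_trial_rate = missing_trial_rate,
    hop_distance_fraction = hop_distance_fraction,
    outcome_link = utils::modifyList(
      list(intercept = -8.3, slope = -20.8, noise_sd = 8, weak_hop = 0.3),
      outcome_link),
    seed = as.integer(seed)
  )
  class(cfg) <- "hop_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "hop_sim_config"))
  if (cfg$n_aclr < 2 || cfg$n_control < 2) {
    stop("simulation_config: need at least 2 subjects per group", call. = FALSE)
  }
  if (!identical(sort(cfg$muscles), sort(MUSCLES))) {
    stop("simulation_config: muscles must be exactly {GM, GL, TA, VM, RF, BF, ST}",
         call. = FALSE)
  }
  if (length(cfg$phase_durations) != 3 || any(cfg$phase_durations <= 0)) {
    stop("simulation_config: phase_durations must be 3 positive durations",
         call. = FALSE)
  }
  if (cfg$missing_trial_rate < 0 || cfg$missing_trial_rate >= 1) {
    stop("simulation_config: missing_trial_rate must be in [0, 1)", call. = FALSE)
  }
  # Nyquist guard for the burst carriers (centroids < 200 Hz, spectral sd 35 Hz)
  max_carrier <- max(hop_muscle_params()$centroid_hz) + 3 * 35
  if (cfg$fs_emg <= 2 * max_carrier) {
    stop("simulation_config: fs_emg must exceed twice the highest burst carrier frequency",
         call. = FALSE)
  }
  if (cfg$trials_per_limb < 1) stop("simulation_config: trials_per_limb >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.hop_sim_config <- function(x, ...) {
  cat("<hop_sim_config>\n")
  cat(sprintf("  subjects: %d ACLR + %d control, %d trials/limb\n",
              x$n_aclr, x$n_control, x$trials_per_limb))
  cat(sprintf("  fs: EMG/force %g Hz, mocap %g Hz\n", x$fs_emg, x$fs_mocap))
  cat(sprintf("  effect_size: %g (contralateral fraction %g)\n",
              x$effect_size, x$contra_effect))
  cat(sprintf("  noise_sd: %g mV, line: %g mV @ %g Hz\n",
              x$noise_sd, x$line_amplitude, x$line_freq))
  cat(sprintf("  phases (s): %s, seed %d\n",
              paste(x$phase_durations, collapse = "/"), x$seed))
  invisible(x)
}
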