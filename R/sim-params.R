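# Per-muscle burst timetable for the synthetic hop.
#
# Each muscle fires a small number of Gaussian-envelope bursts anchored to a
# hop phase (1 take-off, 2 airborne, 3 landing) at a fractional position
# within the phase, plus a low tonic activation spanning the whole movement.
# Carrier centroids are typical surface-EMG spectral centroids (plantar
# flexors and TA higher, quadriceps lower).

#' Base burst parameters of the synthetic muscles
#'
#' One row per burst: muscle, anchoring phase (1 = take-off, 2 = airborne,
#' 3 = landing), fractional position inside the phase, envelope width (Gaussian
#' sigma, seconds), amplitude (mV), and the muscle's carrier spectral centroid
#' (Hz) and tonic activation level (mV).
#'
#' @return A tibble with columns `muscle`, `phase`, `frac`, `sigma_s`,
#'   `amp_mv`, `centroid_hz`, `tonic_mv`.
#' @keywords internal
hop_muscle_params <- function() {
  tribble_rows <- list(
    # muscle phase  frac sigma_s amp_mv
    c("GM", 1, 0.80, 0.060, 0.55), c("GM", 3, 0.35, 0.025, 0.65),
    c("GL", 1, 0.78, 0.060, 0.45), c("GL", 3, 0.40, 0.025, 0.55),
    c("TA", 1, 0.25, 0.060, 0.40), c("TA", 2, 0.60, 0.050, 0.50),
    c("TA", 3, 0.40, 0.030, 0.45),
    c("VM", 1, 0.60, 0.060, 0.60), c("VM", 3, 0.40, 0.030, 0.70),
    c("RF", 1, 0.55, 0.060, 0.55), c("RF", 3, 0.45, 0.030, 0.60),
    c("BF", 1, 0.30, 0.050, 0.25), c("BF", 2, 0.70, 0.050, 0.50),
    c("BF", 3, 0.30, 0.030, 0.50),
    c("ST", 1, 0.30, 0.050, 0.22), c("ST", 2, 0.75, 0.050, 0.50),
    c("ST", 3, 0.30, 0.030, 0.45)
  )
  out <- tibble::tibble(
    muscle = vapply(tribble_rows, `[`, character(1), 1),
    phase = as.integer(vapply(tribble_rows, `[`, character(1), 2)),
    frac = as.numeric(vapply(tribble_rows, `[`, character(1), 3)),
    sigma_s = as.numeric(vapply(tribble_rows, `[`, character(1), 4)),
    amp_mv = as.numeric(vapply(tribble_rows, `[`, character(1), 5))
  )
  spectra <- c(GM = 110, GL = 118, TA = 125, VM = 85, RF = 83, BF = 95, ST = 98)
  tonic <- c(GM = 0.10, GL = 0.08, TA = 0.10, VM = 0.10, RF = 0.10,
             BF = 0.08, ST = 0.08)
  out$centroid_hz <- unname(spectra[out$muscle])
  out$tonic_mv <- unname(tonic[out$muscle])
  out
}

# Group-by-limb effect multipliers. The injected ACLR differences live in the
# quadriceps take-off burst (higher amplitude, earlier onset), the hamstring
# airborne burst (latent, shorter, more intense, centroid up), and nothing
# else: GM, GL and TA carry no group effect so their patterns stay at chance.
# `lf` is the limb loading of the effect (1 surgical, contra_effect contra,
# 0 control).
apply_group_effect <- function(params, effect, lf) {
  e <- effect * lf
  if (e == 0) return(params)
  quad_takeoff <- params$muscle %in% c("VM", "RF") & params$phase == 1L
  ham_air <- params$muscle %in% c("BF", "ST") & params$phase == 2L
  params$amp_mv[quad_takeoff] <- params$amp_mv[quad_takeoff] * (1 + 0.35 * e)
  params$shift_s <- params$shift_s %||% rep(0, nrow(params))
  params$shift_s[quad_takeoff] <- params$shift_s[quad_takeoff] - 0.015 * e
  params$shift_s[ham_air] <- params$shift_s[ham_air] + 0.025 * e
  params$sigma_s[ham_air] <- pmax(params$sigma_s[ham_air] * (1 - 0.08 * e),
                                  0.3 * params$sigma_s[ham_air])
  params$amp_mv[ham_air] <- params$amp_mv[ham_air] * (1 + 0.15 * e)
  ham <- params$muscle %in% c("BF", "ST")
  params$centroid_hz[ham] <- params$centroid_hz[ham] + 6 * e
  params
}

# Subject-level random effects, drawn once per subject from that subject's
# substream: multiplicative amplitude idiosyncrasy, a timing shift and a
# spectral-centroid shift per muscle.
draw_subject_effects <- function(cfg, subject_id) {
  local_seed(substream_seed(cfg$seed, string_key(subject_id), 1L), {
    tibble::tibble(
      muscle = MUSCLES,
      amp_fac = exp(rnorm(7, 0, 0.15)),
      time_shift_s = rnorm(7, 0, 0.015),
      centroid_shift = rnorm(7, 0, 5)
    )
  })
}

string_key <- function(s) {
  v <- utf8ToInt(s)
  sum(v * seq_along(v))
}
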