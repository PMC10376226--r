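#' Generate a synthetic hop cohort with ground truth and subject outcomes
#'
#' Builds `n_aclr + n_control` subjects, two limbs each (`index` is the
#' surgical limb in the ACLR group), `trials_per_limb` hop trials per limb
#' minus trials dropped at `missing_trial_rate`. Each subject also receives a
#' simulated outcome record: thigh-girth side difference, KT-1000 laxity
#' difference, hop-distance ratio, Tegner score and a summed knee-degeneration
#' (WORM-type) score linked linearly to the girth deficit (slope
#' `config$outcome_link$slope`, default -20.8) plus noise, so that regression
#' recovery can be tested against a known truth.
#'
#' @param config A [simulation_config()].
#' @return A `hop_cohort`: list with `trials` (list of [generate_trial()]
#'   results), `truth` (tibble of ground-truth events per trial), `outcomes`
#'   (tibble, one row per subject) and `config`.
#' @examples
#' cfg <- simulation_config(n_aclr = 2, n_control = 2, trials_per_limb = 1,
#'                          seed = 3)
#' coh <- generate_cohort(cfg)
#' nrow(coh$truth)
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  subjects <- tibble::tibble(
    subject_id = c(sprintf("A%02d", seq_len(config$n_aclr)),
                   sprintf("C%02d", seq_len(config$n_control))),
    group = rep(c("ACLR", "Control"), c(config$n_aclr, config$n_control))
  )
  grid <- tidyr::expand_grid(subjects, limb = c("index", "contra"),
                             trial = seq_len(config$trials_per_limb))
  keep <- local_seed(substream_seed(config$seed, 424243L), {
    runif(nrow(grid)) >= config$missing_trial_rate
  })
  grid <- grid[keep, ]

  trials <- purrr::pmap(grid, function(subject_id, group, limb, trial) {
    generate_trial(config, group, limb, subject_id, trial)
  })
  truth <- dplyr::bind_cols(
    grid,
    purrr::map_dfr(trials, function(tr) {
      tibble::tibble(t0 = tr$truth$t0, t1 = tr$truth$t1, t2 = tr$truth$t2,
                     t3 = tr$truth$t3, n_samples = nrow(tr$signals))
    })
  )
  outcomes <- simulate_outcomes(config, subjects)
  structure(list(trials = trials, truth = truth, outcomes = outcomes,
                 config = config),
            class = "hop_cohort")
}

#' Generate only the subject outcome table of a cohort
#'
#' Same outcome simulation as [generate_cohort()] (identical given the same
#' config) without synthesizing any signals; convenient for regression
#' studies over many replicates.
#'
#' @param config A [simulation_config()].
#' @return Tibble, one row per subject.
#' @export
generate_outcomes <- function(config) {
  validate_sim_config(config)
  subjects <- tibble::tibble(
    subject_id = c(sprintf("A%02d", seq_len(config$n_aclr)),
                   sprintf("C%02d", seq_len(config$n_control))),
    group = rep(c("ACLR", "Control"), c(config$n_aclr, config$n_control))
  )
  simulate_outcomes(config, subjects)
}

# Subject outcome tables with a configurable girth -> degeneration-score link
# and a weak secondary hop-ratio link; everything else is unlinked noise.
simulate_outcomes <- function(config, subjects) {
  lk <- config$outcome_link
  local_seed(substream_seed(config$seed, 999983L), {
    n <- nrow(subjects)
    aclr <- subjects$group == "ACLR"
    girth <- ifelse(aclr, rnorm(n, -2.0, 1.0), rnorm(n, 0, 0.5))
    girth <- round(girth * 2) / 2                      # 0.5 cm resolution
    laxity <- ifelse(aclr, rnorm(n, -1, 2), rnorm(n, 0, 0.8))
    laxity <- round(laxity)
    hop <- ifelse(aclr, rnorm(n, 96, 9), rnorm(n, 100, 6))
    hop <- pmax(round(hop), 40)
    tegner <- pmin(pmax(round(rnorm(n, 5.5, 1.4)), 2), 10)
    worms <- lk$intercept + lk$slope * girth + lk$weak_hop * (100 - hop) +
      rnorm(n, 0, lk$noise_sd)
    worms[!aclr] <- abs(rnorm(sum(!aclr), 4, 3))
    tibble::tibble(
      subject_id = subjects$subject_id, group = subjects$group,
      girth_delta_cm = girth, laxity_delta_mm = laxity,
      hop_ratio_pct = hop, tegner = tegner,
      worms_total = pmax(worms, 0),
      age_years = pmax(round(rnorm(n, 35, 9)), 18),
      bmi = round(rnorm(n, 26.5, 3.6), 1),
      follow_up_years = sample(c(10, 12, 12, 12, 12, 15), n, replace = TRUE)
    )
  })
}

#' @export
print.hop_cohort <- function(x, ...) {
  cat(sprintf("<hop_cohort> %d trials from %d subjects (%d ACLR, %d control)\n",
              length(x$trials), nrow(x$outcomes),
              sum(x$outcomes$group == "ACLR"),
              sum(x$outcomes$group == "Control")))
  invisible(x)
}
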