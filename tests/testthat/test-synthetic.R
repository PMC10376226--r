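test_that("identical config and seed reproduce a trial bit for bit", {
  cfg <- tiny_config(seed = 5)
  a <- generate_trial(cfg, "ACLR", "index", "A01", 1)
  b <- generate_trial(cfg, "ACLR", "index", "A01", 1)
  expect_identical(a$signals, b$signals)
  expect_identical(a$mocap, b$mocap)
  expect_identical(a$truth, b$truth)
})

test_that("at zero effect size the group label has no influence on the signals", {
  cfg <- tiny_config(seed = 6, effect_size = 0)
  a <- generate_trial(cfg, "ACLR", "index", "S01", 2)
  c <- generate_trial(cfg, "Control", "index", "S01", 2)
  expect_identical(a$signals, c$signals)
})

test_that("constructed events honor their defining contracts", {
  for (seed in c(3, 9)) {
    tr <- generate_trial(tiny_config(seed = seed), "Control", "contra", "C02", 1)
    tt <- tr$truth
    expect_true(tt$t0 < tt$t1 && tt$t1 < tt$t2 && tt$t2 < tt$t3)
    expect_lte(tt$t3, nrow(tr$signals))
    v <- tr$signals$vGRF
    # force is zero until contact, first exceeds 50 N exactly at t2
    expect_lte(max(abs(v[seq_len(tt$t2 - 1)])), 50)
    expect_gt(v[tt$t2], 50)
    expect_lte(abs(which.max(v) - tt$t3), 1)  # force noise can shift the argmax
    # t1 lies on the mocap grid
    expect_equal((tt$t1 - 1) %% 24, 0)
    # EMG is exactly quiet before onset when noise and line are off
    trc <- generate_trial(clean_config(seed = seed), "Control", "contra", "C02", 1)
    emg <- as.matrix(trc$signals[c("GM", "GL", "TA", "VM", "RF", "BF", "ST")])
    expect_equal(max(abs(emg[seq_len(trc$truth$t0 - 1), ])), 0)
  }
})

test_that("cohort counts follow the trial-limb convention", {
  cfg <- simulation_config(n_aclr = 11, n_control = 12, trials_per_limb = 3,
                           phase_durations = c(0.30, 0.20, 0.10),
                           pre_duration = 0.5, tail_duration = 0.15,
                           missing_trial_rate = 0, seed = 8)
  # counting only; build the grid the cohort generator builds
  coh <- generate_cohort(
    simulation_config(n_aclr = 2, n_control = 2, trials_per_limb = 3,
                      phase_durations = c(0.30, 0.20, 0.10),
                      pre_duration = 0.5, tail_duration = 0.15, seed = 8))
  expect_equal(nrow(coh$truth), 2 * 2 * 2 * 3)
  per <- dplyr::count(coh$truth, subject_id, limb)
  expect_true(all(per$n == 3))
  # full-cohort arithmetic for the study sizes: 66 ACLR-side and 72
  # control-side trial-limb records, 69 per limb pairing across groups
  expect_equal(cfg$n_aclr * 2 * cfg$trials_per_limb, 66)
  expect_equal(cfg$n_control * 2 * cfg$trials_per_limb, 72)
  expect_equal((cfg$n_aclr + cfg$n_control) * cfg$trials_per_limb, 69)
})

test_that("missing trials are dropped at the requested rate, deterministically", {
  cfg <- simulation_config(n_aclr = 4, n_control = 4, trials_per_limb = 3,
                           phase_durations = c(0.30, 0.20, 0.10),
                           pre_duration = 0.5, tail_duration = 0.15,
                           missing_trial_rate = 0.3, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_lt(nrow(a$truth), 4 * 2 * 2 * 3)
  expect_gt(nrow(a$truth), 0)
})

test_that("invalid labels and configurations are rejected", {
  cfg <- tiny_config()
  expect_error(generate_trial(cfg, "Patient", "index", "X", 1))
  expect_error(generate_trial(cfg, "ACLR", "left", "X", 1))
  expect_error(simulation_config(n_aclr = 1, n_control = 5), "2 subjects")
  expect_error(simulation_config(phase_durations = c(0.3, -0.1, 0.1)),
               "positive")
  expect_error(simulation_config(missing_trial_rate = 1), "missing_trial_rate")
  expect_error(simulation_config(fs_emg = 300), "carrier")
  expect_error(simulation_config(muscles = c("GM", "GL")), "muscles")
})

test_that("classification rate is non-decreasing in effect size", {
  rate_at <- function(e) {
    cfg <- simulation_config(n_aclr = 4, n_control = 4, trials_per_limb = 2,
                             phase_durations = c(0.35, 0.25, 0.12),
                             pre_duration = 0.5, tail_duration = 0.15,
                             effect_size = e, seed = 77)
    cp <- cohort_patterns(generate_cohort(cfg))
    res <- run_comparisons(cp, comparisons = "ACLR_Contra vs Control_Idx",
                           phase_scopes = "all", muscles = c("VM", "RF"))
    mean(res$rate_percent)
  }
  rates <- vapply(c(0, 1.5, 3), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("simulated outcomes carry the configured girth-score link", {
  cfg <- simulation_config(n_aclr = 200, n_control = 2, seed = 31,
                           outcome_link = list(intercept = 30, slope = -15,
                                               noise_sd = 2))
  out <- generate_outcomes(cfg)
  expect_equal(nrow(out), 202)
  expect_true(all(out$worms_total >= 0))
  expect_true(all(out$hop_ratio_pct > 0))
  aclr <- out[out$group == "ACLR", ]
  fit <- lm(worms_total ~ girth_delta_cm, data = aclr)
  expect_lt(abs(unname(coef(fit)[2]) - (-15)), 1.5)
})
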