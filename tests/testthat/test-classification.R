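test_that("vectorization flattens the selected phase row-major", {
  m <- matrix(seq_len(14 * 300), nrow = 14)
  p <- structure(m, class = c("hop_pattern", "matrix"))
  v_all <- vectorize_pattern(p, "all")
  expect_length(v_all, 4200)
  v_take <- vectorize_pattern(p, "take-off")
  expect_length(v_take, 1400)
  expect_equal(v_take, as.vector(t(m[, 1:100])))
  v_land <- vectorize_pattern(p, "landing")
  expect_equal(v_land, as.vector(t(m[, 201:300])))
  expect_error(vectorize_pattern(p, "flight"))
  # distinct patterns vectorize distinctly
  m2 <- m
  m2[3, 7] <- -1
  expect_false(identical(vectorize_pattern(structure(m2, class = class(p))),
                         v_all))
})

test_that("hand-worked 1-NN LOOCV toys give 4/4 and 0/4", {
  f <- matrix(c(0, 1, 10, 11), ncol = 1)
  res <- knn_loocv(f, c("A", "A", "B", "B"), cv_unit = "trial")
  expect_equal(res$n_correct, 4L)
  expect_equal(res$rate_percent, 100)
  # alternating labels on a line: every neighbor (after the first-index tie
  # rule) carries the opposite label
  f2 <- matrix(0:3, ncol = 1)
  res2 <- knn_loocv(f2, c("A", "B", "A", "B"), cv_unit = "trial")
  expect_equal(res2$n_correct, 0L)
  expect_equal(res2$rate_percent, 0)
})

test_that("degenerate inputs are rejected", {
  f <- matrix(1:4, ncol = 1)
  expect_error(knn_loocv(f[1, , drop = FALSE], "A", cv_unit = "trial"),
               "at least 2")
  expect_error(knn_loocv(f, c("A", "A", "A", "B"), cv_unit = "trial"),
               "per class")
  expect_error(knn_loocv(f, c("A", "A", "B", "B"), cv_unit = "subject"),
               "units")
})

test_that("vectorized LOOCV matches the brute-force oracle on random sets", {
  set.seed(421)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    k <- sample(1:3, 1)
    f <- matrix(sample(0:4, n * k, replace = TRUE), nrow = n)  # forces ties
    labs <- c("A", "A", "B", "B", sample(c("A", "B"), n - 4, replace = TRUE))
    got <- knn_loocv(f, labs, cv_unit = "trial")
    want <- brute_knn_loocv(f, labs)
    expect_equal(got$n_correct, unname(want["correct"]))
  }
})

test_that("subject-level folds hold out every trial of the subject", {
  # two trials per subject; subject S1's trials are mutual nearest neighbors,
  # so trial-level CV is fooled while subject-level CV is not
  f <- matrix(c(0, 0.1, 5, 5.1, 0.4, 4.8), ncol = 1)
  labs <- c("A", "A", "B", "B", "B", "A")
  units <- c("S1", "S1", "S2", "S2", "S3", "S4")
  trial_res <- knn_loocv(f, labs, units, cv_unit = "trial")
  subj_res <- knn_loocv(f, labs, units, cv_unit = "subject")
  expect_gt(trial_res$n_correct, subj_res$n_correct)
})

test_that("permuted labels classify near chance", {
  set.seed(7)
  n <- 80
  f <- matrix(rnorm(n * 5), nrow = n)
  rates <- replicate(60, {
    labs <- sample(rep(c("A", "B"), n / 2))
    knn_loocv(f, labs, cv_unit = "trial")$rate_percent
  })
  expect_lt(abs(mean(rates) - 50), 5)
  band <- 100 * qbinom(c(0.025, 0.975), n, 0.5) / n
  expect_gt(mean(rates >= band[1] & rates <= band[2]), 0.8)
})

test_that("the comparison grid covers muscles, comparisons and phases", {
  cp <- cached_tiny_patterns()
  res <- run_comparisons(cp, phase_scopes = c("all", "take-off"))
  expect_s3_class(res, "hop_classification")
  expect_equal(nrow(res), 3 * 7 * 2)
  expect_true(all(res$n_correct <= res$n_total))
  expect_equal(res$rate_percent, round(100 * res$n_correct / res$n_total, 1))
  # whole-hop vectors have 4200 features, phase vectors 1400: totals match
  # the limb-pairing convention (2 subjects x 2 trials x 2 limbs)
  expect_true(all(res$n_total == 8))
  expect_error(run_comparisons(cp, comparisons = "nope"), "unknown")
})

test_that("a pattern duplicated across classes triggers a leakage warning", {
  cp <- cached_tiny_patterns()
  sub <- cp[cp$muscle == "VM", ]
  aclr_contra <- which(sub$group == "ACLR" & sub$limb == "contra")[1]
  ctrl_index <- which(sub$group == "Control" & sub$limb == "index")[1]
  sub$pattern[[ctrl_index]] <- sub$pattern[[aclr_contra]]
  expect_warning(
    run_comparisons(sub, comparisons = "ACLR_Contra vs Control_Idx",
                    phase_scopes = "all", muscles = "VM"),
    "leakage")
})

test_that("tidy and glance summarize classification grids", {
  cp <- cached_tiny_patterns()
  res <- run_comparisons(cp, comparisons = "ACLR_Contra vs Control_Idx",
                         phase_scopes = "all")
  g <- glance(judge_rates(res, critical_rate(23)))
  expect_equal(g$n_cells, 7L)
  expect_true(is.finite(g$n_significant))
  td <- tidy(res)
  expect_false(inherits(td, "hop_classification"))
  expect_equal(nrow(td), nrow(res))
})
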