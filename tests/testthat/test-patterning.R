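toy_events <- function(t0, t1, t2, t3) {
  structure(list(t0 = t0, t1 = t1, t2 = t2, t3 = t3), class = "hop_events")
}

test_that("time normalization preserves constants, ramps and identity grids", {
  ev <- toy_events(1, 101, 201, 300)
  m <- matrix(rep(c(2, 5), each = 300), nrow = 2, byrow = TRUE)
  out <- time_normalize(m, ev)
  expect_equal(dim(out), c(2, 300))
  expect_true(all(out[1, ] == 2) && all(out[2, ] == 5))

  ramp <- matrix(seq(0, 99, length.out = 100), nrow = 1)
  ev1 <- toy_events(1, 41, 71, 100)
  out1 <- time_normalize(ramp, ev1)
  # each phase is a linear ramp over 100 frames with the phase's endpoints
  expect_equal(out1[1, 1], 0)
  expect_equal(out1[1, 100], 39)
  expect_equal(out1[1, 101], 40)
  expect_equal(out1[1, 300], 99)
  expect_true(all(abs(diff(out1[1, 1:100]) - 39 / 99) < 1e-12))

  # a phase of exactly 100 samples is reproduced verbatim
  ev2 <- toy_events(1, 101, 201, 300)
  vals <- matrix(sin(seq_len(300)), nrow = 1)
  out2 <- time_normalize(vals, ev2)
  expect_equal(out2[1, 1:100], vals[1, 1:100], tolerance = 1e-12)
})

test_that("degenerate phases are rejected", {
  expect_error(time_normalize(matrix(1, 1, 50), toy_events(1, 2, 10, 50)),
               "degenerate")
  expect_error(time_normalize(matrix(1, 1, 40), toy_events(1, 10, 20, 50)),
               "record length")
})

test_that("z-normalization gives per-band mean 0, SD 1 and is scale invariant", {
  m <- rbind(1:300, sin(seq_len(300)))
  z <- z_normalize(m)
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(z_normalize(10 * m), z, tolerance = 1e-12)
})

test_that("a constant band is flagged and zeroed, not silently normalized", {
  m <- rbind(rep(4, 50), 1:50)
  expect_warning(z <- z_normalize(m), "zero-variance")
  expect_equal(z[1, ], rep(0, 50))
  expect_equal(attr(z, "degenerate_bands"), 1L)
})

test_that("patterns are 14 x 300 and the pipeline is gain invariant", {
  ct <- cached_tiny_trial()
  p1 <- trial_pattern(ct$trial, "VM", ct$events)
  expect_equal(dim(unclass(p1)), c(14, 300))
  expect_equal(attr(p1, "phase_boundaries"), c(0, 100, 200, 300))
  # multiply the raw EMG by 10: conditioning is linear, intensity scales by
  # 100, z-normalization removes it all
  tr10 <- ct$raw
  for (m in c("GM", "GL", "TA", "VM", "RF", "BF", "ST")) {
    tr10$signals[[m]] <- 10 * tr10$signals[[m]]
  }
  tr10c <- condition_trial(tr10)
  p10 <- trial_pattern(tr10c, "VM", ct$events)
  expect_lt(max(abs(unclass(p10) - unclass(p1))), 1e-6)
})

test_that("averaging is the cell-wise mean within groups", {
  ct <- cached_tiny_trial()
  p <- trial_pattern(ct$trial, "RF", ct$events)
  tbl <- tibble::tibble(group = c("A", "A", "B"), limb = "index",
                        muscle = "RF", pattern = list(p, p, -1 * p))
  avg <- average_patterns(tbl)
  a <- avg$pattern[[which(avg$group == "A")]]
  expect_equal(unclass(a), unclass(p), ignore_attr = TRUE)
  expect_equal(avg$n[avg$group == "A"], 2L)
  two <- average_patterns(tibble::tibble(group = "C", limb = "x", muscle = "RF",
                                         pattern = list(p, -1 * p)))
  expect_equal(max(abs(two$pattern[[1]])), 0)
  expect_error(average_patterns(tbl[0, ]))
})

test_that("map export writes a readable, faithful long-form CSV", {
  ct <- cached_tiny_trial()
  p <- trial_pattern(ct$trial, "GM", ct$events)
  path <- withr::local_tempfile(fileext = ".csv")
  export_map(p, path)
  df <- read.csv(path)
  expect_setequal(unique(df$phase), c("take-off", "airborne", "landing"))
  expect_equal(sum(df$frame <= 100), 14 * 100)
  expect_true(all(df$value_scaled >= 0 & df$value_scaled <= 1))
  back <- read_map(path)
  expect_equal(back, unclass(p), ignore_attr = TRUE, tolerance = 1e-12)

  # constant pattern: display copy is all zeros by convention
  const <- matrix(3, 14, 300)
  export_map(const, path)
  expect_true(all(read.csv(path)$value_scaled == 0))
  expect_error(suppressWarnings(read_map(withr::local_tempfile(fileext = ".csv"))))
})
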