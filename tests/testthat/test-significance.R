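# independent oracle: tail probability by full enumeration of all 2^n
# equally likely success/failure sequences
enum_tail <- function(k, n) {
  counts <- vapply(0:(2^n - 1), function(code) {
    sum(bitwAnd(code, bitwShiftL(1L, 0:(n - 1))) > 0)
  }, numeric(1))
  mean(counts >= k)
}

test_that("exact binomial p-values match full enumeration for n <= 12", {
  for (n in c(5, 9, 12)) {
    for (k in 0:n) {
      expect_equal(binomial_pvalue(k, n), enum_tail(k, n), tolerance = 1e-12)
    }
  }
})

test_that("printed tail probabilities and edge cases are reproduced", {
  expect_equal(round(binomial_pvalue(17, 23), 4), 0.0173)
  expect_equal(binomial_pvalue(17, 23), 145499 / 2^23, tolerance = 1e-12)
  expect_equal(binomial_pvalue(23, 23), 0.5^23)
  expect_equal(binomial_pvalue(0, 23), 1)
  expect_error(binomial_pvalue(24, 23), "0..n")
  # two-sided doubles the smaller tail
  expect_equal(binomial_pvalue(17, 23, sidedness = "two"),
               2 * binomial_pvalue(17, 23))
})

test_that("Bonferroni adjustment divides alpha by the comparison count", {
  expect_equal(round(bonferroni_alpha(0.05, 3), 5), 0.01667)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(round(bonferroni_alpha(0.05, 6), 5), 0.00833)
})

test_that("critical rates match the documented conventions", {
  # normal approximation, one-sided, alpha 0.05/3: 17/23 = 73.9%
  cr <- critical_rate(23)
  expect_equal(cr$k_critical, 17L)
  expect_equal(cr$rate_percent, 73.9)
  # the z-computation behind it: k=17 significant, k=16 not
  expect_lt(hopwave:::normal_pvalue(17, 23), 0.05 / 3)
  expect_gt(hopwave:::normal_pvalue(16, 23), 0.05 / 3)
  # exact test, no adjustment: 16/23 = 69.6%
  cr2 <- critical_rate(23, method = "exact", m_comparisons = 1)
  expect_equal(cr2$k_critical, 16L)
  expect_equal(cr2$rate_percent, 69.6)
  # exact test at the adjusted alpha is stricter than the approximation
  expect_equal(critical_rate(23, method = "exact")$k_critical, 18L)
})

test_that("tiny-n critical count agrees with brute-force enumeration", {
  cr <- critical_rate(4, alpha = 0.5, m_comparisons = 1, method = "exact")
  ks <- 0:4
  tails <- vapply(ks, enum_tail, numeric(1), n = 4)
  expect_equal(cr$k_critical, min(ks[tails < 0.5]))
})

test_that("critical rate is monotone in alpha and comparison count", {
  ks_alpha <- vapply(c(0.01, 0.05, 0.2), function(a) {
    critical_rate(40, alpha = a, m_comparisons = 1)$k_critical
  }, integer(1))
  expect_true(all(diff(ks_alpha) <= 0))
  ks_m <- vapply(c(1, 3, 6), function(m) {
    critical_rate(40, m_comparisons = m)$k_critical
  }, integer(1))
  expect_true(all(diff(ks_m) >= 0))
})

test_that("exact and normal p-values converge for large n", {
  for (k in c(115, 125, 135)) {
    expect_lt(abs(binomial_pvalue(k, 200) - hopwave:::normal_pvalue(k, 200)),
              0.01)
  }
})

test_that("an unreachable significance level is an explicit error", {
  expect_error(critical_rate(3, alpha = 0.05, m_comparisons = 3,
                             method = "exact"),
               "minimum achievable")
})

test_that("verdicts use a strict greater-than rule", {
  res <- tibble::tibble(muscle = c("TA", "BF", "GM"),
                        n_correct = c(47, 44, 46), n_total = 62,
                        rate_percent = c(75.8, 71.0, 73.9))
  crit <- critical_rate(23)
  out <- judge_rates(res, crit)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_true(all(out$critical_rate_percent == 73.9))
  expect_equal(out$method[1], "normal")
  # per-row critical rates from each n_total
  out2 <- judge_rates(res, method = "normal")
  expect_true(all(out2$critical_rate_percent > 50))
})

test_that("the smallest detectable proportion reports its power", {
  dp <- detectable_proportion(23)
  expect_gt(dp$p_detectable, 0.5)
  expect_gte(dp$power_at_p, 0.8)
  expect_equal(dp$k_critical, 17L)
  # more subjects make smaller effects detectable
  expect_lt(detectable_proportion(100)$p_detectable, dp$p_detectable)
})
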