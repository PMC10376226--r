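#' Binomial tail p-value for a classification count
#'
#' Probability under `Binomial(n, p0)` of at least `k` successes (one-sided),
#' or twice the smaller tail capped at 1 (two-sided), computed from the exact
#' binomial mass.
#'
#' @param k Observed correct classifications (0..n).
#' @param n Number of classified units.
#' @param p0 Chance probability (default 0.5).
#' @param sidedness `"one"` or `"two"`.
#' @return The tail probability.
#' @examples
#' binomial_pvalue(17, 23)  # 0.0173
#' @export
binomial_pvalue <- function(k, n, p0 = 0.5, sidedness = "one") {
  sidedness <- match.arg(sidedness, c("one", "two"))
  if (k < 0 || k > n) stop("binomial_pvalue: k must be in 0..n", call. = FALSE)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  if (sidedness == "one") return(upper)
  lower <- pbinom(k, n, p0)
  min(1, 2 * min(upper, lower))
}

# One-sided normal-approximation p-value for a proportion against p0,
# no continuity correction.
normal_pvalue <- function(k, n, p0 = 0.5, sidedness = "one") {
  sidedness <- match.arg(sidedness, c("one", "two"))
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  p <- pnorm(z, lower.tail = FALSE)
  if (sidedness == "two") p <- min(1, 2 * min(p, pnorm(z)))
  p
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise significance level.
#' @param m_comparisons Number of comparisons (>= 1).
#' @return `alpha / m_comparisons`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m_comparisons = 3) {
  stopifnot(alpha > 0, alpha < 1, m_comparisons >= 1)
  alpha / m_comparisons
}

#' Critical classification rate
#'
#' The smallest count `k` (and its rate `100 k / n`) whose test p-value
#' against chance falls below the Bonferroni-adjusted alpha, under either the
#' exact binomial test or the one-sided normal approximation of a proportion
#' (no continuity correction). Under the defaults (n = 23, alpha 0.05, three
#' comparisons, normal approximation, one-sided) the critical rate is 73.9%
#' (k = 17); the exact test at the same adjusted alpha gives 18/23. The
#' method is recorded in the result so every verdict states its convention.
#'
#' @param n Number of classified units.
#' @param p0 Chance probability (default 0.5).
#' @param alpha Significance level before adjustment (default 0.05).
#' @param m_comparisons Comparisons for the Bonferroni adjustment (default 3).
#' @param method `"normal"` (normal approximation) or `"exact"`.
#' @param sidedness `"one"` (default) or `"two"`.
#' @return List with `k_critical`, `rate_percent` (1 decimal), `p_value` at
#'   the critical count, `alpha_adjusted`, `method`, `sidedness`, `n`.
#' @examples
#' critical_rate(23)$rate_percent  # 73.9
#' @export
critical_rate <- function(n, p0 = 0.5, alpha = 0.05, m_comparisons = 3,
                          method = "normal", sidedness = "one") {
  method <- match.arg(method, c("normal", "exact"))
  stopifnot(n >= 1)
  a <- bonferroni_alpha(alpha, m_comparisons)
  pfun <- if (method == "exact") binomial_pvalue else normal_pvalue
  for (k in 0:n) {
    p <- pfun(k, n, p0, sidedness)
    if (p < a) {
      return(list(k_critical = k, rate_percent = round(100 * k / n, 1),
                  p_value = p, alpha_adjusted = a, method = method,
                  sidedness = sidedness, n = n))
    }
  }
  stop(sprintf("critical_rate: no k <= n reaches significance (minimum achievable p = %.4g)",
               pfun(n, n, p0, sidedness)), call. = FALSE)
}

#' Judge classification rates against the critical rate
#'
#' A comparison is significant iff its rate strictly exceeds the critical
#' classification rate. The threshold and its convention are attached to
#' every row.
#'
#' @param results A `hop_classification` tibble (from [run_comparisons()]),
#'   or any tibble with a `rate_percent` column.
#' @param crit A [critical_rate()] result; computed from `...` when `NULL`.
#' @param ... Passed to [critical_rate()] when `crit` is `NULL`; `n` defaults
#'   to each row's `n_total`.
#' @return The input with `critical_rate_percent`, `significant`, `method`
#'   columns added.
#' @export
judge_rates <- function(results, crit = NULL, ...) {
  if (!is.null(crit)) {
    results$critical_rate_percent <- crit$rate_percent
    results$method <- crit$method
  } else {
    args <- list(...)
    per_n <- vapply(results$n_total, function(n) {
      do.call(critical_rate, c(list(n = n), args))$rate_percent
    }, numeric(1))
    results$critical_rate_percent <- per_n
    results$method <- (list(...)$method) %||% "normal"
  }
  results$significant <- results$rate_percent > results$critical_rate_percent
  results
}

#' Smallest detectable alternative proportion
#'
#' Power utility: given the critical count for `(n, alpha, m_comparisons,
#' method)`, the smallest true correct-classification probability whose
#' binomial power reaches `power`. Reported alongside critical rates, never
#' used as the significance threshold.
#'
#' @inheritParams critical_rate
#' @param power Target power (default 0.8).
#' @param step Search resolution on the probability scale.
#' @return List with `p_detectable`, `k_critical`, `power_at_p`.
#' @export
detectable_proportion <- function(n, p0 = 0.5, alpha = 0.05, m_comparisons = 3,
                                  method = "normal", sidedness = "one",
                                  power = 0.8, step = 1e-3) {
  crit <- critical_rate(n, p0, alpha, m_comparisons, method, sidedness)
  k <- crit$k_critical
  for (p1 in seq(p0, 1, by = step)) {
    pw <- pbinom(k - 1, n, p1, lower.tail = FALSE)
    if (pw >= power) {
      return(list(p_detectable = p1, k_critical = k, power_at_p = pw))
    }
  }
  list(p_detectable = 1, k_critical = k,
       power_at_p = pbinom(k - 1, n, 1, lower.tail = FALSE))
}
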