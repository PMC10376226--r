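#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; the two-tailed p-value comes from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3); pairs with missing values dropped.
#' @return Tibble with `r`, `p_value`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$r  # 0.6
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("pearson_cor: need at least 3 complete pairs",
                          call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson_cor: zero variance in x or y", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Group-wise summary of a subject outcome table
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of every
#' numeric column, per group, with 1-decimal reporting columns alongside the
#' full-precision values.
#'
#' @param outcomes Tibble with a `group` column plus numeric outcome columns.
#' @param by Grouping column (default `"group"`).
#' @return Tibble: `group`, `variable`, `n`, `mean`, `sd`, `mean_1dp`,
#'   `sd_1dp`.
#' @examples
#' summarize_cohort(hop_demographics())
#' @export
summarize_cohort <- function(outcomes, by = "group") {
  stopifnot(by %in% names(outcomes))
  if (any(table(outcomes[[by]]) < 2)) {
    stop("summarize_cohort: need at least 2 subjects per group", call. = FALSE)
  }
  num <- names(outcomes)[vapply(outcomes, is.numeric, logical(1))]
  outcomes |>
    tidyr::pivot_longer(dplyr::all_of(num), names_to = "variable",
                        values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "variable")))) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_1dp = round(.data$mean, 1), sd_1dp = round(.data$sd, 1))
}

#' Correlate outcomes against a degeneration score
#'
#' Pearson correlation of each candidate outcome against the score field,
#' two-tailed p-values, no multiplicity adjustment; missing values dropped
#' pairwise with the pair count reported.
#'
#' @param outcomes Subject outcome tibble.
#' @param score_field Name of the score column (e.g. `"worms_total"`).
#' @param vars Candidate columns; defaults to all other numeric columns.
#' @return Tibble: `variable`, `r`, `p_value`, `n`.
#' @export
correlate_outcomes <- function(outcomes, score_field = "worms_total",
                               vars = NULL) {
  stopifnot(score_field %in% names(outcomes))
  if (is.null(vars)) {
    num <- names(outcomes)[vapply(outcomes, is.numeric, logical(1))]
    vars <- setdiff(num, score_field)
  }
  purrr::map_dfr(vars, function(v) {
    res <- pearson_cor(outcomes[[v]], outcomes[[score_field]])
    dplyr::bind_cols(tibble::tibble(variable = v), res)
  })
}

#' Bidirectional stepwise linear regression
#'
#' Forward selection with backward elimination on ordinary-least-squares
#' fits: at each step the excluded candidate with the smallest partial-F
#' p-value is added if it falls below `alpha_enter` (alphabetical tie-break),
#' then any included term whose p-value exceeds `alpha_remove` is removed.
#' The standard ordering `alpha_remove >= alpha_enter` guarantees
#' termination. The full step log is returned.
#'
#' @param data Data frame of subjects.
#' @param response Name of the response column.
#' @param candidates Names of candidate predictor columns.
#' @param alpha_enter Entry threshold (default 0.05).
#' @param alpha_remove Removal threshold (default 0.10).
#' @return A `hop_stepwise` object: list with `model` (the final `lm`),
#'   `selected`, `intercept`, `coefficients`, `p_values`, `steps` (tibble
#'   log). Supports [tidy()] and [glance()].
#' @examples
#' d <- data.frame(y = 1:10 * 2 + 1, x = 1:10, z = rnorm(10))
#' stepwise_regression(d, "y", c("x", "z"))$selected
#' @export
stepwise_regression <- function(data, response, candidates,
                                alpha_enter = 0.05, alpha_remove = 0.10) {
  stopifnot(response %in% names(data), all(candidates %in% names(data)),
            alpha_remove >= alpha_enter)
  data <- data[stats::complete.cases(data[c(response, candidates)]), ]
  if (nrow(data) <= length(candidates) + 1) {
    stop("stepwise_regression: need more subjects than candidates + 1",
         call. = FALSE)
  }
  if (length(candidates) > 1) {
    cm <- abs(stats::cor(data[candidates]))
    diag(cm) <- 0
    if (any(cm > 0.9999)) {
      pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop(sprintf("stepwise_regression: collinear candidates %s and %s",
                   candidates[pair[1]], candidates[pair[2]]), call. = FALSE)
    }
  }
  included <- character(0)
  steps <- list()
  fit_with <- function(terms) {
    f <- stats::reformulate(if (length(terms)) terms else "1", response)
    lm(f, data = data)
  }
  term_p <- function(fit, term) {
    s <- summary(fit)$coefficients
    if (!term %in% rownames(s)) return(NA_real_)
    s[term, 4]
  }
  repeat {
    changed <- FALSE
    excl <- sort(setdiff(candidates, included))        # alphabetical tie rule
    if (length(excl)) {
      pv <- vapply(excl, function(v) term_p(fit_with(c(included, v)), v),
                   numeric(1))
      if (any(is.finite(pv)) && min(pv, na.rm = TRUE) < alpha_enter) {
        add <- excl[which.min(pv)]
        included <- c(included, add)
        steps[[length(steps) + 1]] <- tibble::tibble(
          step = length(steps) + 1L, action = "add", term = add,
          p_value = min(pv, na.rm = TRUE))
        changed <- TRUE
      }
    }
    repeat {
      if (!length(included)) break
      fit <- fit_with(included)
      pv <- vapply(included, function(v) term_p(fit, v), numeric(1))
      worst <- which.max(pv)
      if (is.finite(pv[worst]) && pv[worst] > alpha_remove) {
        steps[[length(steps) + 1]] <- tibble::tibble(
          step = length(steps) + 1L, action = "remove",
          term = included[worst], p_value = pv[worst])
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- fit_with(included)
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  structure(list(
    model = fit, selected = included,
    intercept = unname(cf["(Intercept)"]),
    coefficients = cf[setdiff(names(cf), "(Intercept)")],
    p_values = if (length(included)) sm[included, 4] else numeric(0),
    steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(step = integer(), action = character(),
                     term = character(), p_value = numeric())
  ), class = "hop_stepwise")
}

#' @export
print.hop_stepwise <- function(x, ...) {
  cat("<hop_stepwise> selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  if (length(x$selected)) {
    cat(sprintf("  intercept B0 = %.3g\n", x$intercept))
    for (v in x$selected) {
      cat(sprintf("  %s: beta = %.3g, p = %.3g\n", v, x$coefficients[v],
                  x$p_values[v]))
    }
  }
  invisible(x)
}

#' @export
tidy.hop_stepwise <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.hop_stepwise <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, df.residual = x$model$df.residual,
                 n_selected = length(x$selected),
                 nobs = length(x$model$residuals))
}
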