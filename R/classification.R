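#' Vectorize a normalized pattern for classification
#'
#' Row-major flattening of the bands x frames sub-matrix selected by the
#' phase scope: all 300 frames (length 4200) or one 100-frame phase
#' (length 1400).
#'
#' @param pattern A `hop_pattern` (bands x 300 matrix).
#' @param phase_scope `"all"`, `"take-off"`, `"airborne"` or `"landing"`.
#' @return Numeric feature vector.
#' @export
vectorize_pattern <- function(pattern, phase_scope = "all") {
  phase_scope <- match.arg(phase_scope,
                           c("all", "take-off", "airborne", "landing"))
  m <- unclass(pattern)
  fpp <- ncol(m) / 3
  cols <- switch(phase_scope,
                 "all" = seq_len(ncol(m)),
                 "take-off" = seq_len(fpp),
                 "airborne" = fpp + seq_len(fpp),
                 "landing" = 2 * fpp + seq_len(fpp))
  as.vector(t(m[, cols, drop = FALSE]))
}

#' 1-nearest-neighbor classification with leave-one-out cross-validation
#'
#' Every held-out unit is predicted by the label of the Euclidean-nearest
#' remaining feature vector (k = 1); exact distance ties are broken by the
#' lowest sample index. With `cv_unit = "subject"` all vectors sharing a unit
#' id are held out together (grouped LOOCV), preventing same-subject trials
#' from leaking between folds; `cv_unit = "trial"` holds out single vectors.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Class label per row (2 classes, >= 2 samples per class).
#' @param units Unit (subject) id per row; required for grouped CV.
#' @param cv_unit `"subject"` or `"trial"`.
#' @return Tibble with `n_correct`, `n_total`, `rate_percent` (1 decimal).
#' @examples
#' f <- matrix(c(0, 1, 10, 11), ncol = 1)
#' knn_loocv(f, c("A", "A", "B", "B"), cv_unit = "trial")
#' @export
knn_loocv <- function(features, labels, units = NULL, cv_unit = "subject") {
  cv_unit <- match.arg(cv_unit, c("subject", "trial"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2) stop("knn_loocv: need at least 2 samples", call. = FALSE)
  if (length(labels) != n) stop("knn_loocv: labels/features mismatch", call. = FALSE)
  if (length(unique(labels)) < 2 || min(table(labels)) < 2) {
    stop("knn_loocv: need at least 2 samples per class", call. = FALSE)
  }
  if (cv_unit == "subject") {
    if (is.null(units)) stop("knn_loocv: units required for subject-level CV",
                             call. = FALSE)
  } else {
    units <- seq_len(n)
  }
  d2 <- squared_distances(features)
  correct <- logical(n)
  for (i in seq_len(n)) {
    cand <- which(units != units[i])
    if (length(cand) == 0) stop("knn_loocv: empty training fold", call. = FALSE)
    j <- cand[which.min(d2[i, cand])]     # lowest index wins exact ties
    correct[i] <- identical(labels[j], labels[i])
  }
  nc <- sum(correct)
  tibble::tibble(n_correct = nc, n_total = n,
                 rate_percent = round(100 * nc / n, 1))
}

squared_distances <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, `+`) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

# The three pair-wise comparisons: each selects two (group, limb) cells.
comparison_table <- function() {
  tibble::tibble(
    comparison = c("Control_Idx vs Control_Contra",
                   "ACLR_Sx vs ACLR_Contra",
                   "ACLR_Contra vs Control_Idx"),
    group_a = c("Control", "ACLR", "ACLR"),
    limb_a = c("index", "index", "contra"),
    group_b = c("Control", "ACLR", "Control"),
    limb_b = c("contra", "contra", "index")
  )
}

#' Run the per-muscle pair-wise classification grid
#'
#' For each muscle, pair-wise comparison and phase scope, vectorizes the
#' patterns of the two (group, limb) cells and runs 1-NN leave-one-out
#' cross-validation. The three comparisons are: control index vs control
#' contralateral (bilateral symmetry in controls), ACLR surgical vs ACLR
#' contralateral (bilateral symmetry in ACLR), and ACLR contralateral vs
#' control index (group difference).
#'
#' @param patterns Tibble from [cohort_patterns()].
#' @param comparisons Subset of comparison names (default all three).
#' @param phase_scopes Subset of `"all"`, `"take-off"`, `"airborne"`,
#'   `"landing"` (default all four).
#' @param muscles Muscles to classify (default all 7).
#' @param cv_unit `"subject"` (grouped LOOCV, default) or `"trial"`.
#' @return A `hop_classification` tibble: one row per muscle x comparison x
#'   phase scope with `n_correct`, `n_total`, `rate_percent`.
#' @export
run_comparisons <- function(patterns,
                            comparisons = comparison_table()$comparison,
                            phase_scopes = c("all", "take-off", "airborne",
                                             "landing"),
                            muscles = MUSCLES,
                            cv_unit = "subject") {
  ct <- comparison_table()
  ct <- ct[ct$comparison %in% comparisons, ]
  if (nrow(ct) == 0) stop("run_comparisons: unknown comparison", call. = FALSE)
  out <- list()
  for (ci in seq_len(nrow(ct))) {
    sel_a <- patterns$group == ct$group_a[ci] & patterns$limb == ct$limb_a[ci]
    sel_b <- patterns$group == ct$group_b[ci] & patterns$limb == ct$limb_b[ci]
    sub <- patterns[sel_a | sel_b, ]
    cls <- ifelse(sub$group == ct$group_a[ci] & sub$limb == ct$limb_a[ci],
                  "A", "B")
    for (m in muscles) {
      rows <- sub$muscle == m
      if (!any(rows)) next
      pats <- sub$pattern[rows]
      labs <- cls[rows]
      ids <- sub$subject_id[rows]
      key <- vapply(pats, function(p) {
        v <- unclass(p)
        paste(signif(c(sum(v), v[1:4]), 10), collapse = ",")
      }, character(1))
      if (length(intersect(key[labs == "A"], key[labs == "B"]))) {
        warning(sprintf("run_comparisons: possible data leakage - identical %s patterns appear in both classes",
                        m), call. = FALSE)
      }
      for (sc in phase_scopes) {
        feats <- do.call(rbind, lapply(pats, vectorize_pattern, phase_scope = sc))
        res <- knn_loocv(feats, labs, ids, cv_unit)
        out[[length(out) + 1]] <- tibble::tibble(
          comparison = ct$comparison[ci], muscle = m, phase_scope = sc,
          n_correct = res$n_correct, n_total = res$n_total,
          rate_percent = res$rate_percent)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("hop_classification", class(res))
  res
}
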