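#' Plot a normalized wavelet pattern
#'
#' Band-by-frame intensity map with the two phase boundaries marked; the
#' display convention rescales intensity to `[0, 1]` (a constant pattern maps
#' to 0).
#'
#' @param object A `hop_pattern`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hop_pattern <- function(object, ...) {
  m <- unclass(object)
  rng <- range(m)
  scaled <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
  bf <- attr(object, "band_freqs") %||% seq_len(nrow(m))
  df <- tidyr::expand_grid(band = seq_len(nrow(m)), frame = seq_len(ncol(m)))
  df$value <- scaled[cbind(df$band, df$frame)]
  fpp <- ncol(m) / 3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$band,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = c(fpp, 2 * fpp) + 0.5,
                        colour = "cyan", linewidth = 0.4) +
    ggplot2::scale_y_continuous(breaks = seq_len(nrow(m)),
                                labels = round(bf, 1)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "intensity") +
    ggplot2::labs(x = "normalized time (100 frames per phase)",
                  y = "wavelet central frequency (Hz)",
                  title = attr(object, "muscle")) +
    ggplot2::theme_minimal()
}

#' Plot classification rates against the critical rate
#'
#' @param object A `hop_classification` tibble (ideally after
#'   [judge_rates()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hop_classification <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$muscle,
                                        y = .data$rate_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(
      rows = if ("phase_scope" %in% names(df)) ggplot2::vars(.data$phase_scope) else NULL,
      cols = ggplot2::vars(.data$comparison)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::labs(y = "correct classification (%)", x = NULL) +
    ggplot2::theme_minimal()
  if ("critical_rate_percent" %in% names(df)) {
    p <- p + ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$critical_rate_percent),
      colour = "firebrick", linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a classification grid
#'
#' @param x A `hop_classification`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.hop_classification <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "hop_classification")
  out
}

#' One-line summary of a classification grid
#'
#' @param x A `hop_classification`.
#' @param ... Unused.
#' @return Tibble with grid size and rate range; includes the significant
#'   count when verdicts are present.
#' @export
glance.hop_classification <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_muscles = length(unique(x$muscle)),
    min_rate = min(x$rate_percent),
    max_rate = max(x$rate_percent),
    n_significant = if ("significant" %in% names(x)) sum(x$significant)
    else NA_integer_
  )
}
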