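#' Plot a row profile
#'
#' Scatter plots of the raw, normalized and binarized black-pixel profiles
#' of a strip, faceted vertically — the same three views used when tuning
#' the transition criterion by eye. An optional detected transition row is
#' marked with a vertical line.
#'
#' @param object A `ring_profile` tibble from [row_profile()].
#' @param transition_row Optional row index to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ring_profile
#' @export
autoplot.ring_profile <- function(object, transition_row = NULL, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(row = object$row, value = object$count,
                   panel = "raw count"),
    tibble::tibble(row = object$row, value = object$normalized,
                   panel = "normalized (0-100)"),
    tibble::tibble(row = object$row, value = object$binarized,
                   panel = "binarized at 60")
  )
  long$panel <- factor(long$panel, levels = c("raw count",
                                              "normalized (0-100)",
                                              "binarized at 60"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$row, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "row (top to bottom)", y = NULL,
                  title = sprintf("Row black-pixel profile (slope %.4g)",
                                  attr(object, "slope") %||% 0))
  if (!is.null(transition_row) && !is.na(transition_row)) {
    p <- p + ggplot2::geom_vline(xintercept = transition_row,
                                 colour = "red", linetype = 2)
  }
  p
}

#' @rdname autoplot.ring_profile
#' @param x A `ring_profile`.
#' @export
plot.ring_profile <- function(x, ...) print(autoplot.ring_profile(x, ...))

#' Plot per-strip verdicts of a slide
#'
#' One tile per strip, left to right as in the slide, filled by whether the
#' transition criterion fired; the subtitle reports the aggregated distinct
#' degree and IAWA code.
#'
#' @param object A `ring_verdict` from [classify_slide()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ring_verdict
#' @export
autoplot.ring_verdict <- function(object, ...) {
  d <- object$strips
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strip_index, y = 1,
                                  fill = .data$distinct)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#8c1f1f",
                                          `FALSE` = "#f2d8c9"),
                               name = "distinct") +
    ggplot2::scale_x_continuous(breaks = d$strip_index) +
    ggplot2::labs(
      x = "strip (left to right)", y = NULL,
      title = "Per-strip growth-ring boundary verdicts",
      subtitle = sprintf("distinct degree %.0f%% - %s (IAWA %s)",
                         object$distinct_degree, object$label,
                         object$iawa_code)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @rdname autoplot.ring_verdict
#' @param x A `ring_verdict`.
#' @export
plot.ring_verdict <- function(x, ...) print(autoplot.ring_verdict(x, ...))
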