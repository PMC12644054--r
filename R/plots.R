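# ggplot2 visual summaries for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training history
#'
#' Loss terms and validation scores per epoch.
#'
#' @param object a `sleepgraph_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sleepgraph_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$metric != "lr", ]
  d$panel <- ifelse(startsWith(d$metric, "loss"), "loss", "validation")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "sleepgraph training history") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Per-class precision/recall/F1 bars plus aggregate annotations.
#'
#' @param object a `sleepgraph_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sleepgraph_eval <- function(object, ...) {
  d <- tidy(object)
  pc <- d[!is.na(d$class) & d$metric %in% c("precision", "recall", "f1"), ]
  ggplot2::ggplot(pc, ggplot2::aes(x = factor(.data$class), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "class", y = NULL,
                  title = sprintf("accuracy %.3f | macro-F1 %.3f | kappa %.3f",
                                  object$classification$accuracy,
                                  object$classification$macro_f1,
                                  object$classification$kappa)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated session
#'
#' Audio envelope (per-window RMS), window labels, and planted event spans.
#'
#' @param object a `sleepgraph_session`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sleepgraph_session <- function(object, ...) {
  w <- object$windows
  rms <- vapply(seq_len(nrow(w)), function(i) {
    idx <- seq(max(1, floor(w$start[i] * object$sample_rate) + 1),
               min(length(object$audio), ceiling(w$end[i] * object$sample_rate)))
    sqrt(mean(object$audio[idx]^2))
  }, numeric(1))
  d <- tibble::tibble(time = (w$start + w$end) / 2, rms = rms,
                      label = factor(w$label))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$rms)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 2) +
    ggplot2::labs(x = "time (s)", y = "window RMS",
                  title = sprintf("simulated session (seed %d)", object$seed)) +
    ggplot2::theme_minimal()
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$events,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = factor(.data$label)),
      alpha = 0.12, inherit.aes = FALSE) +
      ggplot2::guides(fill = "none")
  }
  p
}
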