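#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Per-axis coordinate traces over time.
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("x", "y", "z"),
                              names_to = "axis", values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$position,
                                     colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "position [m]", colour = "axis") +
    ggplot2::theme_minimal()
}

#' Plot all target points of a trajectory set
#'
#' @param object A `trajectory_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_set <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("x", "y", "z"),
                              names_to = "axis", values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$position,
                                     colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~point) +
    ggplot2::labs(x = "time [s]", y = "position [m]") +
    ggplot2::theme_minimal()
}

#' Plot a quality score against its ideal values
#'
#' @param object A `quality_score`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quality_score <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$component, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$ideal), shape = 4, size = 3) +
    ggplot2::labs(y = "score (x marks the ideal)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy %.1f%%", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
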