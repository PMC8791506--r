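#' Plot a bistability sweep
#'
#' The classic bistability diagram: normalized steady-state output against
#' the input law's total concentration (log2 axis), one point per replicate,
#' open symbols marking non-converged relaxations. Two distinct clusters of
#' points at interior grid values are the visual signature of bistability.
#'
#' @param object a `ptm_sweep`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ptm_sweep <- function(object, ...) {
  tbl <- object$tbl
  ggplot2::ggplot(tbl, ggplot2::aes(x = log2(.data$omega), y = .data$value,
                                    shape = .data$converged)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = expression(log[2] ~ "input total concentration (mmol/m³)"),
      y = "normalized output",
      title = "Monte-Carlo steady-state sweep"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the variance vector of a sweep
#'
#' @param result a `ptm_sweep`.
#' @return A ggplot object.
#' @export
plot_variance_vector <- function(result) {
  V <- variance_vector(result)
  df <- tibble::tibble(position = seq_along(V), V = V)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$V)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "grid position", y = "fourfold variance",
                  title = "Degree of bistability along the input sweep") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the score trajectory of a search
#'
#' @param object a `ptm_trace`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ptm_trace <- function(object, ...) {
  tb <- object$trace
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$iteration, y = .data$score)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "search iteration", y = "evaluation score",
                  title = "Accepted steps of the partition-space search") +
    ggplot2::theme_minimal()
}
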