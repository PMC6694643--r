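#' Plot a prevalence table
#'
#' Bar chart of prevalence per stratum, dodged by study arm when the table
#' was computed by group. Percentages on the y axis.
#'
#' @param object A `prevalence_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prevalence_table <- function(object, ...) {
  dat <- tibble::as_tibble(object) |> dplyr::filter(!.data$empty)
  p <- if (isTRUE(attr(object, "by_group"))) {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$stratum, y = .data$q,
                                      fill = .data$group)) +
      ggplot2::geom_col(position = "dodge")
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$stratum, y = .data$q)) +
      ggplot2::geom_col()
  }
  p +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "prevalence among relatives") +
    ggplot2::theme_minimal()
}

#' Plot a replication report
#'
#' Heritability per degree of relatedness with normal-theory 95% intervals,
#' the core stratified result of the analysis.
#'
#' @param object A `replication_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.replication_report <- function(object, ...) {
  h <- tidy_heritability(object$heritability)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$stratum, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.15
    ) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = expression(h^2 ~ "of liability")) +
    ggplot2::theme_minimal()
}
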