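#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Volcano plot of a differential-abundance result
#'
#' Log2 fold change against -log10 p-value, colored by direction.
#'
#' @param object An `isomir_de` tibble from [de_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.isomir_de <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(.data$p_value),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::scale_colour_manual(values = c(down = "#2166ac",
                                            up = "#b2182b",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change (case / control)"),
                  y = expression(-log[10] ~ "p-value"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname doubling_time
#' @param object A `growth_fit` object.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b", linewidth = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "cell count (log scale)") +
    ggplot2::theme_minimal()
}

#' 5'-offset profile of classified reads
#'
#' Read-weighted distribution of 5' offsets among assigned reads, per
#' sample or condition, as a bar chart; the bar at 0 is the canonical 5'
#' end, positive offsets are upstream (extended) cleavage.
#'
#' @param calls A call tibble from [classify_reads()] or several bound
#'   together with a `group` column.
#' @param group Optional name of a column to facet by.
#' @return A ggplot object.
#' @export
plot_offset_profile <- function(calls, group = NULL) {
  d <- calls |>
    filter(!is.na(.data$offset5)) |>
    group_by(across(any_of(c(group, "offset5")))) |>
    summarise(reads = sum(.data$count), .groups = "drop_last") |>
    mutate(fraction = .data$reads / sum(.data$reads)) |>
    ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$offset5,
                                       y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "5' offset (nt, + = upstream/extended)",
                  y = "fraction of assigned reads") +
    ggplot2::theme_minimal()
  if (!is.null(group)) {
    p <- p + ggplot2::facet_wrap(group)
  }
  p
}
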