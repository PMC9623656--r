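#' Plot accuracy against average herd size
#'
#' Draws the accuracy of each evaluation model as a function of the realized
#' average herd size, one line per herd treatment, faceted by method when
#' more than one is present; the ribbon is the 95% interval over replicates.
#'
#' @param summary An [summarize_accuracy()] table.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(summary) {
  stopifnot(inherits(summary, "accuracy_summary") ||
              all(c("mean_herd_size", "accuracy", "herd_model")
                  %in% names(summary)))
  p <- ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$mean_herd_size, y = .data$accuracy,
                 colour = .data$herd_model, fill = .data$herd_model)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = c(1, 2, 4, 8, 16)) +
    ggplot2::labs(x = "Average herd size (cows)",
                  y = "Accuracy (cor(EBV, TBV))",
                  colour = "Herd effect", fill = "Herd effect") +
    ggplot2::theme_minimal()
  if (length(unique(summary$method)) > 1) {
    p <- p + ggplot2::facet_wrap(~method)
  }
  p
}

#' @rdname plot_accuracy
#' @param object An `accuracy_summary`.
#' @param ... Unused.
#' @export
autoplot.accuracy_summary <- function(object, ...) plot_accuracy(object)

#' Plot the realized herd-size distribution
#'
#' @param sizes Integer herd sizes from [sample_herd_sizes()].
#' @return A ggplot histogram annotated with the realized mean.
#' @export
plot_herd_sizes <- function(sizes) {
  df <- tibble(size = sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = mean(sizes), linetype = 2) +
    ggplot2::labs(x = "Herd size (cows)", y = "Herds",
                  subtitle = paste0("mean = ", round(mean(sizes), 3))) +
    ggplot2::theme_minimal()
}
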