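# ggplot2 views of the main result objects.

#' Plot individual slopes coloured by bootstrap classification
#'
#' One panel per effect: horizontally jittered individual slopes by
#' group, coloured by the bootstrap label, with the group mean overlaid —
#' the standard display of individual-prevalence results.
#'
#' @param classifications Output of [classify_participants()].
#' @param effects Effects to show.
#' @return A ggplot object.
#' @export
plot_slopes <- function(classifications, effects = c("nde", "nse")) {
  df <- dplyr::filter(classifications, .data$effect %in% effects)
  means <- df |>
    dplyr::group_by(.data$group, .data$effect) |>
    dplyr::summarise(empirical_slope = mean(.data$empirical_slope),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group,
                                   y = .data$empirical_slope)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$label),
                         width = 0.2, height = 0, alpha = 0.8) +
    ggplot2::geom_point(data = means, size = 3, shape = 18,
                        colour = "black") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~ .data$effect, scales = "free_y",
                        labeller = ggplot2::labeller(
                          effect = c(nde = "Distance effect",
                                     nse = "Size effect"))) +
    ggplot2::labs(x = "Group", y = "Slope (ms / unit)",
                  colour = "Bootstrap label") +
    ggplot2::theme_minimal()
}

#' Autoplot method for bootstrap classifications
#'
#' @param object Output of [classify_participants()].
#' @param ... Passed to [plot_slopes()].
#' @return A ggplot object.
#' @export
autoplot.mag_classification <- function(object, ...) {
  plot_slopes(object, ...)
}

#' Plot a participant's H0 null distribution against the observed slope
#'
#' Histogram of the bootstrap null slopes with the central 90% interval
#' shaded and the empirical slope marked; the visual counterpart of
#' [classify_slope()].
#'
#' @param boot Output of [h0_bootstrap()].
#' @param empirical_slope Observed slope to mark.
#' @param effect `"nde"` or `"nse"`.
#' @param ci Interval mass to shade.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(boot, empirical_slope,
                                   effect = c("nde", "nse"), ci = 0.90) {
  effect <- match.arg(effect)
  col <- paste0(effect, "_slope")
  q <- quantile(boot[[col]], c((1 - ci) / 2, (1 + ci) / 2), type = 7)
  ggplot2::ggplot(boot, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = q, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = empirical_slope, colour = "red") +
    ggplot2::labs(
      x = sprintf("%s null slope (ms / unit)", toupper(effect)),
      y = "Bootstrap iterations",
      title = sprintf("Observed slope %.1f vs central %.0f%% of H0",
                      empirical_slope, 100 * ci)
    ) +
    ggplot2::theme_minimal()
}
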