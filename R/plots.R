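#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_raster geom_hline labs scale_fill_viridis_c facet_wrap theme_minimal
#' @importFrom rlang .data
NULL

#' Plot degeneration curves
#'
#' Mean +/- SD of each recorded metric as a function of the injured
#' fraction, one panel per metric — the standard degeneration-curve view
#' (accuracy decay, tau-a decay, within-superclass error drift).
#'
#' @param object A `degeneration_experiment` (or its summaries tibble via
#'   [plot_degeneration()]).
#' @param metrics Character subset of metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.degeneration_experiment <- function(object,
                                             metrics = c(
                                               "accuracy",
                                               "within_superclass_error_rate",
                                               "tau_a_object",
                                               "tau_a_superclass"),
                                             ...) {
  plot_degeneration(object$summaries, metrics = metrics)
}

#' @rdname autoplot.degeneration_experiment
#' @param summaries A summaries tibble from [summarize_records()].
#' @export
plot_degeneration <- function(summaries,
                              metrics = c("accuracy",
                                          "within_superclass_error_rate",
                                          "tau_a_object",
                                          "tau_a_superclass")) {
  df <- dplyr::filter(summaries, .data$metric %in% metrics)
  ggplot(df, aes(x = .data$injured_fraction, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd), alpha = 0.25) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "Injured fraction", y = "Mean across replicates (+/- SD)") +
    theme_minimal()
}

#' Plot an RDM as a heat map
#'
#' @param object An `rdm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  n <- nrow(object$D)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$dissimilarity <- as.vector(object$D)[(df$j - 1L) * n + df$i]
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$dissimilarity)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 2)) +
    labs(x = NULL, y = NULL, fill = "1 - r") +
    theme_minimal()
}
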