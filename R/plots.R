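#' @importFrom rlang .data
NULL

#' Plot lesion curves
#'
#' Accuracy against the fraction of synapses removed, one line per
#' removal ordering.
#'
#' @param object A `lesion_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lesion_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fraction, .data$accuracy,
                                       colour = .data$ordering)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of synapses removed", y = "accuracy",
                  colour = "removal order") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the information/energy trade-off
#'
#' Mutual information against synaptic energy for every
#' (variant, lambda, seed) point of an energy experiment.
#'
#' @param object An `info_energy` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.info_energy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$energy,
                                       .data$mutual_information,
                                       colour = .data$variant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "synaptic energy (sum |p m|)",
                  y = "mutual information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a lifelong-learning accuracy matrix
#'
#' Per-task test accuracy at each checkpoint (after each task), one line
#' per task; facets by variant if several are stacked.
#'
#' @param object An `accuracy_matrix` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accuracy_matrix <- function(object, ...) {
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(.data$checkpoint, .data$accuracy,
                                     colour = factor(.data$task))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "tasks learned", y = "test accuracy",
                  colour = "task") +
    ggplot2::theme_minimal()
  if (length(unique(object$variant)) > 1) {
    gg <- gg + ggplot2::facet_wrap(~variant)
  }
  gg
}

#' Release-probability histogram plot
#'
#' @param net A `stoch_net`, or a tibble from
#'   [release_probability_histogram()].
#' @param ... Passed to [release_probability_histogram()].
#' @return A ggplot.
#' @export
plot_release_probabilities <- function(net, ...) {
  h <- if (inherits(net, "stoch_net")) {
    release_probability_histogram(net, ...)
  } else net
  ggplot2::ggplot(h, ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(width = 0.045) +
    ggplot2::geom_vline(xintercept = 0.9, linetype = "dashed") +
    ggplot2::labs(x = "release probability", y = "synapses") +
    ggplot2::theme_minimal()
}
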