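#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ITPC spectrum
#'
#' Electrode-averaged ITPC against frequency with the four frequencies of
#' interest marked.
#'
#' @param object an `ft_itpc`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ft_itpc <- function(object, ...) {
  df <- dplyr::summarise(dplyr::group_by(tidy(object), .data$freq),
                         itpc = mean(.data$itpc), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$itpc)) +
    ggplot2::geom_vline(xintercept = foi_set()$freq, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "ITPC (electrode average)") +
    ggplot2::theme_minimal()
}

#' Plot a modulation spectrum
#'
#' @param object an `ft_modspec`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ft_modspec <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_vline(xintercept = c(4 / 3, 8 / 3, 4, 16 / 3),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Modulation frequency (Hz)", y = "Normalised power") +
    ggplot2::theme_minimal()
}

#' Plot cluster permutation results on the montage
#'
#' Scalp map of per-electrode t values with significant-cluster electrodes
#' circled.
#'
#' @param object an `ft_clusters`.
#' @param montage the electrode layout used for the test.
#' @param alpha significance level for highlighting clusters.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ft_clusters <- function(object, montage = make_montage(),
                                 alpha = 0.05, ...) {
  df <- dplyr::mutate(montage, t = attr(object, "t_obs")[montage$label])
  sig <- unlist(object$electrodes[object$p <= alpha])
  df$significant <- df$label %in% sig
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t), size = 5) +
    ggplot2::geom_point(data = df[df$significant, ], shape = 21, size = 7,
                        stroke = 1) +
    ggplot2::scale_colour_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Per-electrode paired t", colour = "t") +
    ggplot2::theme_void()
}

#' Plot the simulated 2AFC chance null
#'
#' Histogram of simulated guessing accuracies with the 95th-percentile
#' cutoff.
#'
#' @param object an `ft_null`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ft_null <- function(object, ...) {
  df <- tibble::tibble(accuracy = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 1 / 36, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Accuracy under guessing", y = "Simulations") +
    ggplot2::theme_minimal()
}
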