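#' Plot a decoding-accuracy time course
#'
#' Overall accuracy with a SEM ribbon, the shuffle-estimated chance curve,
#' and optionally the per-expression accuracies.
#'
#' @param object A `decoding_timecourse`.
#' @param per_expression Overlay the per-expression accuracy curves.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decoding_timecourse
#' @export
autoplot.decoding_timecourse <- function(object, per_expression = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$center, y = .data$accuracy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$accuracy - .data$se,
                   ymax = .data$accuracy + .data$se),
      fill = "grey70", alpha = 0.5
    ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Window center (ms)", y = "Decoding accuracy") +
    ggplot2::theme_minimal()
  if (!all(is.na(object$chance))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$chance),
                                colour = "grey50", linetype = 2)
  }
  if (per_expression) {
    long <- tidyr::pivot_longer(
      tibble::as_tibble(object),
      dplyr::all_of(c("acc_open_mouth", "acc_neutral", "acc_pout_lips")),
      names_to = "expression", values_to = "acc",
      names_prefix = "acc_"
    )
    p <- p + ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$acc, colour = .data$expression)
    )
  }
  p
}

#' Plot the count of expression-differentiating neurons over time
#'
#' One line per significance criterion; optional horizontal null-percentile
#' thresholds from [shuffle_null_percentiles()].
#'
#' @param object A `sig_counts` tibble.
#' @param null_percentiles Optional result of [shuffle_null_percentiles()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sig_counts
#' @export
autoplot.sig_counts <- function(object, null_percentiles = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$center, y = .data$count,
    colour = factor(.data$alpha)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Window center (ms)", y = "Significant neurons",
                  colour = "criterion") +
    ggplot2::theme_minimal()
  if (!is.null(null_percentiles)) {
    p <- p +
      ggplot2::geom_hline(yintercept = null_percentiles$p95, linetype = 2) +
      ggplot2::geom_hline(yintercept = null_percentiles$p99, linetype = 3)
  }
  p
}

#' Plot an SF-by-size tuning surface
#'
#' SF tuning curves on a log2 axis, one per stimulus size; how the curve
#' peak moves with size distinguishes retina-based from image-based frames.
#'
#' @param object A `tuning_surface` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tuning_surface
#' @export
autoplot.tuning_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sf, y = .data$rate,
    colour = factor(.data$size), group = factor(.data$size)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(trans = "log2", breaks = SF_CENTERS) +
    ggplot2::labs(x = "Image-based SF (cycles/image)", y = "Rate (sp/s)",
                  colour = "size (deg)") +
    ggplot2::theme_minimal()
}

#' Plot weighted-sum time courses per expression
#'
#' @param object A `weighted_sum_timecourse` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot weighted_sum_timecourse
#' @export
autoplot.weighted_sum_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$center, y = .data$weighted_sum, colour = .data$expression
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      open_mouth = "#E69F00", neutral = "black", pout_lips = "#56B4E9"
    )) +
    ggplot2::labs(x = "Window center (ms)", y = "Weighted sum") +
    ggplot2::theme_minimal()
}
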