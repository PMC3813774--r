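#' Fetal-weight frequency distribution curves
#'
#' Gaussian frequency curves per (genotype, treatment) cell, scaled to
#' expected bin counts, with an optional vertical line at the centile
#' threshold — the classic growth-restriction figure.
#'
#' @param fetuses Tibble with `fetal_weight`, `genotype`, `treatment`.
#' @param threshold Optional threshold (g) to mark.
#' @param bin_width Bin width used for the count scaling (g).
#' @return A ggplot object.
#' @export
plot_weight_distributions <- function(fetuses, threshold = NULL,
                                      bin_width = 0.05) {
  curves <- fetuses |>
    dplyr::group_by(.data$genotype, .data$treatment) |>
    dplyr::group_modify(function(d, key) {
      m <- mean(d$fetal_weight); s <- stats::sd(d$fetal_weight)
      x <- seq(m - 4 * s, m + 4 * s, length.out = 200)
      tibble::tibble(x = x,
                     y = nrow(d) * bin_width * stats::dnorm(x, m, s))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(cell = paste(.data$genotype, .data$treatment))
  p <- ggplot2::ggplot(curves, ggplot2::aes(.data$x, .data$y,
                                            colour = .data$cell)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Fetal weight (g)", y = "Expected pups per bin",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot plasma samples with the fitted disappearance curve
#'
#' @param samples Tibble with `time` and `concentration`.
#' @param fit A `decay_fit`.
#' @return A ggplot object.
#' @export
plot_disappearance <- function(samples, fit) {
  grid <- tibble::tibble(
    time = seq(0, max(samples$time), length.out = 200))
  grid$concentration <- fit$plateau +
    (fit$C0 - fit$plateau) * exp(-fit$k * grid$time)
  ggplot2::ggplot(samples, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Time since injection (min)",
                  y = "Plasma tracer (dpm/µl)",
                  subtitle = sprintf("C0 = %.3g, k = %.3g /min, r² = %.3f",
                                     fit$C0, fit$k, fit$r2)) +
    ggplot2::theme_minimal()
}

#' Plot a velocity trace with detected systolic peaks
#'
#' @param object A `velocity_trace`.
#' @param prominence Peak prominence fraction passed to [detect_cycles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.velocity_trace <- function(object, prominence = 0.2, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time, .data$velocity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "Time (s)", y = "Velocity (mm/s)") +
    ggplot2::theme_minimal()
  segs <- try(detect_cycles(object, prominence = prominence), silent = TRUE)
  if (!inherits(segs, "try-error")) {
    peaks <- tibble::tibble(time = unique(c(segs$start, segs$end)))
    peaks$velocity <- object$velocity[match(peaks$time, object$time)]
    p <- p + ggplot2::geom_point(data = peaks, colour = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
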