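#' Dose-response histograms per condition
#'
#' Overlaid per-condition expression histograms — the single-cell view
#' of the promoter channel that the capacity estimate is computed from.
#'
#' @param data Dose-response tibble.
#' @param reporter `"yfp"` or `"cfp"`.
#' @param bins Histogram bin count (display only; default 40).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(data, reporter = "yfp", bins = 40) {
  data <- check_dataset(data, min_cells = 1L)
  ggplot2::ggplot(data, ggplot2::aes(x = pmax(.data[[reporter]], 0),
                                     fill = .data$condition)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = paste(toupper(reporter), "expression (AU)"),
                  y = "cells", fill = "condition") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_dose_response Per-bin-count capacities of a sweep,
#'   with the reported mean +/- sd band.
#' @param object A `capacity_estimate`.
#' @param ... Unused.
#' @export
autoplot.capacity_estimate <- function(object, ...) {
  ggplot2::ggplot(object$per_bin,
                  ggplot2::aes(x = .data$n_bins, y = .data$capacity_bits)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$capacity_bits - object$std_bits,
                      ymax = object$capacity_bits + object$std_bits,
                      alpha = 0.15) +
    ggplot2::geom_hline(yintercept = object$capacity_bits, linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "response bins",
                  y = "jackknife-corrected capacity (bits)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_dose_response Raw vs intrinsic capacity bars.
#' @export
autoplot.intrinsic_estimate <- function(object, ...) {
  df <- tibble::tibble(
    which = factor(c("raw", "intrinsic"), levels = c("raw", "intrinsic")),
    bits = c(if (is.null(object$raw)) NA_real_ else object$raw$capacity_bits,
             object$intrinsic$capacity_bits),
    sd = c(if (is.null(object$raw)) NA_real_ else object$raw$std_bits,
           object$intrinsic$std_bits))
  df <- df[!is.na(df$bits), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$which, y = .data$bits)) +
    ggplot2::geom_col(width = 0.6, fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$bits - .data$sd,
                                        ymax = .data$bits + .data$sd),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "maximal mutual information (bits)") +
    ggplot2::theme_minimal()
}

#' Validation-grid accuracy plot
#'
#' True vs inferred intrinsic capacity for every validation case, with
#' the identity line; points near the line mean the gamma-deflation
#' algorithm recovered the extrinsic-noise-free capacity.
#'
#' @param cases Tibble from [run_validation_grid()].
#' @return A ggplot object.
#' @export
plot_validation <- function(cases) {
  ok <- dplyr::filter(cases, is.na(.data$failed))
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$true_int_bits,
                                   y = .data$inferred_int_bits,
                                   colour = factor(.data$extrinsic_cv),
                                   shape = .data$speed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "true intrinsic capacity (bits)",
                  y = "inferred intrinsic capacity (bits)",
                  colour = "extrinsic CV", shape = "promoter") +
    ggplot2::theme_minimal()
}
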