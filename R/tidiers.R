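#' Tidy a capacity estimate
#'
#' `tidy()` returns the per-bin-count jackknife-corrected capacities;
#' `glance()` returns the one-row sweep summary (mean +/- sd in bits).
#'
#' @param x A `capacity_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.capacity_estimate <- function(x, ...) x$per_bin

#' @rdname tidy.capacity_estimate
#' @export
glance.capacity_estimate <- function(x, ...) {
  tibble::tibble(capacity_bits = x$capacity_bits, std_bits = x$std_bits,
                 n_bin_counts = nrow(x$per_bin), reporter = x$reporter)
}

#' Tidy an intrinsic-capacity estimate
#'
#' `tidy()` returns the per-condition gamma fits (raw and deflated
#' parameters, clamp flags); `glance()` the one-row comparison of the
#' raw and intrinsic capacity.
#'
#' @param x An `intrinsic_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.intrinsic_estimate <- function(x, ...) x$models

#' @rdname tidy.intrinsic_estimate
#' @export
glance.intrinsic_estimate <- function(x, ...) {
  tibble::tibble(
    intrinsic_bits = x$intrinsic$capacity_bits,
    intrinsic_std = x$intrinsic$std_bits,
    raw_bits = if (is.null(x$raw)) NA_real_ else x$raw$capacity_bits,
    raw_std = if (is.null(x$raw)) NA_real_ else x$raw$std_bits,
    n_clamped = x$n_clamped, mode = x$mode)
}

#' Tidy a gamma model
#'
#' @param x A `gamma_model`.
#' @param ... Unused.
#' @return One-row tibble with raw and (if set) deflated parameters.
#' @export
tidy.gamma_model <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, mean = x$mean, var = x$var,
                 a_int = x$a_int, b_int = x$b_int, var_int = x$var_int,
                 clamped = x$clamped, method = x$method)
}
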