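#' Smooth a fluorescence time trace with a centred moving average
#'
#' Applies a centred moving-average filter of odd width to one cell's
#' fluorescence trace. At the trace boundaries the window shrinks to the
#' available samples (mean over the intersection), so the output has the
#' same length as the input and a constant trace is returned unchanged.
#'
#' @param values Numeric vector of fluorescence samples (arbitrary units).
#'   Values may be slightly negative after background subtraction.
#' @param window Odd positive integer window width (default 11 samples).
#' @param cell_id Optional identifier used in error messages.
#' @return Numeric vector of the same length as `values`.
#' @examples
#' smooth_trace(c(rep(0, 10), rep(100, 10)), window = 5)
#' @export
smooth_trace <- function(values, window = 11L, cell_id = NULL) {
  if (!is.numeric(values) || length(values) == 0L) {
    abort("`values` must be a non-empty numeric vector")
  }
  if (any(!is.finite(values))) {
    who <- if (is.null(cell_id)) "trace" else paste0("trace for cell '", cell_id, "'")
    abort(paste0("non-finite fluorescence values in ", who))
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("`window` must be an odd positive integer")
  n <- length(values)
  if (window > n) abort("`window` must not exceed the trace length")
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Convert a smoothed trace to a scalar expression value
#'
#' Gene expression is quantified as the maximal fluorescence over the
#' plateau portion of the (already smoothed) trace — by default elements
#' 33 to 64 (1-based, inclusive) of a 64-frame trace sampled every
#' 2.5 minutes, i.e. after the reporter concentration has reached its
#' plateau.
#'
#' @param values Numeric trace, typically the output of [smooth_trace()].
#' @param plateau_range Integer pair `(first, last)` of 1-based inclusive
#'   indices over which the maximum is taken. Default `c(33, 64)`.
#' @return A single numeric expression scalar (AU).
#' @export
extract_expression <- function(values, plateau_range = c(33L, 64L)) {
  if (!is.numeric(values)) abort("`values` must be numeric")
  pr <- as.integer(plateau_range)
  if (length(pr) != 2L || any(!is.finite(pr)) || pr[1] > pr[2] ||
      pr[1] < 1L || pr[2] > length(values)) {
    abort("`plateau_range` must lie within 1..length(values)")
  }
  max(values[pr[1]:pr[2]])
}

# Order condition labels: numeric labels ascending (no input / 0 first),
# otherwise "no input"-like labels first then first-appearance order.
order_conditions <- function(labels) {
  labels <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(labels))
  if (!any(is.na(num))) return(labels[order(num)])
  noin <- grepl("^(no[ ._-]?input|none|0)$", labels, ignore.case = TRUE)
  c(labels[noin], labels[!noin])
}

#' Assemble a dose-response dataset from single-cell time traces
#'
#' Smooths every trace, reduces it to a plateau-maximum expression scalar,
#' and pairs YFP and CFP scalars per cell. The result is the empirical
#' "promoter channel": one row per cell with its condition label and its
#' YFP (and, when a matching CFP trace exists, CFP) expression value.
#'
#' Traces with a duplicated `(cell_id, condition, channel)` key are an
#' error; traces with missing frames and CFP traces without a YFP partner
#' are excluded and counted in the `summary` attribute of the result.
#'
#' @param traces Long-format tibble/data frame with columns
#'   `cell_id`, `condition`, `channel` (`"YFP"`/`"CFP"`), `frame`
#'   (1..`n_frames`) and `value` (AU).
#' @param window Moving-average window passed to [smooth_trace()].
#' @param plateau_range Index pair passed to [extract_expression()].
#' @param n_frames Required trace length (default 64 frames).
#' @return Tibble with columns `condition` (factor, stimulus order),
#'   `cell_id`, `yfp`, `cfp` (`NA` when unpaired), carrying a `summary`
#'   attribute (cells per condition, exclusion counts).
#' @export
assemble_dataset <- function(traces, window = 11L, plateau_range = c(33L, 64L),
                             n_frames = 64L) {
  need <- c("cell_id", "condition", "channel", "frame", "value")
  if (!all(need %in% names(traces))) {
    abort(paste0("`traces` must have columns: ", paste(need, collapse = ", ")))
  }
  traces <- tibble::as_tibble(traces)
  if (!all(traces$channel %in% c("YFP", "CFP"))) {
    abort("`channel` must be 'YFP' or 'CFP'")
  }

  key <- traces |>
    dplyr::distinct(.data$cell_id, .data$condition, .data$channel, .data$frame) |>
    dplyr::count(.data$cell_id, .data$condition, .data$channel, name = "nf")
  dup <- traces |>
    dplyr::count(.data$cell_id, .data$condition, .data$channel, .data$frame) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate trace rows for cell '", dup$cell_id[1], "'"))
  }
  short <- key |> dplyr::filter(.data$nf != n_frames)
  traces <- traces |>
    dplyr::anti_join(short, by = c("cell_id", "condition", "channel"))

  scalars <- traces |>
    dplyr::arrange(.data$frame) |>
    dplyr::summarise(
      scalar = extract_expression(
        smooth_trace(.data$value, window = window, cell_id = .data$cell_id[1]),
        plateau_range = plateau_range),
      .by = c("condition", "cell_id", "channel"))

  wide <- scalars |>
    tidyr::pivot_wider(names_from = "channel", values_from = "scalar")
  if (!"YFP" %in% names(wide)) wide$YFP <- NA_real_
  if (!"CFP" %in% names(wide)) wide$CFP <- NA_real_

  unmatched_cfp <- sum(is.na(wide$YFP) & !is.na(wide$CFP))
  out <- wide |>
    dplyr::filter(!is.na(.data$YFP)) |>
    dplyr::transmute(
      condition = .data$condition,
      cell_id = as.character(.data$cell_id),
      yfp = .data$YFP, cfp = .data$CFP)

  lev <- order_conditions(out$condition)
  out <- out |>
    dplyr::mutate(condition = factor(.data$condition, levels = lev)) |>
    dplyr::arrange(.data$condition, .data$cell_id)

  attr(out, "summary") <- list(
    cells_per_condition = table(out$condition),
    excluded_short_traces = nrow(short),
    excluded_unmatched_cfp = unmatched_cfp)
  out
}

# Internal validator for the (condition, cell_id, yfp[, cfp]) dataset shape.
check_dataset <- function(data, paired = FALSE, min_cells = 2L) {
  if (!all(c("condition", "yfp") %in% names(data))) {
    abort("dataset must have columns `condition` and `yfp`")
  }
  data <- tibble::as_tibble(data)
  if (!is.factor(data$condition)) {
    data$condition <- factor(data$condition, levels = order_conditions(data$condition))
  }
  data$condition <- droplevels(data$condition)
  if (nlevels(data$condition) < 2L) abort("dataset needs at least 2 conditions")
  cnt <- table(data$condition)
  if (any(cnt < min_cells)) {
    abort(paste0("every condition needs at least ", min_cells, " cells"))
  }
  if (paired) {
    if (!"cfp" %in% names(data) || anyNA(data$cfp)) {
      n_bad <- if ("cfp" %in% names(data)) sum(is.na(data$cfp)) else nrow(data)
      abort(paste0("paired analysis requires CFP for every cell; ",
                   n_bad, " unpaired records"))
    }
  }
  data
}
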