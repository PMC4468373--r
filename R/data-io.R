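#' Read single-cell fluorescence traces from CSV
#'
#' Two dialects are accepted: long format with header
#' `cell_id,condition,channel,frame,value` (frame 1..64, channel YFP or
#' CFP) and wide format `cell_id,condition,channel,v1,...,v64`. Wide
#' input is pivoted to long. Malformed rows are an error citing the
#' offending line.
#'
#' @param path CSV file path (UTF-8, "." decimal separator).
#' @return Long-format tibble suitable for [assemble_dataset()].
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  long <- all(c("cell_id", "condition", "channel", "frame", "value") %in% header)
  wide <- all(c("cell_id", "condition", "channel", "v1") %in% header)
  if (!long && !wide) {
    abort("unknown trace dialect: expected long (frame,value) or wide (v1..v64) columns")
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (wide) {
    x <- tidyr::pivot_longer(x, dplyr::starts_with("v"), names_to = "frame",
                             values_to = "value", names_prefix = "v")
  }
  for (col in c("frame", "value")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v)) {
      abort(paste0("non-numeric ", col, " at data row(s): ",
                   paste(utils::head(which(is.na(v)), 5), collapse = ", ")))
    }
    x[[col]] <- v
  }
  x$frame <- as.integer(x$frame)
  x
}

#' Read / write a dose-response dataset CSV
#'
#' The dataset dialect is `condition,cell_id,yfp,cfp` with an empty
#' `cfp` field for unpaired cells. Values round-trip bit-exactly.
#'
#' @param path CSV file path.
#' @return `read_dataset()`: a validated dose-response tibble with
#'   conditions in stimulus order.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # numeric fields are parsed via strtod (exact round trip of the shortest
  # decimal representation); the stream parser can be off by one ulp
  x <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  for (col in c("yfp", "cfp")) {
    if (!col %in% names(x)) next
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.na(x[[col]]) & nzchar(x[[col]]) & is.na(v))
    if (length(bad) > 0L) {
      abort(paste0("malformed numeric ", col, " at data row(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    x[[col]] <- v
  }
  if (anyNA(x$yfp)) abort("missing yfp values in dataset file")
  x$condition <- factor(x$condition, levels = order_conditions(x$condition))
  x
}

#' @param data Dose-response tibble.
#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(
    dplyr::mutate(data, condition = as.character(.data$condition)), path)
  invisible(path)
}

# Convert results to plain lists for JSON serialisation.
as_result_list <- function(x, ...) UseMethod("as_result_list")

#' @export
as_result_list.capacity_estimate <- function(x, ...) {
  list(capacity_bits = x$capacity_bits,
       std_bits = x$std_bits,
       per_bin_values = setNames(as.list(x$per_bin$capacity_bits),
                                 x$per_bin$n_bins),
       optimal_input = setNames(as.list(x$optimal_input$weight),
                                x$optimal_input$condition),
       reporter = x$reporter,
       settings = x$settings)
}

#' @export
as_result_list.intrinsic_estimate <- function(x, ...) {
  list(intrinsic = as_result_list(x$intrinsic),
       raw = if (!is.null(x$raw)) as_result_list(x$raw),
       gamma_models = x$models,
       n_clamped = x$n_clamped, mode = x$mode, seed = x$seed)
}

#' @export
as_result_list.data.frame <- function(x, ...) x

#' Write a result object to JSON
#'
#' Serialises a `capacity_estimate`, `intrinsic_estimate` or result
#' tibble to JSON together with its generating settings, the package
#' version and a timestamp, so every output file carries its own
#' provenance.
#'
#' @param result Result object.
#' @param path Output path (`.json`).
#' @export
write_results <- function(result, path) {
  payload <- list(
    result = as_result_list(result),
    package = "promcap",
    version = as.character(utils::packageVersion("promcap")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
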