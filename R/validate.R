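#' In-silico validation grid for the intrinsic-capacity algorithm
#'
#' Checks the gamma-deflation estimate of the intrinsic channel capacity
#' against ground truth on simulated data. For every combination of
#' model, promoter speed and extrinsic-noise CV, two dual-reporter
#' datasets are simulated under an amplitude-modulation schedule: one
#' with per-cell extrinsic factors at the requested CV (the algorithm's
#' input) and a matched one with the extrinsic factors switched off
#' (whose ordinary capacity estimate is the true intrinsic capacity).
#' The per-case error is the difference between the inferred and true
#' intrinsic capacity, reported both in bits and as a percentage of the
#' truth.
#'
#' The full published-scale grid is 10 models x 2 speeds x 4 CVs
#' (80 cases) at ~1000 cells over 10 AM conditions; smaller grids run in
#' minutes and obey the same error bounds up to seed-to-seed scatter.
#'
#' @param models Character vector of model names (see [model_names()]).
#' @param speeds Promoter speeds to include.
#' @param extrinsic_cvs Extrinsic-noise CV levels.
#' @param n_conditions AM input levels including "no input" (default 10).
#' @param n_cells Cells per condition per dataset.
#' @param seed Master seed; per-case seeds are derived deterministically.
#' @param bin_min,bin_max Capacity bin sweep (single-reporter range).
#' @param fractions,n_resamples Jackknife settings (see
#'   [jackknife_capacity()]).
#' @param mode Intrinsic estimation mode (see
#'   [intrinsic_capacity_sweep()]).
#' @return Tibble with one row per case: `model`, `speed`,
#'   `extrinsic_cv`, `true_int_bits`, `inferred_int_bits`, `error_bits`,
#'   `error_pct`, `n_clamped`, `failed` (with the error message when a
#'   case failed).
#' @export
run_validation_grid <- function(models = model_names(),
                                speeds = c("fast", "slow"),
                                extrinsic_cvs = c(0.1, 0.2, 0.3, 0.4),
                                n_conditions = 10L, n_cells = 1000L, seed,
                                bin_min = 15L, bin_max = 35L,
                                fractions = c(1, 0.5, 0.25),
                                n_resamples = 20L,
                                mode = c("sampled", "analytic")) {
  seed <- assert_seed(seed)
  mode <- match.arg(mode)
  grid <- tidyr::expand_grid(model = models, speed = speeds,
                             extrinsic_cv = extrinsic_cvs)
  schedule <- am_schedule(n_conditions)
  purrr::pmap_dfr(
    c(grid, list(idx = seq_len(nrow(grid)))),
    function(model, speed, extrinsic_cv, idx) {
      base <- tibble::tibble(model = model, speed = speed,
                             extrinsic_cv = extrinsic_cv)
      tryCatch({
        m <- sim_model(model, speed)
        noisy <- generate_dual_reporter_dataset(
          m, schedule, n_cells, extrinsic_cv, seed = derive_seed(seed, idx))
        clean <- generate_dual_reporter_dataset(
          m, schedule, n_cells, extrinsic_cv = 0,
          seed = derive_seed(seed, idx + 10000L))
        inf <- intrinsic_capacity_sweep(
          noisy, bin_min, bin_max, seed = derive_seed(seed, idx + 20000L),
          mode = mode, fractions = fractions, n_resamples = n_resamples,
          include_raw = FALSE)
        truth <- capacity_sweep(
          clean, reporter = "yfp", bin_min, bin_max, fractions, n_resamples,
          seed = derive_seed(seed, idx + 30000L))
        err <- inf$intrinsic$capacity_bits - truth$capacity_bits
        dplyr::mutate(base,
          true_int_bits = truth$capacity_bits,
          inferred_int_bits = inf$intrinsic$capacity_bits,
          error_bits = err,
          error_pct = 100 * abs(err) / truth$capacity_bits,
          n_clamped = inf$n_clamped,
          failed = NA_character_)
      }, error = function(e) {
        dplyr::mutate(base, true_int_bits = NA_real_,
                      inferred_int_bits = NA_real_, error_bits = NA_real_,
                      error_pct = NA_real_, n_clamped = NA_integer_,
                      failed = conditionMessage(e))
      })
    })
}

#' Summarise a validation grid
#'
#' @param cases Tibble from [run_validation_grid()].
#' @return One-row tibble: mean and maximum percentage error, the signed
#'   mean error in bits (the algorithm tends to slightly underestimate,
#'   so this is typically <= 0), case counts, clamp count and failures.
#' @export
error_summary <- function(cases) {
  if (nrow(cases) == 0L) abort("no validation cases supplied")
  ok <- dplyr::filter(cases, is.na(.data$failed))
  tibble::tibble(
    mean_error_pct = if (nrow(ok)) mean(ok$error_pct) else NA_real_,
    max_error_pct = if (nrow(ok)) max(ok$error_pct) else NA_real_,
    mean_signed_error_bits = if (nrow(ok)) mean(ok$error_bits) else NA_real_,
    n_cases = nrow(cases),
    n_failed = sum(!is.na(cases$failed)),
    n_clamped = sum(ok$n_clamped))
}
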