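#' Exact stochastic simulation of one cell
#'
#' Runs the Gillespie stochastic simulation algorithm for a
#' gene-expression model under a piecewise-constant TF input profile and
#' returns the protein copy number at `t_end` (or, if `sample_times` is
#' given, the protein level at each requested time — useful for
#' synthesising fluorescence time traces).
#'
#' @param model A `sim_model` from [sim_model()].
#' @param profile List with `levels` (TF level per segment, normalized
#'   0-1 scale), `breaks` (end time of each segment but the last, min)
#'   and optionally `t_end`; e.g. one entry of an [am_schedule()].
#' @param t_end Simulation end time in minutes (defaults to
#'   `profile$t_end`).
#' @param seed Integer seed (required).
#' @param translation_factor,tf_factor Extrinsic per-cell multipliers
#'   (dimensionless; 1 = population average).
#' @param sample_times Optional vector of times at which to record the
#'   protein level instead of returning only the final count.
#' @return Final protein count, or a numeric vector along
#'   `sample_times`.
#' @export
gillespie_simulate <- function(model, profile, t_end = NULL, seed,
                               translation_factor = 1, tf_factor = 1,
                               sample_times = NULL) {
  if (!inherits(model, "sim_model")) abort("`model` must be a `sim_model`")
  seed <- assert_seed(seed)
  t_end <- t_end %||% profile$t_end
  if (is.null(t_end) || t_end <= 0) abort("`t_end` must be positive")
  lv <- as.numeric(profile$levels)
  br <- as.numeric(profile$breaks)
  if (any(lv < 0)) abort("TF profile levels must be non-negative")
  withr::with_seed(seed, {
    if (is.null(sample_times)) {
      ssa_population_cpp(model, lv, br, t_end, translation_factor, tf_factor)[1]
    } else {
      ssa_trajectory_cpp(model, lv, br, as.numeric(sample_times),
                         translation_factor, tf_factor)$protein
    }
  })
}

# Gamma multipliers with mean 1 and the given CV (cv = 0 -> exactly 1).
extrinsic_factors <- function(n, cv) {
  if (cv < 0) abort("`extrinsic_cv` must be >= 0")
  if (cv == 0) rep(1, n) else rgamma(n, shape = 1 / cv^2, scale = cv^2)
}

#' Simulate a dual-reporter dose-response dataset
#'
#' For every condition of an input schedule, simulates `n_cells` cells.
#' Each cell draws one extrinsic state — a translation-rate factor and a
#' TF-abundance factor, both gamma-distributed with mean 1 and CV
#' `extrinsic_cv` — and then runs two conditionally independent
#' stochastic simulations of the same gene (the CFP and YFP reporter
#' copies) sharing that extrinsic state. Reporter covariance therefore
#' reflects exactly the injected extrinsic variability, while the
#' within-cell reaction noise of the two copies is independent
#' (intrinsic).
#'
#' @param model A `sim_model`.
#' @param schedule An `input_schedule` ([am_schedule()]/[fm_schedule()]).
#' @param n_cells Cells per condition (>= 2).
#' @param extrinsic_cv CV of both extrinsic factors (0 disables them).
#' @param seed Integer seed (required).
#' @return Dose-response tibble (`condition`, `cell_id`, `yfp`, `cfp`)
#'   with conditions ordered as in the schedule; expression scalars are
#'   final protein counts.
#' @export
generate_dual_reporter_dataset <- function(model, schedule, n_cells,
                                           extrinsic_cv, seed) {
  if (!inherits(schedule, "input_schedule")) {
    abort("`schedule` must be an `input_schedule`")
  }
  if (n_cells < 2L) abort("`n_cells` must be >= 2")
  seed <- assert_seed(seed)
  conds <- names(schedule$conditions)
  out <- purrr::imap_dfr(schedule$conditions, function(pf, cond) {
    withr::with_seed(derive_seed(seed, match(cond, conds)), {
      tl <- extrinsic_factors(n_cells, extrinsic_cv)
      tf <- extrinsic_factors(n_cells, extrinsic_cv)
      lv <- as.numeric(pf$levels); br <- as.numeric(pf$breaks)
      yfp <- ssa_population_cpp(model, lv, br, pf$t_end, tl, tf)
      cfp <- ssa_population_cpp(model, lv, br, pf$t_end, tl, tf)
      tibble::tibble(condition = cond,
                     cell_id = paste0(cond, "_", seq_len(n_cells)),
                     yfp = yfp, cfp = cfp)
    })
  })
  out$condition <- factor(out$condition, levels = conds)
  out
}

#' Fast parametric dual-reporter generator
#'
#' A closed-form stand-in for the stochastic simulator: per condition,
#' both reporters are drawn independently from a gamma distribution with
#' the requested mean and intrinsic CV, and each cell multiplies both by
#' a shared gamma factor with mean 1 and CV `extrinsic_cv`. Useful as a
#' quick fixture with known moments: the total squared CV composes as
#' `cv_int^2 + cv_ext^2 + cv_int^2 cv_ext^2`.
#'
#' @param means Per-condition mean expression (AU, > 0); names become
#'   condition labels (default `s1`, `s2`, ...).
#' @param cvs Intrinsic CV per condition (recycled; 0 gives a point mass
#'   scaled by the shared factor).
#' @param extrinsic_cv CV of the shared per-cell factor.
#' @param n_cells Cells per condition.
#' @param seed Integer seed (required).
#' @return Dose-response tibble (`condition`, `cell_id`, `yfp`, `cfp`).
#' @export
generate_parametric_dataset <- function(means, cvs, extrinsic_cv, n_cells,
                                        seed) {
  if (any(means <= 0)) abort("`means` must be positive")
  if (any(cvs < 0)) abort("`cvs` must be >= 0")
  seed <- assert_seed(seed)
  cvs <- rep_len(cvs, length(means))
  labs <- names(means) %||% paste0("s", seq_along(means))
  out <- withr::with_seed(seed, {
    purrr::pmap_dfr(list(means, cvs, labs), function(mu, cv, lab) {
      f <- extrinsic_factors(n_cells, extrinsic_cv)
      draw <- function() {
        if (cv == 0) rep(mu, n_cells)
        else rgamma(n_cells, shape = 1 / cv^2, scale = mu * cv^2)
      }
      tibble::tibble(condition = lab,
                     cell_id = paste0(lab, "_", seq_len(n_cells)),
                     yfp = draw() * f, cfp = draw() * f)
    })
  })
  out$condition <- factor(out$condition, levels = labs)
  out
}

#' Synthesise single-cell fluorescence traces
#'
#' Builds a long-format table of 64-frame fluorescence time traces
#' (2.5-min sampling) from parametric expression scalars: each cell's
#' trace rises along a saturating curve to its plateau value (reached
#' well before frame 33) with additive Gaussian measurement noise, for
#' end-to-end tests of the trace-processing pipeline.
#'
#' @inheritParams generate_parametric_dataset
#' @param noise_sd Measurement noise SD as a fraction of the plateau
#'   value (default 0.05).
#' @param channels Channels to emit (default both `YFP` and `CFP`).
#' @return Long tibble (`cell_id`, `condition`, `channel`, `frame`,
#'   `value`) suitable for [assemble_dataset()], with the underlying
#'   scalar dataset attached as attribute `truth`.
#' @export
generate_trace_dataset <- function(means, cvs, extrinsic_cv, n_cells, seed,
                                   noise_sd = 0.05,
                                   channels = c("YFP", "CFP")) {
  seed <- assert_seed(seed)
  truth <- generate_parametric_dataset(means, cvs, extrinsic_cv, n_cells, seed)
  frames <- 1:64
  rise <- 1 - exp(-(frames * 2.5) / 15)  # plateau (>98%) by ~frame 24
  traces <- withr::with_seed(derive_seed(seed, 1L), {
    long <- tidyr::pivot_longer(truth, dplyr::all_of(tolower(channels)),
                                names_to = "channel", values_to = "scalar")
    long$channel <- toupper(long$channel)
    tidyr::crossing(long, frame = frames) |>
      dplyr::mutate(
        value = .data$scalar * rise[.data$frame] +
          stats::rnorm(dplyr::n(), sd = noise_sd * .data$scalar)) |>
      dplyr::select("cell_id", "condition", "channel", "frame", "value")
  })
  attr(traces, "truth") <- truth
  traces
}
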