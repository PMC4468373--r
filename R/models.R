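#' Stochastic gene-expression model library
#'
#' Declares a library of ten stochastic gene-expression models — five
#' with a linear TF-to-promoter coupling and five nonlinear — each
#' parameterised for a fast or a slow promoter. All models share the
#' species set (promoter activation state, mRNA, protein) and rate units
#' of 1/min; they differ in their TF coupling (proportional, Hill h = 2
#' or h = 4, saturating, two-step cooperative, protein positive
#' feedback), in whether transcription passes through an explicit mRNA
#' species, and in basal leak. Rate constants are chosen so that final
#' protein counts after a sustained 70-min input span roughly 10-1000
#' molecules across the input range, with monotone dose-response means.
#' The concrete parameter values are this package's own reconstruction
#' of that model class, not a transcription of any published table.
#'
#' Fast promoters switch at ~10/min, slow promoters at ~0.1/min.
#'
#' @param name One of `model_names()`.
#' @param promoter_speed `"fast"` or `"slow"`.
#' @return A `sim_model`: named list of reaction parameters understood
#'   by [gillespie_simulate()].
#' @export
sim_model <- function(name, promoter_speed = c("fast", "slow")) {
  promoter_speed <- match.arg(promoter_speed)
  base <- list(
    # coupling: 0 linear u/K, 1 Hill h=2, 2 Hill h=4, 3 saturating u/(K+u)
    coupling = 0L, n_act = 1L, has_mrna = 1L,
    k_on = 20, k_off = 10, k_m = 2, d_m = 0.2, k_p = 1, d_p = 0.01,
    K = 1, basal = 0.02, fb = 0, fb_ref = 1)
  variant <- switch(
    name,
    # --- linear couplings -------------------------------------------------
    lin_telegraph = list(linearity = "linear"),
    lin_burst     = list(linearity = "linear", has_mrna = 0L, k_m = 6,
                         basal = 0.03),
    lin_graded    = list(linearity = "linear", k_on = 4, k_off = 40, k_m = 30,
                         basal = 0.002),
    lin_basal     = list(linearity = "linear", basal = 0.08),
    lin_slowmrna  = list(linearity = "linear", d_m = 0.05, k_m = 0.6, k_p = 2),
    # --- nonlinear couplings ----------------------------------------------
    hill2_telegraph = list(linearity = "nonlinear", coupling = 1L, K = 0.5),
    hill4_telegraph = list(linearity = "nonlinear", coupling = 2L, K = 0.5),
    mm_saturating   = list(linearity = "nonlinear", coupling = 3L, K = 0.3),
    coop_twostep    = list(linearity = "nonlinear", n_act = 2L, k_on = 60,
                           k_m = 3),
    pos_feedback    = list(linearity = "nonlinear", fb = 2, fb_ref = 300),
    abort(paste0("unknown model '", name, "'; see model_names()")))
  m <- utils::modifyList(base, variant[setdiff(names(variant), "linearity")])
  if (promoter_speed == "slow") {
    m$k_on <- m$k_on / 100
    m$k_off <- m$k_off / 100
    # keep the mean transcriptional output comparable: slow promoters spend
    # the same fraction of time active, only the switching timescale changes
  }
  structure(c(m, list(name = name, linearity = variant$linearity,
                      promoter_speed = promoter_speed)),
            class = "sim_model")
}

#' @rdname sim_model
#' @export
model_names <- function() {
  c("lin_telegraph", "lin_burst", "lin_graded", "lin_basal", "lin_slowmrna",
    "hill2_telegraph", "hill4_telegraph", "mm_saturating", "coop_twostep",
    "pos_feedback")
}

#' TF input schedules
#'
#' Piecewise-constant nuclear-TF time profiles. `am_schedule()` gives
#' sustained 70-min pulses whose amplitudes span the input range
#' (default: no input plus seven levels mirroring the experimental
#' 1-NM-PP1 titration on a 0-1 normalized scale; any number of equally
#' spaced levels can be requested). `fm_schedule()` gives trains of 0-9
#' five-minute pulses at a fixed amplitude with the experimental
#' inter-pulse intervals, so that every train spans the same 85-min
#' window.
#'
#' @param n_levels For AM: number of conditions including "0" (no input).
#'   With the default 8, amplitudes mirror the experimental titration;
#'   otherwise levels are equally spaced on (0, 1].
#' @param amplitude For FM: pulse amplitude on the normalized TF scale.
#' @param n_pulses For FM: vector of pulse counts (default 0:9).
#' @return An `input_schedule`: list with `modality` and a named list
#'   `conditions`, each entry holding `levels`, `breaks` (segment end
#'   times, min) and `t_end`.
#' @export
am_schedule <- function(n_levels = 8L) {
  amps <- if (n_levels == 8L) {
    c(0, c(100, 175, 275, 413, 690, 1117, 3000) / 3000)
  } else {
    c(0, seq_len(n_levels - 1L) / (n_levels - 1L))
  }
  conditions <- lapply(amps, function(a) {
    list(levels = c(a, 0), breaks = 70, t_end = 70)
  })
  names(conditions) <- formatC(amps, format = "fg", digits = 4)
  structure(list(modality = "AM", conditions = conditions),
            class = "input_schedule")
}

#' @rdname am_schedule
#' @export
fm_schedule <- function(amplitude = 690 / 3000, n_pulses = 0:9) {
  gaps <- c(`1` = NA, `2` = 40, `3` = 25, `4` = 17.5, `5` = 13, `6` = 10,
            `7` = 7.86, `8` = 6.25, `9` = 5)
  t_end <- 90
  conditions <- lapply(n_pulses, function(k) {
    if (k == 0L) return(list(levels = 0, breaks = numeric(0), t_end = t_end))
    gap <- if (k == 1L) 0 else gaps[[as.character(k)]]
    levels <- rep(c(amplitude, 0), k)
    durs <- rep(c(5, gap), k)
    durs[2 * k] <- Inf
    ends <- cumsum(durs[-(2 * k)])
    list(levels = levels, breaks = ends, t_end = t_end)
  })
  names(conditions) <- as.character(n_pulses)
  structure(list(modality = "FM", conditions = conditions),
            class = "input_schedule")
}
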