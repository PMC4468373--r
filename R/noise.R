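#' Extrinsic variance from dual-reporter pairs
#'
#' The extrinsic component of expression variance is the covariance of
#' the two reporters measured in the same cells,
#' `sigma_ext^2 = <CFP * YFP> - <CFP><YFP>` (population moments):
#' cell-wide factors move both reporters together, whereas intrinsic
#' reaction noise is uncorrelated between them.
#'
#' @param cfp,yfp Numeric vectors of paired per-cell expression values
#'   (same cells, same order).
#' @return Covariance in AU^2.
#' @export
extrinsic_variance <- function(cfp, yfp) {
  if (length(cfp) != length(yfp)) abort("`cfp` and `yfp` must be paired")
  if (length(cfp) < 2L) abort("need at least 2 dual-reporter pairs")
  mean(cfp * yfp) - mean(cfp) * mean(yfp)
}

#' Dual-reporter noise decomposition per condition
#'
#' Splits the expression variability of each condition into intrinsic
#' and extrinsic components with the standard dual-reporter estimators:
#' `eta2_int = <(C - Y)^2> / (2 <C><Y>)`,
#' `eta2_ext = (<CY> - <C><Y>) / (<C><Y>)`, and
#' `eta2_tot = eta2_int + eta2_ext` (additivity holds by construction).
#' Population (1/n) moments are used throughout so the decomposition is
#' exact. Because the two fluorophores are not on a common intensity
#' scale, CFP is by default rescaled per condition to match the YFP mean
#' before the symmetric formulas are applied (`rescale = FALSE` turns
#' this off).
#'
#' @param data Paired dose-response tibble (`condition`, `yfp`, `cfp`).
#' @param rescale Rescale CFP to the YFP mean per condition (default TRUE).
#' @return Tibble with one row per condition: means, `var_total` and
#'   `var_ext`/`var_int` for the YFP reporter (AU^2), and the normalized
#'   `eta2_tot`, `eta2_int`, `eta2_ext`.
#' @export
noise_components <- function(data, rescale = TRUE) {
  data <- check_dataset(data, paired = TRUE, min_cells = 2L)
  data |>
    dplyr::summarise(
      one_condition_noise(.data$cfp, .data$yfp, rescale = rescale),
      .by = "condition")
}

one_condition_noise <- function(cfp, yfp, rescale = TRUE) {
  m_c <- mean(cfp); m_y <- mean(yfp)
  if (m_c <= 0 || m_y <= 0) abort("noise normalization requires positive means")
  cs <- if (rescale) cfp * (m_y / m_c) else cfp
  m_cs <- mean(cs)
  var_total <- mean(yfp^2) - m_y^2
  var_ext <- extrinsic_variance(cs, yfp)
  eta2_int <- mean((cs - yfp)^2) / (2 * m_cs * m_y)
  eta2_ext <- var_ext / (m_cs * m_y)
  tibble::tibble(
    mean_cfp = m_c, mean_yfp = m_y,
    var_total = var_total, var_ext = var_ext, var_int = var_total - var_ext,
    eta2_tot = eta2_int + eta2_ext, eta2_int = eta2_int, eta2_ext = eta2_ext)
}
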