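#' Conditional mutual information MI(R2; S | R1)
#'
#' Given the discretized three-way distribution p(R1, R2, S), returns
#' `sum p(r1, r2, s) log2[ p(r1) p(r1, r2, s) / (p(r1, r2) p(r1, s)) ]`,
#' the information R2 carries about the signal S beyond what R1 already
#' carries. Together with the single-reporter term it satisfies the
#' chain rule `MI(R1, R2; S) = MI(R1; S) + MI(R2; S | R1)`.
#'
#' @param joint3 Non-negative 3-d array with dimensions (R1, R2, S)
#'   summing to 1; zero-mass terms contribute 0.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(joint3) {
  if (length(dim(joint3)) != 3L) abort("`joint3` must be a 3-d array (R1, R2, S)")
  if (any(joint3 < 0)) abort("`joint3` has negative entries")
  if (abs(sum(joint3) - 1) > 1e-6) abort("`joint3` must sum to 1 (within 1e-6)")
  p_r1 <- apply(joint3, 1, sum)
  p_r12 <- apply(joint3, c(1, 2), sum)
  p_r1s <- apply(joint3, c(1, 3), sum)
  nz <- which(joint3 > 0, arr.ind = TRUE)
  p <- joint3[nz]
  sum(p * log2(p_r1[nz[, 1]] * p /
                 (p_r12[cbind(nz[, 1], nz[, 2])] * p_r1s[cbind(nz[, 1], nz[, 3])])))
}

# Conditional matrix over the flattened (R1, R2) response alphabet:
# per reporter, equal-width bins over [0, pooled max]; one row per condition.
joint_cond_probs <- function(y_list, c_list, n_bins) {
  y_all <- unlist(y_list, use.names = FALSE)
  c_all <- unlist(c_list, use.names = FALSE)
  if (diff(range(y_all)) == 0 || diff(range(c_all)) == 0) {
    abort("degenerate support: all pooled expression values are identical")
  }
  ey <- seq(0, max(y_all), length.out = n_bins + 1L)
  ec <- seq(0, max(c_all), length.out = n_bins + 1L)
  t(mapply(function(y, v) {
    flat <- (bin_index(y, ey) - 1L) * n_bins + bin_index(v, ec)
    tabulate(flat, nbins = n_bins^2) / length(y)
  }, y_list, c_list))
}

#' Joint two-reporter channel capacity with a bin-count sweep
#'
#' Discretizes the paired (YFP, CFP) response in two dimensions
#' (`n_bins` equal-width bins per reporter), treats the flattened pair
#' as a single response alphabet, and estimates the maximal joint mutual
#' information `I(R1, R2; S)` by Blahut-Arimoto over p(S) with the same
#' jackknife undersampling correction as [capacity_sweep()]. The sweep
#' runs over 8 to 20 bins per reporter by default.
#'
#' @inheritParams capacity_sweep
#' @return A `capacity_estimate` for the joint channel.
#' @export
joint_capacity_sweep <- function(data, bin_min = 8L, bin_max = 20L,
                                 fractions = c(1, 0.5, 0.25), n_resamples = 20L,
                                 seed, tol = 1e-10, max_iter = 10000L) {
  seed <- assert_seed(seed)
  data <- check_dataset(data, paired = TRUE, min_cells = 2L)
  if (bin_min < 2L || bin_max < bin_min) abort("invalid bin sweep range")
  yv <- pmax(data$yfp, 0)
  cv <- pmax(data$cfp, 0)
  groups <- split(seq_len(nrow(data)), data$condition)
  if (min(fractions) * min(lengths(groups)) < 3) {
    abort("smallest fraction x smallest condition must keep >= 3 cells")
  }
  bins <- seq.int(bin_min, bin_max)
  caps <- vapply(bins, function(nb) {
    res <- jackknife_extrapolate(
      groups,
      function(ix) {
        W <- joint_cond_probs(lapply(ix, function(i) yv[i]),
                              lapply(ix, function(i) cv[i]), nb)
        ba_capacity_cpp(W, tol, as.integer(max_iter))$capacity_bits
      },
      fractions, n_resamples, seed = derive_seed(seed, nb))
    res$capacity_bits
  }, numeric(1))
  per_bin <- tibble::tibble(n_bins = bins, capacity_bits = caps)
  ref_bins <- bins[ceiling(length(bins) / 2)]
  W <- joint_cond_probs(lapply(groups, function(i) yv[i]),
                        lapply(groups, function(i) cv[i]), ref_bins)
  ba <- blahut_arimoto(W, tol, max(max_iter, 200000L))
  optimal_input <- tibble::tibble(condition = levels(data$condition),
                                  weight = ba$input_weights)
  new_capacity_estimate(
    per_bin, optimal_input, reporter = "joint",
    settings = list(bin_min = bin_min, bin_max = bin_max, fractions = fractions,
                    n_resamples = n_resamples, seed = seed, tol = tol,
                    max_iter = max_iter, reference_bins = ref_bins))
}
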