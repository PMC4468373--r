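test_that("discretize builds normalized per-condition histograms", {
  d <- tibble::tibble(
    condition = rep(c("a", "b"), each = 20),
    yfp = c(runif(20, 0, 1), runif(20, 9, 10)))
  ch <- discretize(d, "yfp", 20)
  expect_s3_class(ch, "discrete_channel")
  expect_equal(rowSums(ch$cond_probs), c(a = 1, b = 1))
  # disjoint supports: no bin is occupied by both conditions
  expect_true(all(ch$cond_probs[1, ] * ch$cond_probs[2, ] == 0))

  # point mass lands in a single (indicator) row
  d2 <- tibble::tibble(condition = rep(c("a", "b"), each = 5),
                       yfp = c(rep(5, 5), 1:5))
  ch2 <- discretize(d2, "yfp", 10)
  expect_equal(sum(ch2$cond_probs[1, ] == 1), 1)

  # histogram totals equal cell counts before normalization
  withr::with_seed(1, {
    d3 <- tibble::tibble(condition = rep(c("a", "b"), c(37, 61)),
                         yfp = rgamma(98, 3, scale = 20))
    ch3 <- discretize(d3, "yfp", 15)
    expect_equal(unname(rowSums(ch3$cond_probs * c(37, 61))), c(37, 61))
  })

  expect_error(discretize(tibble::tibble(condition = c("a", "b"),
                                         yfp = c(2, 2)), "yfp", 5),
               "degenerate")
})

test_that("mutual information matches direct summation", {
  # independence
  p <- outer(c(0.3, 0.7), c(0.2, 0.5, 0.3))
  expect_equal(mutual_information(p), 0)
  # noiseless binary
  expect_equal(mutual_information(diag(2) / 2), 1)
  # hand-derived: 1 - H2(0.2)
  j <- matrix(c(0.4, 0.1, 0.1, 0.4), 2)
  expect_equal(mutual_information(j), 1 - h2(0.2), tolerance = 1e-12)
  # arbitrary tables agree with the loop oracle
  withr::with_seed(2, {
    for (i in 1:10) {
      m <- matrix(rexp(12), 3, 4); m <- m / sum(m)
      expect_equal(mutual_information(m), mi_direct(m), tolerance = 1e-12)
    }
  })
  expect_error(mutual_information(matrix(c(-0.1, 1.1, 0, 0), 2)), "negative")
  expect_error(mutual_information(diag(2)), "sum to 1")
})

test_that("Blahut-Arimoto reaches known capacities", {
  # useless channel: identical rows
  res <- blahut_arimoto(matrix(0.25, 3, 4))
  expect_equal(res$capacity_bits, 0, tolerance = 1e-12)
  # noiseless 4-symbol channel: 2 bits, uniform input
  res4 <- blahut_arimoto(diag(4))
  expect_equal(res4$capacity_bits, 2, tolerance = 1e-9)
  expect_equal(res4$input_weights, rep(0.25, 4), tolerance = 1e-6)
  # binary symmetric channel, flip 0.1
  bsc <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  expect_equal(blahut_arimoto(bsc)$capacity_bits, 1 - h2(0.1),
               tolerance = 1e-9)
})

test_that("BA agrees with the closed-form binary capacity and the R reference", {
  withr::with_seed(7, {
    for (i in 1:20) {
      W <- random_channel(2, 2)
      cap <- blahut_arimoto(W, tol = 1e-12, max_iter = 1e6)$capacity_bits
      expect_equal(cap, binary_capacity_closed_form(W), tolerance = 1e-8)
    }
    # larger channels: compiled solver vs plain-R reference, and the
    # reference lower bound must be non-decreasing along its iterations
    for (i in 1:5) {
      W <- random_channel(4, 8)
      ref <- ba_reference(W)
      expect_equal(blahut_arimoto(W, tol = 1e-12, max_iter = 1e6)$capacity_bits,
                   ref$capacity_bits, tolerance = 1e-8)
      expect_true(all(diff(ref$lower_trace) > -1e-12))
    }
  })
})

test_that("the optimised input beats uniform and capacity obeys its bounds", {
  withr::with_seed(11, {
    for (i in 1:10) {
      ns <- sample(2:6, 1); nr <- sample(3:12, 1)
      W <- random_channel(ns, nr)
      res <- blahut_arimoto(W, max_iter = 1e6)
      expect_lte(res$capacity_bits, log2(ns) + 1e-9)
      expect_gte(res$capacity_bits, -1e-12)
      mi_at <- function(p) mutual_information(W * p)
      expect_gte(mi_at(res$input_weights), mi_at(rep(1 / ns, ns)) - 1e-9)
      # capacity is invariant under permutation of the input symbols
      perm <- sample(ns)
      expect_equal(blahut_arimoto(W[perm, , drop = FALSE], max_iter = 1e6)$capacity_bits,
                   res$capacity_bits, tolerance = 1e-9)
    }
  })
})

test_that("jackknife removes the undersampling bias", {
  # no bias to remove on a noiseless channel
  d <- generate_parametric_dataset(c(10, 1000), 0.05, 0, 400, seed = 3)
  jk <- jackknife_capacity(d, "yfp", n_bins = 20, seed = 5)
  expect_equal(as.numeric(jk), 1, tolerance = 1e-6)

  # response independent of condition: plug-in is biased up, the
  # corrected estimate collapses to ~0
  withr::with_seed(8, {
    vals <- rgamma(400, shape = 4, scale = 25)
    d0 <- tibble::tibble(condition = rep(c("a", "b"), each = 200), yfp = vals)
  })
  plugin <- plugin_capacity(split(d0$yfp, d0$condition), 20)
  corrected <- as.numeric(jackknife_capacity(d0, "yfp", 20, seed = 9))
  expect_gt(plugin, 0.01)
  expect_lt(abs(corrected), 0.05)
  expect_lt(corrected + 1e-12, plugin)

  # overlapping gamma channel: corrected is closer to the large-N value
  means <- c(50, 90, 160, 280)
  big <- generate_parametric_dataset(means, 0.45, 0, 20000, seed = 21)
  truth <- plugin_capacity(split(pmax(big$yfp, 0), big$condition), 20)
  small <- generate_parametric_dataset(means, 0.45, 0, 200, seed = 22)
  plug_small <- plugin_capacity(split(pmax(small$yfp, 0), small$condition), 20)
  corr_small <- as.numeric(jackknife_capacity(small, "yfp", 20, seed = 23))
  expect_lt(abs(corr_small - truth), abs(plug_small - truth))
})

test_that("capacity sweep reports mean and spread over bin counts", {
  d <- generate_parametric_dataset(c(10, 1000), 0.05, 0, 300, seed = 4)
  est <- capacity_sweep(d, seed = 6, n_resamples = 5)
  expect_s3_class(est, "capacity_estimate")
  expect_equal(est$capacity_bits, 1, tolerance = 1e-6)
  expect_lt(est$std_bits, 1e-6)
  expect_equal(nrow(est$per_bin), 21)

  # heavy overlap among 8 conditions: strictly below log2(8)
  d8 <- generate_parametric_dataset(seq(40, 250, length.out = 8), 0.6, 0,
                                    150, seed = 7)
  est8 <- capacity_sweep(d8, seed = 8, n_resamples = 5)
  expect_lt(est8$capacity_bits, 3)
  expect_gt(est8$capacity_bits, 0)

  # capacity is invariant under a positive rescaling of the AU axis
  d_scaled <- dplyr::mutate(d8, yfp = yfp * 3.7)
  est_scaled <- capacity_sweep(d_scaled, seed = 8, n_resamples = 5)
  expect_equal(est_scaled$capacity_bits, est8$capacity_bits, tolerance = 1e-12)

  # seeded determinism
  est8b <- capacity_sweep(d8, seed = 8, n_resamples = 5)
  expect_identical(est8b$per_bin, est8$per_bin)
})

test_that("tidiers and autoplot work on capacity estimates", {
  d <- generate_parametric_dataset(c(10, 1000), 0.05, 0, 100, seed = 4)
  est <- capacity_sweep(d, bin_min = 15, bin_max = 18, seed = 6,
                        n_resamples = 3)
  expect_named(tidy(est), c("n_bins", "capacity_bits"))
  g <- glance(est)
  expect_equal(g$capacity_bits, est$capacity_bits)
  expect_s3_class(autoplot(est), "ggplot")
  expect_s3_class(plot_dose_response(d), "ggplot")
})
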