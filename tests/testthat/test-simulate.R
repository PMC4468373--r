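test_that("a dead network stays in its initial state", {
  m <- sim_model("lin_telegraph", "fast")
  m[c("k_on", "k_m", "basal")] <- list(0, 0, 0)
  expect_equal(gillespie_simulate(m, list(levels = 1, breaks = numeric(0)),
                                  t_end = 100, seed = 61), 0)
})

test_that("constitutive birth-death matches the analytic stationary law", {
  # production k = 10/min (basal = 1, protein-only), decay 1/min:
  # stationary distribution is Poisson(10)
  m <- sim_model("lin_burst", "fast")
  m[c("k_m", "basal", "has_mrna", "d_p", "k_on")] <- list(10, 1, 0L, 1, 0)
  prof <- list(levels = 0, breaks = numeric(0))
  p <- withr::with_seed(62,
    promcap:::ssa_population_cpp(m, 0, numeric(0), 50, rep(1, 5000),
                                 rep(1, 5000)))
  se_mean <- sqrt(10 / 5000)
  expect_lt(abs(mean(p) - 10), 3 * se_mean)
  fano <- var(p) / mean(p)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / 5000) + 0.05)
  # chi-square goodness of fit against Poisson(10), alpha = 0.001
  breaks <- c(-Inf, 4:16, Inf)
  obs <- table(cut(p, breaks))
  expp <- diff(ppois(c(-Inf, 4:16, Inf), 10)) * 5000
  chi2 <- sum((as.numeric(obs) - expp)^2 / expp)
  expect_lt(chi2, qchisq(0.999, df = length(expp) - 1))
})

test_that("accumulating-reporter mean matches the deterministic rate equations", {
  # telegraph at half occupancy with stable protein: E[P](t) follows
  # k_p * m_ss * (t - (1 - exp(-d_m t)) / d_m)
  m <- sim_model("lin_telegraph", "fast")
  m$d_p <- 0; m$basal <- 0
  u <- m$k_off / m$k_on  # occupancy exactly 1/2
  prof <- list(levels = u, breaks = numeric(0))
  p <- withr::with_seed(63,
    promcap:::ssa_population_cpp(m, u, numeric(0), 70, rep(1, 2000),
                                 rep(1, 2000)))
  m_ss <- m$k_m * 0.5 / m$d_m
  expected <- m$k_p * m_ss * (70 - (1 - exp(-m$d_m * 70)) / m$d_m)
  expect_lt(abs(mean(p) - expected), 3 * sd(p) / sqrt(2000) + 0.02 * expected)
})

test_that("simulation is bit-for-bit reproducible under a seed", {
  m <- sim_model("hill4_telegraph", "slow")
  sch <- am_schedule(4)
  d1 <- generate_dual_reporter_dataset(m, sch, 30, 0.2, seed = 64)
  d2 <- generate_dual_reporter_dataset(m, sch, 30, 0.2, seed = 64)
  expect_identical(d1, d2)
  d3 <- generate_dual_reporter_dataset(m, sch, 30, 0.2, seed = 65)
  expect_false(identical(d1$yfp, d3$yfp))
})

test_that("dose-response means are monotone for every library model", {
  sch <- am_schedule(5)
  for (nm in model_names()) for (sp in c("fast", "slow")) {
    d <- generate_dual_reporter_dataset(sim_model(nm, sp), sch, 120, 0,
                                        seed = 66)
    st <- dplyr::summarise(d, m = mean(yfp), se = sd(yfp) / sqrt(dplyr::n()),
                           .by = condition)
    gaps <- diff(st$m)
    tol <- 3 * sqrt(st$se[-1]^2 + st$se[-nrow(st)]^2)
    expect_true(all(gaps > -tol),
                label = paste("monotone dose-response for", nm, sp))
  }
})

test_that("extrinsic factors create the expected reporter covariance", {
  m <- sim_model("lin_telegraph", "fast")
  one <- am_schedule(2)
  one$conditions <- one$conditions[2]  # a single induced condition
  # no extrinsic noise: reporter covariance ~ 0
  d0 <- generate_dual_reporter_dataset(m, one, 1500, 0, seed = 67)
  se <- sd(d0$yfp) * sd(d0$cfp) / sqrt(1500)
  expect_lt(abs(extrinsic_variance(d0$cfp, d0$yfp)), 3 * se)
  # extrinsic CV 0.3: normalized extrinsic noise ~ 0.09
  d3 <- generate_dual_reporter_dataset(m, one, 1500, 0.3, seed = 68)
  nc <- promcap:::one_condition_noise(d3$cfp, d3$yfp)$eta2_ext
  expect_gt(nc, 0.07)
  # both factors (translation and TF) contribute, so the observed
  # covariance can exceed the single-factor expectation
  expect_lt(nc, 0.35)
  # exchangeable reporters: equal means within sampling error
  expect_equal(mean(d3$cfp) / mean(d3$yfp), 1, tolerance = 0.05)
})

test_that("the parametric generator obeys its moment identities", {
  # extrinsic_cv = 0: marginal CV equals the intrinsic CV
  d <- generate_parametric_dataset(100, cvs = 0.3, extrinsic_cv = 0,
                                   n_cells = 20000, seed = 69)
  expect_equal(sd(d$yfp) / mean(d$yfp), 0.3, tolerance = 0.03)
  # multiplicative composition of CVs
  d2 <- generate_parametric_dataset(100, cvs = 0.3, extrinsic_cv = 0.2,
                                    n_cells = 20000, seed = 70)
  cv_tot2 <- 0.3^2 + 0.2^2 + 0.3^2 * 0.2^2
  expect_equal((sd(d2$yfp) / mean(d2$yfp))^2, cv_tot2, tolerance = 0.08)
  # 8 well-separated conditions (relative to the equal-width bins),
  # tiny noise: ~3 bits
  d8 <- generate_parametric_dataset(seq(100, 2900, by = 400), cvs = 0.01,
                                    extrinsic_cv = 0, n_cells = 150, seed = 71)
  expect_equal(capacity_sweep(d8, seed = 72, n_resamples = 5)$capacity_bits,
               3, tolerance = 0.01)
})
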