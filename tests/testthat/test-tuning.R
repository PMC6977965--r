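test_that("cosine fits recover exact cosine tuning and conventions", {
  theta <- seq(-pi, pi, length.out = 721)[-1]
  rates <- 10 + 5 * cos(theta - pi / 6)
  f <- fit_cosine(rates, theta)
  expect_equal(f$b0, 10, tolerance = 1e-9)
  expect_equal(f$r, 5, tolerance = 1e-9)
  expect_equal(f$PD, pi / 6, tolerance = 1e-9)
  # atan2 conventions: (b1, b2) = (0, 1) -> 0 deg; (1, 0) -> 90 deg
  f01 <- fit_cosine(3 + cos(theta), theta)
  expect_equal(f01$PD, 0, tolerance = 1e-9)
  f10 <- fit_cosine(3 + sin(theta), theta)
  expect_equal(f10$PD, pi / 2, tolerance = 1e-9)
  expect_error(fit_cosine(c(1, 2, 3), c(0.5, 0.5, 0.5)), "distinct")
})

test_that("cosine reconstruction identity holds for arbitrary fits", {
  set.seed(61)
  theta <- runif(300, -pi, pi)
  for (i in 1:20) {
    rates <- rpois(300, exp(0.5 + 0.8 * cos(theta - runif(1, -pi, pi))))
    f <- fit_cosine(rates, theta)
    lhs <- f$b0 + f$r * cos(theta - f$PD)
    rhs <- f$b0 + f$b1 * sin(theta) + f$b2 * cos(theta)
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  }
})

test_that("empirical tuning curves summarize binned rates", {
  theta <- rep((0:15) * 2 * pi / 16, each = 30)
  flat <- empirical_tuning_curve(rep(10, length(theta)), theta)
  expect_equal(flat$mean, rep(10, 16))
  expect_equal(flat$ci_lo, flat$ci_hi)
  dense_theta <- runif(60000, -pi, pi)
  rates <- 10 + 5 * cos(dense_theta)
  curve <- empirical_tuning_curve(rates, dense_theta)
  # bin means approximate the curve at bin centers (flat-top correction
  # is below the stated 0.1 tolerance at 22.5-degree bins)
  expect_true(all(abs(curve$mean - (10 + 5 * cos(curve$center))) < 0.1))
  # permutation invariance
  o <- sample(length(dense_theta))
  curve2 <- empirical_tuning_curve(rates[o], dense_theta[o])
  expect_equal(curve2$mean, curve$mean)
  # an empty bin is reported NA with a warning
  expect_warning(ec <- empirical_tuning_curve(rep(1, 10), rep(0, 10)),
                 "empty")
  expect_true(is.na(ec$mean[9]))
})

test_that("bootstrap PDs are tight, equivariant and reproducible", {
  set.seed(62)
  theta <- runif(2000, -pi, pi)
  rates <- 10 + 5 * cos(theta - 0.7)
  pd1 <- bootstrap_pd(rates, theta, n_boot = 100, seed = 3)
  expect_lt(abs(wrap_angle(pd1$PD - 0.7)), pi / 180)
  expect_lt(diff(range(pd1$pd_samples)), 2 * pi / 180)
  # rotating all directions rotates the PD estimate
  phi <- 2.1
  pd2 <- bootstrap_pd(rates, wrap_angle(theta + phi), n_boot = 100, seed = 3)
  expect_lt(abs(wrap_angle(pd2$PD - pd1$PD - phi)), 2 * pi / 180)
  # determinism under the same seed
  pd3 <- bootstrap_pd(rates, theta, n_boot = 100, seed = 3)
  expect_identical(pd1$pd_samples, pd3$pd_samples)
})

test_that("shuffle-null tuning significance flags real tuning only", {
  set.seed(63)
  theta <- runif(1500, -pi, pi)
  strong <- rpois(1500, exp(1 + 1.2 * cos(theta - 1)))
  ts <- tuning_significance(strong, theta, n_boot = 100, seed = 5)
  expect_true(ts$tuned)
  expect_gt(ts$depth, ts$null_cut)
  zero <- rep(0, 1500)
  ts0 <- tuning_significance(zero, theta, n_boot = 50, seed = 5)
  expect_false(ts0$tuned)
  expect_equal(ts0$depth, 0)
})

test_that("PD shifts wrap on the circle", {
  deg <- function(x) x * pi / 180
  expect_equal(pd_shift(deg(170), deg(-170)), deg(20), tolerance = 1e-12)
  expect_equal(pd_shift(1.2, 1.2), 0)
  set.seed(64)
  a <- runif(50, -pi, pi); b <- runif(50, -pi, pi)
  expect_equal(pd_shift(a, b), -pd_shift(b, a), tolerance = 1e-12)
  expect_true(all(pd_shift(a, b) > -pi & pd_shift(a, b) <= pi))
})

test_that("circular VAF takes its textbook values", {
  sh <- (0:15) * 2 * pi / 16
  expect_equal(cvaf(sh, sh)$mean, 1)
  expect_equal(cvaf(sh, sh + pi / 2)$per_neuron, rep(0, 16),
               tolerance = 1e-12)
  expect_equal(cvaf(sh, sh + pi)$mean, -1)
  expect_equal(cvaf(c(pi / 4, -pi / 4), c(0, 0))$mean, cos(pi / 4),
               tolerance = 1e-12)
  expect_error(cvaf(1:3, 1:2), "length")
})

test_that("model-predicted tuning mirrors the observed pipeline", {
  ds <- bin_signals(small_two_ws_session(n_trials = 12, seed = 151))
  des <- build_design(ds, "whole_arm")
  fit <- fit_poisson_glm(des, ds$counts[, 1], neuron_id = "n1")
  mt <- model_predicted_tuning(fit, ds, condition = "ws1")
  expect_s3_class(mt$curve, "tuning_curve")
  expect_s3_class(mt$fit, "cosine_fit")
  # a "model" that reproduces observed counts exactly gives the observed
  # curve: compare via the correlation utility
  rows <- ds$condition == "ws1"
  obs_curve <- empirical_tuning_curve(ds$counts[rows, 1], ds$theta[rows])
  expect_equal(tuning_curve_correlation(list(obs_curve, obs_curve),
                                        list(obs_curve, obs_curve)), 1)
})

test_that("tuning-curve correlation is a location-free association", {
  theta <- rep((0:15) * 2 * pi / 16, each = 5)
  c1 <- empirical_tuning_curve(10 + 5 * cos(theta), theta)
  c2 <- empirical_tuning_curve(2 + 3 * cos(theta - 2), theta)
  shift1 <- c1; shift1$mean <- c1$mean + 7
  shift2 <- c2; shift2$mean <- c2$mean + 7
  neg <- c1; neg$mean <- -(c1$mean - mean(c1$mean))
  expect_equal(tuning_curve_correlation(list(c1, c2), list(c1, c2)), 1)
  expect_equal(tuning_curve_correlation(list(c1, c2), list(shift1, shift2)),
               1, tolerance = 1e-9)
  expect_equal(tuning_curve_correlation(list(c1, c1), list(neg, neg)), -1)
  flat <- c1; flat$mean <- rep(4, 16)
  expect_warning(
    r <- tuning_curve_correlation(list(flat, flat), list(c1, c2)),
    "variance")
  expect_true(is.na(r))
})
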