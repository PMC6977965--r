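test_that("two-class LDA separates what is separable", {
  set.seed(71)
  x <- c(rnorm(50, -10, 0.1), rnorm(50, 10, 0.1))
  y <- rep(c("a", "b"), each = 50)
  m <- fit_lda(x, y)
  expect_equal(mean(predict(m, x) == y), 1)
  # identical class distributions stay near chance out of sample
  x2 <- rnorm(400)
  y2 <- rep(c("a", "b"), 200)
  m2 <- fit_lda(x2[1:200], y2[1:200])
  acc <- mean(predict(m2, x2[201:400]) == y2[201:400])
  expect_lt(abs(acc - 0.5), 0.2)
  expect_error(fit_lda(x, rep("a", 100)), "2 classes")
})

test_that("equal-covariance LDA uses the perpendicular-bisector boundary", {
  set.seed(72)
  n <- 4000
  mu0 <- c(1, 2); mu1 <- c(3, -1)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2) + rep(mu0, each = n),
             matrix(rnorm(2 * n), ncol = 2) + rep(mu1, each = n))
  y <- rep(c("a", "b"), each = n)
  m <- fit_lda(X, y)
  # oracle: with identity covariance the boundary is the perpendicular
  # bisector; the discriminant direction is mu1 - mu0 and the midpoint
  # scores exactly at the threshold
  expect_equal(m$w / sqrt(sum(m$w^2)),
               (mu1 - mu0) / sqrt(sum((mu1 - mu0)^2)), tolerance = 0.05)
  mid_score <- sum(m$w * (colMeans(m$means)))
  expect_equal(mid_score, m$threshold, tolerance = 1e-9)
})

test_that("LDA accuracy is invariant to invertible affine maps", {
  set.seed(73)
  X <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 1.2), ncol = 2))
  y <- rep(c("a", "b"), each = 100)
  base <- separability_index(X, y, K = 5, R = 3, seed = 4)
  for (i in 1:3) {
    A <- matrix(rnorm(4), 2)
    while (abs(det(A)) < 0.2) A <- matrix(rnorm(4), 2)
    Xa <- X %*% t(A) + rep(rnorm(2), each = nrow(X))
    tr <- separability_index(Xa, y, K = 5, R = 3, seed = 4)
    expect_equal(tr$index, base$index, tolerance = 0.03)
  }
})

test_that("singular pooled covariance is ridge-jittered, not fatal", {
  X <- cbind(c(rep(0, 10), rep(1, 10)), 0)  # constant second feature
  y <- rep(c("a", "b"), each = 10)
  m <- fit_lda(X, y)
  expect_true(m$jittered)
  expect_equal(mean(predict(m, X) == y), 1)
})

test_that("separability index calibrates to its extremes and chance", {
  labs <- rep(c("active", "passive"), each = 100)
  # a perfect 1-D code
  perfect <- separability_index(as.numeric(labs == "active"), labs,
                                K = 5, R = 3, seed = 5)
  expect_equal(perfect$index, 1)
  expect_equal(perfect$chance, 0.5)
  # label-independent features stay within binomial bounds of chance
  set.seed(74)
  noise <- separability_index(rnorm(200), labs, K = 5, R = 20, seed = 6)
  expect_gt(noise$index, 0.38)
  expect_lt(noise$index, 0.62)
  expect_true(noise$ci[1] <= 0.5)
  # duplicating every trial leaves the index about unchanged
  dup <- separability_index(rep(rnorm(200), 2), rep(labs, 2), K = 5,
                            R = 20, seed = 6)
  expect_lt(abs(dup$index - noise$index), 0.1)
  expect_error(separability_index(rnorm(6), rep(c("a", "b"), 3), K = 5),
               "fewer")
})

test_that("separability CI widens with fold-score variance", {
  tight <- cv_confint(rep(c(0.79, 0.81), 50), 5, 20)
  wide <- cv_confint(rep(c(0.6, 1.0), 50), 5, 20)
  expect_lt(diff(tight), diff(wide))
  expect_equal(mean(tight), 0.8, tolerance = 1e-12)
})

test_that("kinematic separability reads the 12-D whole-arm window vector", {
  ses <- small_co_session(n_trials = 60, seed = 221)
  w <- extract_windows(ses, session_onsets(ses))
  ks <- kinematic_separability(w, K = 5, R = 5, seed = 7)
  expect_true(ks$index >= 0 && ks$index <= 1)
  # identical kinematics across conditions collapse to chance: relabel
  # conditions at random so features carry no class signal
  w2 <- w
  set.seed(75)
  w2$condition <- sample(w$condition)
  ks2 <- kinematic_separability(w2, K = 5, R = 5, seed = 7)
  expect_lt(abs(ks2$index - 0.5), 0.15)
})

test_that("consistency-separability correlation reports sign and CI", {
  set.seed(76)
  sep <- runif(40, 0.5, 1)
  cons <- -sep + rnorm(40, 0, 0.1)
  r <- consistency_vs_separability(cons, sep, n_boot = 2000, seed = 8)
  expect_lt(r$correlation, 0)
  expect_lt(r$ci[2], 0)
  expect_error(consistency_vs_separability(1:3, 1:3), "at least 5")
  expect_warning(
    r2 <- consistency_vs_separability(rnorm(10), rep(0.7, 10),
                                      n_boot = 100),
    "variance")
  expect_true(is.na(r2$correlation))
})

test_that("pooled-covariance LDA matches the reference implementation", {
  set.seed(77)
  X <- rbind(matrix(rnorm(300, 0), ncol = 3),
             matrix(rnorm(300, 0.8), ncol = 3))
  y <- rep(c("a", "b"), each = 100)
  mine <- fit_lda(X, y)
  ref <- MASS::lda(X, grouping = y, prior = c(0.5, 0.5))
  Xnew <- matrix(rnorm(600), ncol = 3)
  expect_equal(predict(mine, Xnew),
               as.character(predict(ref, Xnew)$class))
})
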