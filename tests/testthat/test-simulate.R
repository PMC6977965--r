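test_that("two-workspace sessions are reproducible and physically consistent", {
  ses1 <- small_two_ws_session(seed = 101)
  ses2 <- small_two_ws_session(seed = 101)
  expect_identical(ses1$counts, ses2$counts)
  expect_identical(ses1$samples, ses2$samples)
  # link-length conservation at every sample
  g <- ses1$geometry
  err_u <- abs(sqrt(ses1$samples$elbow_x^2 + ses1$samples$elbow_y^2) -
                 g$upper_arm_length)
  err_f <- abs(sqrt((ses1$samples$hand_x - ses1$samples$elbow_x)^2 +
                      (ses1$samples$hand_y - ses1$samples$elbow_y)^2) -
                 g$forearm_length)
  expect_lt(max(err_u), 1e-9)
  expect_lt(max(err_f), 1e-9)
  # analytic hand velocity agrees with position finite differences
  tr1 <- ses1$samples[ses1$samples$trial_id == 1, ]
  fd <- diff(tr1$hand_x) / diff(tr1$t)
  mid <- (tr1$hand_vx[-1] + tr1$hand_vx[-nrow(tr1)]) / 2
  expect_lt(max(abs(fd - mid)), 0.05 * max(abs(tr1$hand_vx)) + 1e-6)
})

test_that("workspace assignment is uniform and targets stay in the square", {
  ses <- simulate_two_workspace_session(
    task_config(n_trials = 100), arm_geometry(),
    neuron_population(1, "untuned", prefix = "u"), seed = 5)
  counts <- table(ses$events$condition)
  # binomial(100, 1/2) 99% bounds
  expect_true(all(counts >= 37 & counts <= 63))
  cfg <- task_config()
  for (ws_id in 1:2) {
    ws <- cfg$workspaces[[ws_id]]
    rows <- ses$samples$condition == paste0("ws", ws_id)
    expect_true(all(abs(ses$samples$hand_x[rows] - ws$center[1]) <=
                      ws$side / 2 + 1e-9))
    expect_true(all(abs(ses$samples$hand_y[rows] - ws$center[2]) <=
                      ws$side / 2 + 1e-9))
  }
  # mean hand position separates by roughly the workspace-center distance
  m1 <- colMeans(ses$samples[ses$samples$condition == "ws1",
                             c("hand_x", "hand_y")])
  m2 <- colMeans(ses$samples[ses$samples$condition == "ws2",
                             c("hand_x", "hand_y")])
  d_centers <- sqrt(sum((cfg$workspaces[[1]]$center -
                           cfg$workspaces[[2]]$center)^2))
  expect_equal(sqrt(sum((m1 - m2)^2)), d_centers, tolerance = 0.25)
})

test_that("unreachable workspaces are rejected before simulation", {
  cfg <- task_config(workspaces = list(
    list(center = c(0, 0.5), side = 0.1),
    list(center = c(0.05, 0.25), side = 0.1)))
  expect_error(
    simulate_two_workspace_session(cfg, arm_geometry(),
                                   neuron_population(1, "untuned")),
    "reachable")
})

test_that("center-out sessions alternate conditions and bump as commanded", {
  ses <- small_co_session(n_trials = 40, seed = 201)
  expect_equal(as.integer(table(ses$events$condition)[c("active", "passive")]),
               c(20L, 20L))
  # passive initial velocity within 15 degrees of the bump direction
  pas <- ses$events[ses$events$condition == "passive", ]
  for (i in seq_len(nrow(pas))) {
    tr <- pas$trial_id[i]
    rows <- which(ses$samples$trial_id == tr &
                    ses$samples$t > pas$bump_onset[i] + 0.015 &
                    ses$samples$t < pas$bump_onset[i] + 0.045)
    v <- colMeans(ses$samples[rows, c("hand_vx", "hand_vy")])
    ang_err <- abs(wrap_angle(atan2(v[2], v[1]) - pas$movement_dir[i]))
    expect_lt(ang_err, 15 * pi / 180)
  }
})

test_that("zero bump force produces zero passive displacement", {
  ses <- small_co_session(n_trials = 10, seed = 301, bump_force = 0)
  pas_tr <- ses$events$trial_id[ses$events$condition == "passive"]
  for (tr in pas_tr) {
    rows <- ses$samples$trial_id == tr
    expect_lt(max(abs(ses$samples$hand_vx[rows])), 1e-12)
    expect_lt(diff(range(ses$samples$hand_x[rows])), 1e-12)
    expect_lt(diff(range(ses$samples$hand_y[rows])), 1e-12)
  }
})

test_that("spike generation matches its Poisson law", {
  # intercept-only neuron: mean count near exp(intercept) over many bins
  nrn <- ground_truth_neuron("u1", "untuned", intercept = log(2))
  covs <- data.frame(trial_id = 1L, dummy = numeric(10000))
  counts <- generate_spike_counts(list(nrn), covs, dt = 0.05,
                                  bin_width = 0.05, seed = 9)
  m <- mean(counts)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - 2), 3 * se)
  expect_true(all(counts >= 0 & counts == round(counts)))
})

test_that("condition gains of zero silence the tuned drive", {
  nrn <- ground_truth_neuron("g0", "hand_only", intercept = log(1.5),
                             coefficients = c(0, 0, 0, 5, 5, 0),
                             active_gain = 0, passive_gain = 0)
  covs <- data.frame(trial_id = 1L,
                     hand_x = rnorm(4000, 0, 0.05),
                     hand_y = rnorm(4000, 0.2, 0.05), hand_z = 0,
                     hand_vx = rnorm(4000, 0, 0.2),
                     hand_vy = rnorm(4000, 0, 0.2), hand_vz = 0)
  cond <- rep(c("active", "passive"), 2000)
  counts <- generate_spike_counts(list(nrn), covs, dt = 0.05,
                                  condition = cond, seed = 10)
  m <- mean(counts)
  expect_lt(abs(m - 1.5), 3 * sd(counts) / sqrt(length(counts)))
  # no dependence on the (silenced) velocity covariate
  expect_lt(abs(cor(counts[, 1], covs$hand_vx)), 0.05)
})

test_that("velocity-tuned neurons follow the exp-cosine rate law", {
  theta <- runif(6000, -pi, pi)
  speed <- 0.2
  covs <- data.frame(trial_id = 1L, hand_x = 0, hand_y = 0.2, hand_z = 0,
                     hand_vx = speed * cos(theta),
                     hand_vy = speed * sin(theta), hand_vz = 0)
  b <- c(3, 4)  # tuned to velocity with PD atan2(4, 3)
  nrn <- ground_truth_neuron("c1", "hand_only", intercept = log(1),
                             coefficients = c(0, 0, 0, b, 0))
  counts <- generate_spike_counts(list(nrn), covs, dt = 0.05, seed = 11)
  bins <- bin_directions(theta)
  emp <- tapply(counts[, 1], bins, mean)
  centers <- (0:15) * 2 * pi / 16
  r <- speed * sqrt(sum(b^2))
  pd <- atan2(b[2], b[1])
  analytic <- exp(r * cos(centers - pd))
  expect_gt(cor(as.numeric(emp), analytic), 0.98)
  expect_equal(as.numeric(emp), analytic, tolerance = 0.15)
})

test_that("generation validates coefficient dimensionality", {
  bad <- ground_truth_neuron("b", "hand_only", 0, coefficients = c(1, 2))
  covs <- data.frame(trial_id = 1L, hand_x = 0, hand_y = 0, hand_z = 0,
                     hand_vx = 0, hand_vy = 0, hand_vz = 0)
  expect_error(generate_spike_counts(list(bad), covs, dt = 0.05),
               "coefficients")
})
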