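test_that("binning averages covariates and conserves spike counts", {
  ses <- small_two_ws_session(seed = 111)
  ds <- bin_signals(ses)
  expect_s3_class(ds, "binned_dataset")
  expect_equal(nrow(ds$covariates), nrow(ds$counts))
  expect_equal(length(ds$trial_id), nrow(ds$counts))
  expect_true(all(ds$theta > -pi & ds$theta <= pi))
  # hand_z is constant zero -> every bin zero
  expect_true(all(ds$covariates$hand_z == 0))
  # oracle: direct summation of counts over retained complete bins
  n_per <- as.integer(round(ds$bin_width / ses$sim_dt))
  total_direct <- 0
  for (tr in unique(ses$samples$trial_id)) {
    idx <- which(ses$samples$trial_id == tr)
    hold_end <- ses$events$hold_end[ses$events$trial_id == tr]
    keep <- idx[ses$samples$t[idx] >= hold_end - 1e-9]
    keep <- keep[seq_len((length(keep) %/% n_per) * n_per)]
    total_direct <- total_direct + sum(ses$counts[keep, ])
  }
  expect_equal(sum(ds$counts), total_direct)
  # hold samples (before hold_end) are excluded: bins per trial match the
  # post-hold duration
  per_trial <- table(ds$trial_id)
  cfg <- ses$config
  expected_bins <- round(cfg$targets_per_trial * cfg$movement_duration /
                           cfg$bin_width)
  expect_true(all(per_trial == expected_bins))
})

test_that("bin width must subdivide the simulation step grid", {
  ses <- small_two_ws_session(seed = 112)
  expect_error(bin_signals(ses, bin_width = 0.005), "multiple")
  expect_error(bin_signals(ses, bin_width = 0.033), "multiple")
})

test_that("movement onset follows the backward 10%-of-peak sweep", {
  # hand-traced example: peak 10 at 40 ms, threshold 1; sweep stops at the
  # last sample >= threshold (20 ms); the 0.5 sample is excluded
  accel <- c(0, 0.5, 2, 6, 10, 7)
  t <- seq(0, 0.05, by = 0.01)
  expect_equal(detect_movement_onset(accel, t, 0), 0.02)
  # delta spike: onset at that sample
  expect_equal(detect_movement_onset(c(0, 0, 5, 0), (0:3) / 100, 0), 0.02)
  # invariance to positive rescaling
  expect_equal(detect_movement_onset(accel * 37.3, t, 0), 0.02)
  # search start restricts the peak, not the backward sweep
  accel2 <- c(1, 3, 1, 0, 2, 8, 4)
  t2 <- (0:6) / 100
  expect_equal(detect_movement_onset(accel2, t2, 0.03), 0.04)
  expect_error(detect_movement_onset(c(0, 0), c(0, 0.01), 0.02), "samples")
  expect_error(detect_movement_onset(c(0, 0), c(0, 0.01), 0), "zero")
})

test_that("windows convert counts to rates over exactly 120 ms", {
  ses <- small_co_session(n_trials = 20, seed = 211)
  on <- session_onsets(ses)
  w <- extract_windows(ses, on)
  expect_s3_class(w, "trial_windows")
  expect_equal(w$rates, w$counts / 0.12)
  # a neuron with 3 spikes in its window reports 25 spikes/s
  expect_true(any(w$counts == 3))
  expect_equal(unique(w$rates[w$counts == 3]), 25)
  # window-averaged velocity equals displacement over the window
  i <- which.max(abs(w$covariates$hand_vx))
  tr <- w$trial_id[i]
  rows <- which(ses$samples$trial_id == tr)
  t0 <- on$onset[on$trial_id == tr]
  sel <- rows[ses$samples$t[rows] >= t0 - 1e-9 &
                ses$samples$t[rows] < t0 + 0.12 - 1e-9]
  disp <- ses$samples$hand_x[max(sel) + 1] - ses$samples$hand_x[min(sel)]
  expect_equal(w$covariates$hand_vx[i], disp / 0.12, tolerance = 0.15)
  # a window running past the trial end drops the trial with a warning
  bad <- data.frame(trial_id = 1, onset = max(ses$samples$t[
    ses$samples$trial_id == 1]) - 0.05)
  expect_warning(expect_error(extract_windows(ses, bad), "complete"),
                 "dropped")
})

test_that("direction bins partition the circle with the stated convention", {
  deg <- function(x) x * pi / 180
  expect_equal(bin_directions(deg(5)), 0L)
  expect_equal(bin_directions(deg(350)), 0L)
  expect_equal(bin_directions(deg(11.25)), 1L)   # upper edge excluded
  expect_equal(bin_directions(deg(-11.25)), 0L)  # lower edge included
  expect_equal(bin_directions(deg(168.75)), 8L)
  # every angle lands in exactly one bin, the nearest center
  theta <- seq(-3 * pi, 3 * pi, length.out = 1001)
  b <- bin_directions(theta)
  expect_true(all(b >= 0 & b <= 15))
  centers <- (0:15) * 2 * pi / 16
  nearest <- vapply(theta, function(a) {
    which.min(abs(wrap_angle(a - centers)))[1] - 1L
  }, 0L)
  off_boundary <- abs(abs(wrap_angle(theta %% (2 * pi / 16))) -
                        pi / 16) > 1e-6
  expect_equal(b[off_boundary], nearest[off_boundary])
  expect_error(bin_directions(c(0, NA)), "finite")
})

test_that("uniform resampling flattens the direction histogram", {
  set.seed(3)
  # already uniform: 10 per bin stays 10 per bin
  theta <- rep((0:15) * 2 * pi / 16, each = 10)
  idx <- uniform_direction_resample(theta)
  expect_equal(length(idx), 160)
  tab <- tabulate(bin_directions(theta[idx]) + 1, 16)
  expect_equal(diff(range(tab)), 0)
  # median rule: bins of 100 and 50 among 75s draw 75 each
  sizes <- c(100, 50, rep(75, 14))
  theta2 <- rep((0:15) * 2 * pi / 16, times = sizes)
  idx2 <- uniform_direction_resample(theta2)
  tab2 <- tabulate(bin_directions(theta2[idx2]) + 1, 16)
  expect_true(all(tab2 == 75))
  # an empty bin is an error naming the bin
  theta3 <- rep(c(0, pi / 2), 50)
  expect_error(uniform_direction_resample(theta3), "bin 1")
})
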