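#' Task configuration for synthetic sessions
#'
#' Collects the behavioral parameters of the two simulated tasks. Defaults
#' follow the experimental design the package emulates: 50 ms analysis bins,
#' two 10 x 10 cm workspaces (near-contralateral and far-ipsilateral for a
#' right arm), 2 N passive bumps, and a 120 ms post-onset analysis window.
#'
#' @param bin_width Analysis bin width (s).
#' @param workspaces List of workspaces, each `list(center = c(x, y), side)`
#'   in metres. Two for the two-workspace task.
#' @param n_trials Number of trials.
#' @param targets_per_trial Reaches per trial (two-workspace task).
#' @param movement_duration Duration of one reach (s).
#' @param hold_duration Center-hold before the first movement (s).
#' @param bump_force Passive perturbation amplitude (N).
#' @param bump_duration Perturbation pulse length (s).
#' @param analysis_window Post-onset analysis window (s); must be an
#'   integer multiple of `sim_dt`.
#' @param sim_dt Simulation sample step (s); `bin_width` and
#'   `analysis_window` must be integer multiples of it.
#' @param center Center-out start point (m), also the full-workspace center.
#' @param reach_distance Center-out target distance (m).
#' @param hand_mass Effective hand + handle mass for the passive point-mass
#'   model (kg).
#' @param hand_damping 2-vector of damping coefficients along x and y
#'   (N s/m) for the passive model; mild anisotropy stands in for the
#'   direction-dependent impedance of the arm.
#' @param passive_drift_force 2-vector (N): constant postural-yield force
#'   acting on the hand while the bump displaces it, modeling the
#'   unstabilized arm sagging toward the body irrespective of bump
#'   direction. This is what makes passive arm kinematics (notably the
#'   elbow path) systematically different from active reaches.
#' @param position_jitter_sd SD of start/target position jitter (m).
#' @param bump_jitter_frac Multiplicative SD of trial-to-trial bump
#'   amplitude variation.
#' @param reaction_time_range Range of active-trial reaction times (s).
#' @param rng_seed Integer seed recorded with the config.
#' @return Object of class `task_config`.
#' @export
task_config <- function(bin_width = 0.05,
                        workspaces = list(
                          list(center = c(-0.05, 0.15), side = 0.10),
                          list(center = c(0.05, 0.25), side = 0.10)),
                        n_trials = 100,
                        targets_per_trial = 3,
                        movement_duration = 0.6,
                        hold_duration = 0.3,
                        bump_force = 2.0,
                        bump_duration = 0.13,
                        analysis_window = 0.120,
                        sim_dt = 0.01,
                        center = c(0, 0.20),
                        reach_distance = 0.08,
                        hand_mass = 0.6,
                        hand_damping = c(9, 10.5),
                        passive_drift_force = c(0, -0.3),
                        position_jitter_sd = 0.002,
                        bump_jitter_frac = 0.1,
                        reaction_time_range = c(0.25, 0.35),
                        rng_seed = 1L) {
  check_scalar_pos(bin_width, "bin_width")
  check_scalar_pos(sim_dt, "sim_dt")
  check_scalar_pos(movement_duration, "movement_duration")
  stopifnot(n_trials > 0, targets_per_trial > 0, bump_force >= 0,
            length(hand_damping) == 2, all(hand_damping > 0), hand_mass > 0)
  for (w in workspaces) {
    stopifnot(length(w$center) == 2, w$side > 0)
  }
  mult_ok <- function(x) abs(x / sim_dt - round(x / sim_dt)) < 1e-9
  if (!mult_ok(bin_width)) {
    stop_invalid("bin_width must be an integer multiple of sim_dt")
  }
  if (!mult_ok(analysis_window)) {
    stop_invalid("analysis_window must be an integer multiple of sim_dt")
  }
  structure(
    list(bin_width = bin_width, workspaces = workspaces, n_trials = n_trials,
         targets_per_trial = targets_per_trial,
         movement_duration = movement_duration,
         hold_duration = hold_duration,
         bump_force = bump_force, bump_duration = bump_duration,
         analysis_window = analysis_window, sim_dt = sim_dt,
         center = center, reach_distance = reach_distance,
         hand_mass = hand_mass, hand_damping = hand_damping,
         passive_drift_force = passive_drift_force,
         position_jitter_sd = position_jitter_sd,
         bump_jitter_frac = bump_jitter_frac,
         reaction_time_range = reaction_time_range,
         rng_seed = as.integer(rng_seed)),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("Task config: %d trials, %.0f ms bins, %.0f ms window, %.1f N bump\n",
              x$n_trials, 1000 * x$bin_width, 1000 * x$analysis_window,
              x$bump_force))
  invisible(x)
}

# check that a square workspace is fully inside the reachable annulus
check_workspace_reachable <- function(ws, geometry) {
  s <- geometry$shoulder_origin[1:2]
  half <- ws$side / 2
  corners <- rbind(
    ws$center + c(-half, -half), ws$center + c(half, -half),
    ws$center + c(-half, half), ws$center + c(half, half))
  d <- sqrt((corners[, 1] - s[1])^2 + (corners[, 2] - s[2])^2)
  lo <- abs(geometry$upper_arm_length - geometry$forearm_length)
  hi <- geometry$upper_arm_length + geometry$forearm_length
  # nearest point of the square to the shoulder may be interior to an edge
  px <- pmin(pmax(s[1], ws$center[1] - half), ws$center[1] + half)
  py <- pmin(pmax(s[2], ws$center[2] - half), ws$center[2] + half)
  dmin <- sqrt((px - s[1])^2 + (py - s[2])^2)
  if (max(d) > hi - 1e-6 || dmin < lo + 1e-6) {
    stop_invalid(
      "workspace centered at (%.2f, %.2f) is not fully reachable by the arm",
      ws$center[1], ws$center[2])
  }
  invisible(TRUE)
}
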