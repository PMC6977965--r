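# ---- internal trial-kinematics helpers -------------------------------------

# evaluate a minimum-jerk segment analytically at arbitrary local times
mj_eval <- function(p0, p1, duration, tl) {
  tau <- pmin(pmax(tl / duration, 0), 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  ds <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration
  dds <- (60 * tau - 180 * tau^2 + 120 * tau^3) / duration^2
  d <- p1 - p0
  list(pos = cbind(p0[1] + s * d[1], p0[2] + s * d[2]),
       vel = cbind(ds * d[1], ds * d[2]),
       acc = cbind(dds * d[1], dds * d[2]))
}

# kinematics of a hold followed by a chain of minimum-jerk reaches
reach_chain_kinematics <- function(points, hold, duration, dt) {
  n_seg <- nrow(points) - 1
  total <- hold + n_seg * duration
  t <- seq(0, total - dt / 2, by = dt)
  pos <- matrix(0, length(t), 2)
  vel <- matrix(0, length(t), 2)
  acc <- matrix(0, length(t), 2)
  in_hold <- t < hold - 1e-9
  pos[in_hold, 1] <- points[1, 1]
  pos[in_hold, 2] <- points[1, 2]
  mv <- which(!in_hold)
  if (length(mv)) {
    tm <- t[mv] - hold
    seg <- pmin(floor(tm / duration + 1e-9), n_seg - 1)
    tl <- tm - seg * duration
    for (s in unique(seg)) {
      ix <- which(seg == s)
      ev <- mj_eval(points[s + 1, ], points[s + 2, ], duration, tl[ix])
      pos[mv[ix], ] <- ev$pos
      vel[mv[ix], ] <- ev$vel
      acc[mv[ix], ] <- ev$acc
    }
  }
  list(t = t, pos = pos, vel = vel, acc = acc)
}

# passive point-mass-with-damping displacement under a force pulse;
# exact per-axis update of m v' = F - c v between samples
bump_kinematics <- function(start, force_vec, bump_onset, bump_duration,
                            total, mass, damping, dt,
                            drift_force = c(0, 0)) {
  t <- seq(0, total - dt / 2, by = dt)
  n <- length(t)
  pos <- matrix(rep(start, each = n), n, 2)
  vel <- matrix(0, n, 2)
  acc <- matrix(0, n, 2)
  v <- c(0, 0)
  p <- start
  for (i in seq_len(n)) {
    moving <- t[i] >= bump_onset - 1e-9
    in_pulse <- moving && t[i] < bump_onset + bump_duration - 1e-9
    # the postural-yield drift acts while the perturbation displaces the
    # arm (no drift before the bump, when the hold is actively maintained)
    f <- if (in_pulse) force_vec + drift_force else c(0, 0)
    pos[i, ] <- p
    vel[i, ] <- v
    acc[i, ] <- (f - damping * v) / mass
    vinf <- f / damping
    decay <- exp(-damping * dt / mass)
    p <- p + vinf * dt + (v - vinf) * (mass / damping) * (1 - decay)
    v <- vinf + (v - vinf) * decay
  }
  list(t = t, pos = pos, vel = vel, acc = acc)
}

# assemble the full per-sample covariate table + counts for a session
assemble_session <- function(trials, neurons, geometry, config, seed,
                             task) {
  dt <- config$sim_dt
  samp_list <- list()
  for (tr in seq_along(trials)) {
    k <- trials[[tr]]$kin
    hand <- k$pos
    elbow <- elbow_from_hand(hand, geometry)
    q <- joint_angles(hand, elbow, geometry)
    ml <- surrogate_muscle_lengths(q, dt, geometry)
    elbow_v <- central_diff(elbow, dt)
    dq <- central_diff(q, dt)
    n <- nrow(hand)
    force <- trials[[tr]]$force
    df <- data.frame(
      trial_id = tr, t = k$t, condition = trials[[tr]]$condition,
      hand_x = hand[, 1], hand_y = hand[, 2], hand_z = 0,
      hand_vx = k$vel[, 1], hand_vy = k$vel[, 2], hand_vz = 0,
      hand_ax = k$acc[, 1], hand_ay = k$acc[, 2], hand_az = 0,
      elbow_x = elbow[, 1], elbow_y = elbow[, 2], elbow_z = 0,
      elbow_vx = elbow_v[, 1], elbow_vy = elbow_v[, 2], elbow_vz = 0,
      q1 = q[, 1], q2 = q[, 2], dq1 = dq[, 1], dq2 = dq[, 2],
      fx = force[, 1], fy = force[, 2], fz = force[, 3],
      tx = force[, 4], ty = force[, 5], tz = force[, 6],
      stringsAsFactors = FALSE)
    lcols <- as.data.frame(ml$lengths)
    names(lcols) <- paste0("len_", names(lcols))
    dcols <- as.data.frame(ml$dlengths)
    names(dcols) <- paste0("dlen_", colnames(ml$dlengths))
    samp_list[[tr]] <- cbind(df, lcols, dcols)
  }
  samples <- do.call(rbind, samp_list)
  rownames(samples) <- NULL
  events <- do.call(rbind, lapply(seq_along(trials), function(tr) {
    e <- trials[[tr]]$events
    data.frame(trial_id = tr, condition = trials[[tr]]$condition,
               hold_end = e$hold_end, go_cue = e$go_cue,
               bump_onset = e$bump_onset, movement_dir = e$movement_dir,
               stringsAsFactors = FALSE)
  }))
  counts <- generate_spike_counts(
    neurons, samples, dt = dt, bin_width = config$bin_width,
    condition = samples$condition, trial_id = samples$trial_id)
  structure(
    list(samples = samples, counts = counts, events = events,
         neurons = neurons, geometry = geometry, config = config,
         sim_dt = dt, rng_seed = seed, task = task),
    class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("Synthetic %s session: %d trials, %d samples x %d neurons (dt %.0f ms)\n",
              x$task, nrow(x$events), nrow(x$samples), ncol(x$counts),
              1000 * x$sim_dt))
  invisible(x)
}

force_noise <- function(n, sd_f = 0.05, sd_t = 0.01) {
  cbind(stats::rnorm(n, 0, sd_f), stats::rnorm(n, 0, sd_f),
        stats::rnorm(n, 0, sd_f), stats::rnorm(n, 0, sd_t),
        stats::rnorm(n, 0, sd_t), stats::rnorm(n, 0, sd_t))
}

clamp_to_square <- function(p, center, side) {
  half <- side / 2
  c(min(max(p[1], center[1] - half), center[1] + half),
    min(max(p[2], center[2] - half), center[2] + half))
}

#' Simulate a two-workspace random-target session
#'
#' Each trial picks one of the two 10 x 10 cm workspaces uniformly at
#' random; after a center-hold at the (jittered) workspace center the hand
#' performs a chain of minimum-jerk reaches to targets drawn uniformly in
#' the square. The elbow follows from closed-form two-link inverse
#' kinematics, so hand and elbow kinematics are decorrelated only through
#' the workspace manipulation — the design feature the task exists for.
#' Handle force on these active movements is effective hand mass times hand
#' acceleration plus sensor noise. Ground-truth Poisson spike counts are
#' drawn at the simulation rate.
#'
#' @param config A [task_config()] with exactly 2 workspaces.
#' @param geometry An [arm_geometry()].
#' @param neurons List of [ground_truth_neuron()] objects.
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @return A `synthetic_session` object; conditions are `"ws1"` / `"ws2"`.
#' @export
simulate_two_workspace_session <- function(config, geometry, neurons,
                                           seed = config$rng_seed) {
  stopifnot(inherits(config, "task_config"), length(config$workspaces) == 2)
  force(neurons)
  for (w in config$workspaces) check_workspace_reachable(w, geometry)
  with_seed(seed, {
    trials <- lapply(seq_len(config$n_trials), function(tr) {
      ws_id <- sample.int(2, 1)
      ws <- config$workspaces[[ws_id]]
      start <- clamp_to_square(
        ws$center + stats::rnorm(2, 0, config$position_jitter_sd),
        ws$center, ws$side)
      targets <- t(replicate(config$targets_per_trial,
        ws$center + stats::runif(2, -ws$side / 2, ws$side / 2)))
      kin <- reach_chain_kinematics(rbind(start, targets),
                                    config$hold_duration,
                                    config$movement_duration, config$sim_dt)
      force <- force_noise(length(kin$t))
      force[, 1] <- force[, 1] + config$hand_mass * kin$acc[, 1]
      force[, 2] <- force[, 2] + config$hand_mass * kin$acc[, 2]
      list(kin = kin, force = force, condition = paste0("ws", ws_id),
           events = list(hold_end = config$hold_duration, go_cue = NA_real_,
                         bump_onset = NA_real_, movement_dir = NA_real_))
    })
    assemble_session(trials, neurons, geometry, config, seed,
                     task = "two_workspace")
  })
}

#' Simulate a center-out active/passive session
#'
#' Active trials: after a center hold and a go cue, the hand reaches with a
#' minimum-jerk profile to one of 4 targets at 0, 90, 180 and 270 degrees.
#' Passive trials (half the session, alternating by default): during the
#' hold, the manipulandum bumps the hand with a `bump_force` pulse in one
#' of the four target directions; the hand then moves as a damped point
#' mass, with mildly anisotropic damping standing in for the
#' direction-dependent impedance of the arm. Point-mass parameters are
#' chosen so that hand speed over the 120 ms analysis window approximates
#' the active reaches. Recorded handle force is the commanded pulse
#' (passive) or mass times acceleration (active), plus sensor noise.
#'
#' @param config A [task_config()]; `center`, `reach_distance`,
#'   `bump_force`, `hand_mass`, `hand_damping` matter here.
#' @param geometry An [arm_geometry()].
#' @param neurons List of [ground_truth_neuron()] objects; their
#'   `active_gain` / `passive_gain` take effect in this task.
#' @param assignment `"alternate"` (exact 50/50) or `"random"`.
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @return A `synthetic_session`; conditions are `"active"` / `"passive"`,
#'   and `events` carries go-cue and bump-onset times and the nominal
#'   movement direction of every trial.
#' @export
simulate_center_out_session <- function(config, geometry, neurons,
                                        assignment = c("alternate", "random"),
                                        seed = config$rng_seed) {
  stopifnot(inherits(config, "task_config"))
  assignment <- match.arg(assignment)
  force(neurons); force(geometry)
  dirs <- c(0, pi / 2, pi, 3 * pi / 2)
  with_seed(seed, {
    is_passive <- if (assignment == "alternate") {
      seq_len(config$n_trials) %% 2 == 0
    } else {
      stats::runif(config$n_trials) < 0.5
    }
    trials <- lapply(seq_len(config$n_trials), function(tr) {
      d <- sample(dirs, 1)
      start <- config$center + stats::rnorm(2, 0, config$position_jitter_sd)
      if (is_passive[tr]) {
        amp <- max(config$bump_force *
                     (1 + config$bump_jitter_frac * stats::rnorm(1)), 0)
        bump_onset <- config$hold_duration
        drift <- if (amp > 0) config$passive_drift_force else c(0, 0)
        kin <- bump_kinematics(
          start, amp * c(cos(d), sin(d)), bump_onset, config$bump_duration,
          total = bump_onset + 0.6, mass = config$hand_mass,
          damping = config$hand_damping, dt = config$sim_dt,
          drift_force = drift)
        force <- force_noise(length(kin$t))
        pulse <- kin$t >= bump_onset - 1e-9 &
          kin$t < bump_onset + config$bump_duration - 1e-9
        force[pulse, 1] <- force[pulse, 1] + amp * cos(d)
        force[pulse, 2] <- force[pulse, 2] + amp * sin(d)
        list(kin = kin, force = force, condition = "passive",
             events = list(hold_end = bump_onset, go_cue = NA_real_,
                           bump_onset = bump_onset, movement_dir = d))
      } else {
        rt <- stats::runif(1, config$reaction_time_range[1],
                           config$reaction_time_range[2])
        target <- config$center + config$reach_distance * c(cos(d), sin(d)) +
          stats::rnorm(2, 0, config$position_jitter_sd)
        kin <- reach_chain_kinematics(
          rbind(start, target), config$hold_duration + rt,
          config$movement_duration, config$sim_dt)
        # 200 ms tail at the target so the analysis window always fits
        tail_n <- as.integer(round(0.2 / config$sim_dt))
        extra_t <- kin$t[length(kin$t)] + config$sim_dt * seq_len(tail_n)
        kin$t <- c(kin$t, extra_t)
        kin$pos <- rbind(kin$pos, matrix(rep(kin$pos[nrow(kin$pos), ],
                                             each = tail_n), tail_n, 2))
        kin$vel <- rbind(kin$vel, matrix(0, tail_n, 2))
        kin$acc <- rbind(kin$acc, matrix(0, tail_n, 2))
        force <- force_noise(length(kin$t))
        force[, 1] <- force[, 1] + config$hand_mass * kin$acc[, 1]
        force[, 2] <- force[, 2] + config$hand_mass * kin$acc[, 2]
        list(kin = kin, force = force, condition = "active",
             events = list(hold_end = config$hold_duration,
                           go_cue = config$hold_duration,
                           bump_onset = NA_real_, movement_dir = d))
      }
    })
    assemble_session(trials, neurons, geometry, config, seed,
                     task = "center_out")
  })
}

#' Detect movement onsets for every trial of a center-out session
#'
#' Applies [detect_movement_onset()] trial by trial, searching from the
#' bump time on passive trials and from go-cue + 200 ms on active trials,
#' using the magnitude of the recorded hand acceleration.
#'
#' @param session A center-out `synthetic_session`.
#' @return Data frame with `trial_id` and `onset` (s, trial clock).
#' @export
session_onsets <- function(session) {
  stopifnot(inherits(session, "synthetic_session"))
  ev <- session$events
  onsets <- vapply(seq_len(nrow(ev)), function(i) {
    tr <- ev$trial_id[i]
    idx <- which(session$samples$trial_id == tr)
    accel <- sqrt(session$samples$hand_ax[idx]^2 +
                    session$samples$hand_ay[idx]^2)
    start <- if (ev$condition[i] == "passive") ev$bump_onset[i] else
      ev$go_cue[i] + 0.2
    # a trial with no detectable movement (e.g. zero-amplitude bump) gets
    # its window anchored at the search start instead of failing
    tryCatch(detect_movement_onset(accel, session$samples$t[idx], start),
             error = function(e) start)
  }, 0)
  data.frame(trial_id = ev$trial_id, onset = onsets)
}
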