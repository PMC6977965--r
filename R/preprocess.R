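#' Bin a session into analysis bins
#'
#' Averages covariates and sums spike counts over consecutive `bin_width`
#' windows within each trial's retained epoch (from the end of the
#' center-hold period to the end of the trial; hold samples are discarded,
#' as are incomplete bins at the end of a trial). Each bin's movement
#' direction is the direction of its bin-averaged hand velocity.
#'
#' @param session A [simulate_two_workspace_session()] /
#'   [simulate_center_out_session()] session.
#' @param bin_width Bin width (s); integer multiple of the simulation step.
#' @return Object of class `binned_dataset`: `covariates` (data frame),
#'   `counts` (T x N integer matrix), `bin_width`, `trial_id`, `condition`,
#'   `theta` (rad, (-pi, pi]), `direction_bin` (0-15).
#' @export
bin_signals <- function(session, bin_width = session$config$bin_width) {
  stopifnot(inherits(session, "synthetic_session"))
  dt <- session$sim_dt
  ratio <- bin_width / dt
  if (bin_width < dt || abs(ratio - round(ratio)) > 1e-9) {
    stop_invalid("bin_width must be an integer multiple of the %.0f ms simulation step",
                 1000 * dt)
  }
  n_per <- as.integer(round(ratio))
  samp <- session$samples
  cov_cols <- setdiff(colnames(samp), c("trial_id", "t", "condition"))
  rows_list <- list()
  counts_list <- list()
  meta_list <- list()
  for (tr in unique(samp$trial_id)) {
    idx <- which(samp$trial_id == tr)
    hold_end <- session$events$hold_end[session$events$trial_id == tr]
    keep <- idx[samp$t[idx] >= hold_end - 1e-9]
    n_bins <- length(keep) %/% n_per
    if (n_bins == 0) next
    keep <- keep[seq_len(n_bins * n_per)]
    grp <- rep(seq_len(n_bins), each = n_per)
    cv <- as.matrix(samp[keep, cov_cols])
    binned_cov <- rowsum(cv, grp) / n_per
    binned_cnt <- rowsum(session$counts[keep, , drop = FALSE], grp)
    rows_list[[length(rows_list) + 1]] <- binned_cov
    counts_list[[length(counts_list) + 1]] <- binned_cnt
    meta_list[[length(meta_list) + 1]] <- data.frame(
      trial_id = tr, condition = samp$condition[keep[1]],
      stringsAsFactors = FALSE)[rep(1, n_bins), ]
  }
  covariates <- as.data.frame(do.call(rbind, rows_list))
  counts <- do.call(rbind, counts_list)
  meta <- do.call(rbind, meta_list)
  rownames(covariates) <- rownames(counts) <- rownames(meta) <- NULL
  theta <- atan2(covariates$hand_vy, covariates$hand_vx)
  structure(
    list(covariates = covariates, counts = counts, bin_width = bin_width,
         trial_id = meta$trial_id, condition = meta$condition,
         theta = wrap_angle(theta), direction_bin = bin_directions(theta)),
    class = "binned_dataset")
}

#' @export
print.binned_dataset <- function(x, ...) {
  cat(sprintf("Binned dataset: %d bins x %d neurons, %.0f ms bins, %d trials, conditions: %s\n",
              nrow(x$counts), ncol(x$counts), 1000 * x$bin_width,
              length(unique(x$trial_id)),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Detect movement onset from handle acceleration
#'
#' Finds the first acceleration peak at or after `search_start`, then
#' sweeps backward in time until the acceleration drops below 10% of that
#' peak. The onset is the last sample whose acceleration is still at or
#' above the threshold (the first sub-threshold sample is excluded). The
#' rule is scale-free: rescaling the acceleration trace leaves the onset
#' unchanged. Onset is reported at sample resolution.
#'
#' @param accel Per-sample acceleration magnitudes.
#' @param t Per-sample times (s), same length.
#' @param search_start Time (s) from which to search for the peak: the bump
#'   time on passive trials, go-cue + 200 ms on active trials.
#' @param threshold_frac Fraction of the peak defining onset (default 0.1).
#' @return Onset time (s).
#' @export
detect_movement_onset <- function(accel, t, search_start,
                                  threshold_frac = 0.1) {
  stopifnot(length(accel) == length(t))
  from <- which(t >= search_start - 1e-9)
  if (!length(from)) stop_invalid("no samples at or after search_start")
  seg <- accel[from]
  if (max(seg) <= 0) stop_invalid("flat zero acceleration: no onset found")
  # first local maximum of the searched segment (global max of the rising
  # portion up to the first decrease would also do; use the first sample
  # that is >= both neighbours and at least 10%% of the segment max, falling
  # back to the global max)
  peak_rel <- which.max(seg)
  for (i in seq_along(seg)) {
    left_ok <- i == 1 || seg[i] >= seg[i - 1]
    right_ok <- i == length(seg) || seg[i] >= seg[i + 1]
    if (left_ok && right_ok && seg[i] >= threshold_frac * max(seg) &&
        (i == length(seg) || seg[i] > seg[i + 1] || seg[i] == max(seg))) {
      peak_rel <- i
      break
    }
  }
  peak_idx <- from[peak_rel]
  thr <- threshold_frac * accel[peak_idx]
  onset_idx <- peak_idx
  while (onset_idx > 1 && accel[onset_idx - 1] >= thr) {
    onset_idx <- onset_idx - 1
  }
  t[onset_idx]
}

#' Extract post-onset analysis windows
#'
#' One record per trial: covariates averaged and firing rates computed
#' (window spike count / window length, spikes/s) over
#' `[onset, onset + window)`. Trials whose window would run past the end of
#' the recorded samples are dropped with a warning.
#'
#' @param session A synthetic session.
#' @param onsets Data frame with `trial_id` and `onset` (s, trial clock).
#' @param window Window length (s), default 120 ms.
#' @return Object of class `trial_windows`: `covariates` (data frame of
#'   window-averaged signals), `rates` (trials x neurons, spikes/s),
#'   `counts` (raw window spike counts), `trial_id`, `condition`,
#'   `direction` (rad; target or bump direction), `window`.
#' @export
extract_windows <- function(session, onsets,
                            window = session$config$analysis_window) {
  stopifnot(inherits(session, "synthetic_session"))
  samp <- session$samples
  cov_cols <- setdiff(colnames(samp), c("trial_id", "t", "condition"))
  res_cov <- list(); res_cnt <- list(); res_meta <- list()
  dropped <- 0
  for (i in seq_len(nrow(onsets))) {
    tr <- onsets$trial_id[i]
    on <- onsets$onset[i]
    idx <- which(samp$trial_id == tr)
    win <- idx[samp$t[idx] >= on - 1e-9 & samp$t[idx] < on + window - 1e-9]
    expected <- as.integer(round(window / session$sim_dt))
    if (length(win) < expected) {
      dropped <- dropped + 1
      next
    }
    win <- win[seq_len(expected)]
    ev <- session$events[session$events$trial_id == tr, ]
    res_cov[[length(res_cov) + 1]] <- colMeans(as.matrix(samp[win, cov_cols]))
    res_cnt[[length(res_cnt) + 1]] <- colSums(session$counts[win, , drop = FALSE])
    res_meta[[length(res_meta) + 1]] <- data.frame(
      trial_id = tr, condition = samp$condition[win[1]],
      direction = ev$movement_dir[1], stringsAsFactors = FALSE)
  }
  if (dropped > 0) {
    warning(sprintf("%d trial(s) dropped: analysis window exceeded trial bounds",
                    dropped))
  }
  if (!length(res_cov)) stop_invalid("no trials with a complete analysis window")
  covariates <- as.data.frame(do.call(rbind, res_cov))
  counts <- do.call(rbind, res_cnt)
  meta <- do.call(rbind, res_meta)
  rownames(covariates) <- rownames(counts) <- rownames(meta) <- NULL
  structure(
    list(covariates = covariates, rates = counts / window, counts = counts,
         trial_id = meta$trial_id, condition = meta$condition,
         direction = wrap_angle(meta$direction), window = window),
    class = "trial_windows")
}

#' @export
print.trial_windows <- function(x, ...) {
  cat(sprintf("Trial windows: %d trials x %d neurons, %.0f ms window, conditions: %s\n",
              nrow(x$rates), ncol(x$rates), 1000 * x$window,
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Assign movement directions to circular bins
#'
#' Partitions the circle into `n_bins` equal half-open bins centered on
#' `k * (360 / n_bins)` degrees, k = 0 .. n_bins - 1. With the default 16
#' bins each bin is 22.5 degrees wide; bin k covers
#' `[k * 22.5 - 11.25, k * 22.5 + 11.25)` degrees, wrapped.
#'
#' @param theta Angles (rad), any finite values.
#' @param n_bins Number of bins (default 16).
#' @return Integer bin indices in 0 .. n_bins - 1.
#' @export
#' @examples
#' bin_directions(c(0, pi / 2, pi, -pi / 2))
bin_directions <- function(theta, n_bins = 16) {
  if (any(!is.finite(theta))) stop_invalid("directions must be finite")
  width <- 2 * pi / n_bins
  as.integer(floor((theta + width / 2) / width)) %% n_bins
}

#' Resample rows to a uniform direction distribution
#'
#' Draws, with replacement, an equal number of rows from every direction
#' bin, so the resampled direction histogram is exactly uniform. The
#' per-bin draw count is the median occupied-bin count. Used by the PD
#' bootstrap to remove direction-sampling bias.
#'
#' @param theta Row directions (rad).
#' @param n_bins Direction bins (16 for binned streams, 4 for the
#'   center-out windows).
#' @return Integer vector of resampled row indices (length
#'   `n_bins * per-bin count`).
#' @export
uniform_direction_resample <- function(theta, n_bins = 16) {
  bins <- bin_directions(theta, n_bins)
  tab <- tabulate(bins + 1L, nbins = n_bins)
  if (any(tab == 0)) {
    stop_invalid("direction bin %d is empty; cannot resample uniformly",
                 which(tab == 0)[1] - 1L)
  }
  n_draw <- as.integer(round(stats::median(tab)))
  idx_by_bin <- split(seq_along(theta), bins)
  resample_from_bins(idx_by_bin, n_draw)
}

# draw n_draw rows with replacement from every bin's index set
resample_from_bins <- function(idx_by_bin, n_draw) {
  unlist(lapply(idx_by_bin, function(ix) {
    ix[sample.int(length(ix), n_draw, replace = TRUE)]
  }), use.names = FALSE)
}
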