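#' Empirical direction tuning curve
#'
#' Mean firing rate and normal-approximation 95% confidence interval of the
#' mean in each of 16 direction bins, 22.5 degrees wide, centered on
#' k * 22.5 degrees.
#'
#' @param rates Firing rates (or counts) per observation.
#' @param directions Movement directions (rad).
#' @param n_bins Number of direction bins (default 16).
#' @return Object of class `tuning_curve`: data frame with `bin`, `center`
#'   (rad), `mean`, `ci_lo`, `ci_hi`, `n`. Empty bins are reported as `NA`
#'   with a warning.
#' @export
empirical_tuning_curve <- function(rates, directions, n_bins = 16) {
  stopifnot(length(rates) == length(directions))
  bins <- bin_directions(directions, n_bins)
  centers <- wrap_angle((0:(n_bins - 1)) * 2 * pi / n_bins)
  out <- data.frame(bin = 0:(n_bins - 1), center = centers,
                    mean = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    n = 0L)
  for (b in 0:(n_bins - 1)) {
    x <- rates[bins == b]
    out$n[b + 1] <- length(x)
    if (length(x) == 0) next
    m <- mean(x)
    se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    out$mean[b + 1] <- m
    out$ci_lo[b + 1] <- m - 1.96 * se
    out$ci_hi[b + 1] <- m + 1.96 * se
  }
  if (any(out$n == 0)) {
    warning(sprintf("%d empty direction bin(s) reported as NA",
                    sum(out$n == 0)))
  }
  structure(out, class = c("tuning_curve", "data.frame"))
}

#' Least-squares cosine tuning fit
#'
#' Fits `rate = b0 + b1 sin(theta) + b2 cos(theta)`, equivalently
#' `b0 + r cos(theta - PD)` with `PD = atan2(b1, b2)` and
#' `r = sqrt(b1^2 + b2^2)`.
#'
#' @param rates Firing rates (or counts; PD is scale-invariant).
#' @param directions Directions (rad); at least 3 distinct values.
#' @return Object of class `cosine_fit`: `b0`, `b1`, `b2`, `PD` (rad, in
#'   (-pi, pi]), `r` (modulation depth, >= 0).
#' @export
fit_cosine <- function(rates, directions) {
  stopifnot(length(rates) == length(directions))
  if (length(unique(round(wrap_angle(directions), 12))) < 3) {
    stop_invalid("need at least 3 distinct directions for a cosine fit")
  }
  X <- cbind(1, sin(directions), cos(directions))
  qrx <- qr(X)
  if (qrx$rank < 3) stop_invalid("rank-deficient cosine design")
  b <- qr.coef(qrx, rates)
  structure(list(b0 = b[1], b1 = b[2], b2 = b[3],
                 PD = wrap_angle(atan2(b[2], b[3])),
                 r = sqrt(b[2]^2 + b[3]^2)),
            class = "cosine_fit")
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("Cosine fit: b0 = %.3f, r = %.3f, PD = %.1f deg\n",
              x$b0, x$r, 180 / pi * x$PD))
  invisible(x)
}

#' Bootstrap preferred direction
#'
#' Each iteration resamples rows to a uniform direction distribution
#' ([uniform_direction_resample()]) and refits the cosine model; the
#' preferred direction is the circular mean of the bootstrap PDs and the
#' modulation depth the arithmetic mean of the bootstrap depths.
#'
#' @param rates,directions Paired observations.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param n_bins Direction bins for the uniform resampling.
#' @param seed Integer seed.
#' @return Object of class `pd_estimate`: `PD`, `depth`, `pd_samples`,
#'   `r_samples`.
#' @export
bootstrap_pd <- function(rates, directions, n_boot = 1000, n_bins = 16,
                         seed = 1L) {
  rates <- as.numeric(rates)  # force now: promises must not run seeded
  plan <- resample_plan(directions, n_bins)
  S <- sin(directions); C <- cos(directions)
  with_seed(seed, {
    pd <- numeric(n_boot)
    rr <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      idx <- resample_from_bins(plan$idx_by_bin, plan$n_draw)
      b <- cosine_coefs(rates[idx], S[idx], C[idx])
      pd[i] <- wrap_angle(atan2(b[2], b[3]))
      rr[i] <- sqrt(b[2]^2 + b[3]^2)
    }
    structure(list(PD = circ_mean(pd), depth = mean(rr), pd_samples = pd,
                   r_samples = rr, n_boot = n_boot),
              class = "pd_estimate")
  })
}

# uniform-resampling plan shared across bootstrap iterations
resample_plan <- function(directions, n_bins) {
  bins <- bin_directions(directions, n_bins)
  tab <- tabulate(bins + 1L, nbins = n_bins)
  if (any(tab == 0)) {
    stop_invalid("direction bin %d is empty; cannot resample uniformly",
                 which(tab == 0)[1] - 1L)
  }
  list(idx_by_bin = split(seq_along(directions), bins),
       n_draw = as.integer(round(stats::median(tab))))
}

# normal-equation solve of rate ~ 1 + sin + cos (tiny 3x3 system)
cosine_coefs <- function(y, s, c) {
  n <- length(y)
  A <- matrix(c(n, sum(s), sum(c),
                sum(s), sum(s^2), sum(s * c),
                sum(c), sum(s * c), sum(c^2)), 3, 3)
  solve(A, c(sum(y), sum(y * s), sum(y * c)))
}

#' @export
print.pd_estimate <- function(x, ...) {
  cat(sprintf("Bootstrap PD: %.1f deg, depth %.3f (%d iterations)\n",
              180 / pi * x$PD, x$depth, x$n_boot))
  invisible(x)
}

#' Shuffle-null test for directional tuning
#'
#' The observed modulation depth (mean bootstrap `r`) is compared with a
#' null distribution built by uniform-resampling directions and
#' independently permuting the firing rates on each iteration, destroying
#' any rate-direction association. A neuron is tuned when its observed
#' depth exceeds the 95th percentile of the null depths.
#'
#' @inheritParams bootstrap_pd
#' @param percentile Null percentile defining significance (default 0.95).
#' @return List: `tuned`, `depth` (observed mean r), `null_cut` (null
#'   percentile), `null_samples`.
#' @export
tuning_significance <- function(rates, directions, n_boot = 1000,
                                n_bins = 16, seed = 1L, percentile = 0.95) {
  rates <- as.numeric(rates)
  force(seed)
  obs <- bootstrap_pd(rates, directions, n_boot, n_bins,
                      seed = derive_seed(seed, "tuning_obs"))
  plan <- resample_plan(directions, n_bins)
  S <- sin(directions); C <- cos(directions)
  null_r <- with_seed(derive_seed(seed, "tuning_null"), {
    vapply(seq_len(n_boot), function(i) {
      idx <- resample_from_bins(plan$idx_by_bin, plan$n_draw)
      b <- cosine_coefs(rates[idx][sample.int(length(idx))], S[idx], C[idx])
      sqrt(b[2]^2 + b[3]^2)
    }, 0)
  })
  cut <- stats::quantile(null_r, percentile, names = FALSE)
  list(tuned = obs$depth > cut, depth = obs$depth, null_cut = cut,
       null_samples = null_r)
}

#' Wrapped preferred-direction shift
#'
#' `wrap(pd_b - pd_a)` on (-pi, pi]: the signed rotation from the first
#' condition's PD to the second's.
#'
#' @param pd_a,pd_b Angles (rad).
#' @return Shift in (-pi, pi].
#' @export
#' @examples
#' pd_shift(170 * pi / 180, -170 * pi / 180)  # +20 degrees through the cut
pd_shift <- function(pd_a, pd_b) {
  stopifnot(all(is.finite(pd_a)), all(is.finite(pd_b)))
  wrap_angle(pd_b - pd_a)
}

#' Circular VAF of predicted PD shifts
#'
#' `cVAF_i = cos(actual_i - predicted_i)`: the inner product of unit
#' vectors at the two shift angles, so 1 for perfect prediction, 0 at 90
#' degrees of error, -1 for antipodal error.
#'
#' @param actual_shifts,predicted_shifts Equal-length vectors (rad).
#' @return List: `per_neuron` (cVAF_i) and `mean`.
#' @export
cvaf <- function(actual_shifts, predicted_shifts) {
  if (length(actual_shifts) != length(predicted_shifts)) {
    stop_invalid("actual and predicted shift vectors differ in length")
  }
  ci <- cos(wrap_angle(actual_shifts - predicted_shifts))
  list(per_neuron = ci, mean = mean(ci))
}

#' Tuning curve and PD of model-predicted activity
#'
#' Pushes a fitted model's predicted rates through the same empirical
#' tuning curve and cosine machinery applied to observed rates.
#'
#' @param glm A [fit_poisson_glm()] object.
#' @param dataset Dataset with the model's covariates.
#' @param condition Optional condition label selecting rows.
#' @param n_bins Direction bins.
#' @return List: `curve` ([empirical_tuning_curve()]) and `fit`
#'   ([fit_cosine()]) of the predicted rates.
#' @export
model_predicted_tuning <- function(glm, dataset, condition = NULL,
                                   n_bins = 16) {
  des <- build_design(dataset, glm$model)
  pred <- predict_rates(glm, des)
  theta <- dataset$theta
  rows <- if (is.null(condition)) rep(TRUE, length(pred)) else
    dataset$condition == condition
  list(curve = empirical_tuning_curve(pred[rows], theta[rows], n_bins),
       fit = fit_cosine(pred[rows], theta[rows]))
}

#' Correlation between actual and model-predicted tuning curves
#'
#' Product-moment correlation between the concatenated per-bin means of
#' the two conditions (16 bins x 2 conditions = 32 points), location- and
#' scale-invariant as correlations are.
#'
#' @param actual,predicted Lists of two [empirical_tuning_curve()] objects
#'   (one per condition, same order).
#' @return Scalar correlation, or `NA` with a warning if either
#'   concatenated curve has zero variance.
#' @export
tuning_curve_correlation <- function(actual, predicted) {
  stopifnot(length(actual) == 2, length(predicted) == 2)
  a <- c(actual[[1]]$mean, actual[[2]]$mean)
  p <- c(predicted[[1]]$mean, predicted[[2]]$mean)
  ok <- is.finite(a) & is.finite(p)
  if (stats::sd(a[ok]) == 0 || stats::sd(p[ok]) == 0) {
    warning("zero variance in a tuning curve; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a[ok], p[ok])
}

#' Summarize per-fold PD shifts into a session-level cVAF
#'
#' Takes the per-(neuron, model, repeat, fold) actual and predicted shifts
#' recorded by the cross-validation engine, restricts to neurons tuned in
#' both conditions, and reports: per-neuron circular-mean shifts, the
#' per-fold mean cVAF across neurons, and each model's session cVAF with
#' its corrected-resampled 95% confidence interval over the
#' `K * R` folds.
#'
#' @param shifts Data frame from [run_two_workspace_experiment()]'s engine
#'   (columns neuron, model, rep, fold, actual_shift, predicted_shift).
#' @param tuned_neurons Neuron labels to retain.
#' @param K,R Cross-validation shape.
#' @return List: `per_neuron` (circular-mean actual/predicted shift and
#'   mean cVAF per neuron and model), `per_model` (session mean cVAF, CI).
#' @export
summarize_pd_shifts <- function(shifts, tuned_neurons, K, R) {
  s <- shifts[shifts$neuron %in% tuned_neurons, ]
  if (!nrow(s)) stop_invalid("no tuned neurons in shift records")
  s$cvaf <- cos(wrap_angle(s$actual_shift - s$predicted_shift))
  per_neuron <- do.call(rbind, lapply(
    split(s, list(s$neuron, s$model), drop = TRUE), function(g) {
      data.frame(neuron = g$neuron[1], model = g$model[1],
                 actual_shift = circ_mean(g$actual_shift),
                 predicted_shift = circ_mean(g$predicted_shift),
                 mean_cvaf = mean(g$cvaf), stringsAsFactors = FALSE)
    }))
  fold_means <- stats::aggregate(cvaf ~ model + rep + fold, data = s, FUN = mean)
  per_model <- do.call(rbind, lapply(split(fold_means, fold_means$model),
                                     function(g) {
    scores <- g$cvaf
    ci <- if (length(scores) == K * R) cv_confint(scores, K, R) else
      rep(NA_real_, 2)
    data.frame(model = g$model[1], mean_cvaf = mean(scores),
               ci_lo = ci[1], ci_hi = ci[2], n_folds = length(scores),
               stringsAsFactors = FALSE)
  }))
  rownames(per_neuron) <- rownames(per_model) <- NULL
  list(per_neuron = per_neuron, per_model = per_model)
}
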