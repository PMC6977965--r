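#' Poisson deviance pseudo-R-squared
#'
#' Likelihood-based goodness of fit for spike counts: one minus the ratio
#' of the model's Poisson deviance to the deviance of a null model that
#' predicts the (training-set) mean count in every bin,
#' \deqn{pR^2 = 1 - \frac{\sum_\tau f \log(f/\hat f) - (f - \hat f)}
#'                    {\sum_\tau f \log(f/\bar f) - (f - \bar f)},}
#' with the convention `0 * log(0/x) = 0`. Ranges over (-inf, 1]: 1 for a
#' saturated prediction, 0 for a model no better than the null mean,
#' negative for one that is worse. Values around 0.2 are typically
#' considered a good fit for cortical spike counts.
#'
#' @param observed Nonnegative integer counts.
#' @param predicted Positive predicted counts per bin, same length.
#' @param null_mean Scalar null prediction; by convention the mean count of
#'   the training set, so test-set scores are leakage-free.
#' @return Scalar pseudo-R-squared.
#' @export
#' @examples
#' pseudo_r2(c(2, 0, 1, 3), c(2, 0.5, 1, 3), 1.5)
pseudo_r2 <- function(observed, predicted, null_mean) {
  check_counts(observed)
  if (length(predicted) != length(observed)) {
    stop_invalid("observed and predicted lengths differ")
  }
  if (any(predicted < 0) || any(predicted == 0 & observed > 0) ||
      !is.finite(null_mean) || null_mean <= 0) {
    stop_invalid("predicted values and null_mean must be positive (a zero prediction is only admissible for a zero count)")
  }
  half_dev <- function(fhat) {
    term <- ifelse(observed > 0, observed * log(observed / fhat), 0)
    sum(term - (observed - fhat))
  }
  d_null <- half_dev(null_mean)
  if (d_null <= 1e-300) {
    stop_invalid("null deviance is zero (constant counts equal to null_mean); pseudo-R2 undefined")
  }
  1 - half_dev(predicted) / d_null
}

#' Corrected resampled t-test for repeated cross-validation scores
#'
#' Fold scores from repeated k-fold cross-validation are not independent
#' (training sets overlap), so the naive one-sample t-test is anti-
#' conservative. The corrected test inflates the squared standard error
#' from `sigma^2 / (K R)` to `(1/(K R) + (1/K) / (1 - 1/K)) * sigma^2`
#' and refers the statistic to a t distribution with `K R - 1` degrees of
#' freedom. At K = 5, R = 20 the variance multiplier is
#' 1/100 + (1/5)/(4/5) = 0.26.
#'
#' @param d Vector of exactly `K * R` paired fold differences.
#' @param K Folds per repeat.
#' @param R Repeats.
#' @return Object of class `corrected_ttest`: `mean`, `var`, `t_stat`,
#'   `df = K * R - 1`, `p_value` (two-sided), `degenerate` (TRUE when the
#'   fold variance is exactly zero).
#' @export
corrected_resampled_ttest <- function(d, K, R) {
  if (length(d) != K * R || any(!is.finite(d))) {
    stop_invalid("d must contain exactly K * R finite values")
  }
  n <- K * R
  mu <- mean(d)
  v <- stats::var(d)
  mult <- 1 / n + (1 / K) / (1 - 1 / K)
  degenerate <- v == 0
  if (degenerate) {
    t_stat <- if (mu == 0) 0 else sign(mu) * Inf
    p <- if (mu == 0) 1 else 0
  } else {
    t_stat <- mu / sqrt(mult * v)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(
    list(mean = mu, var = v, t_stat = t_stat, df = n - 1, p_value = p,
         multiplier = mult, K = K, R = R, degenerate = degenerate),
    class = "corrected_ttest")
}

#' @export
print.corrected_ttest <- function(x, ...) {
  cat(sprintf("Corrected resampled t-test: mean %.4g, t = %.3f (df %d), p = %.3g\n",
              x$mean, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Confidence interval from repeated-CV fold scores
#'
#' 95% interval around the mean fold score using the corrected resampled
#' standard error (same correction as [corrected_resampled_ttest()]).
#'
#' @param scores `K * R` fold scores.
#' @param K,R Cross-validation shape.
#' @param level Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
cv_confint <- function(scores, K, R, level = 0.95) {
  stopifnot(length(scores) == K * R)
  mult <- 1 / (K * R) + (1 / K) / (1 - 1 / K)
  half <- stats::qt(1 - (1 - level) / 2, df = K * R - 1) *
    sqrt(mult * stats::var(scores))
  mean(scores) + c(-1, 1) * half
}

# ---- repeated k-fold engine ------------------------------------------------

# trial-level fold assignment: trials randomly split into K groups
assign_folds <- function(trials, K) {
  stats::setNames(sample(rep_len(seq_len(K), length(trials))), trials)
}

glm_counts <- function(dataset) {
  if (inherits(dataset, "trial_windows")) dataset$counts else dataset$counts
}

#' Repeated k-fold cross-validation of encoding models
#'
#' Splits trials (never individual bins) into K folds, R times; on every
#' repeat-fold, each requested model is fit to the training bins of every
#' neuron and scored by test-set [pseudo_r2()] with the training-mean null.
#' All models see identical folds (paired design), enabling the corrected
#' resampled t-test on per-fold score differences. The muscle model's PCA
#' bases are fit on the training fold only.
#'
#' @param dataset A `binned_dataset` or `trial_windows` object.
#' @param models Character vector of [encoding_model_names()].
#' @param K Folds (default 5).
#' @param R Repeats (default 20).
#' @param seed Integer seed controlling fold assignment.
#' @param neurons Columns of the count matrix to analyze (default all).
#' @return Object of class `cv_result`: `scores` (data frame with neuron,
#'   model, rep, fold, pr2, converged), `folds` (per-repeat trial-to-fold
#'   maps), `K`, `R`, `seed`.
#' @export
repeated_kfold <- function(dataset, models, K = 5, R = 20, seed = 1L,
                           neurons = NULL) {
  repeated_cv_analysis(dataset, models, K = K, R = R, seed = seed,
                       neurons = neurons, pd_shift = FALSE)$cv
}

#' Repeated-CV model evaluation with PD-shift and tuning-curve records
#'
#' The engine behind [repeated_kfold()] and the two-workspace pipeline:
#' identical fits, but with `pd_shift = TRUE` it additionally records, for
#' every neuron, model and fold, the actual and model-predicted
#' preferred-direction shift between the two conditions (cosine fits on
#' the fold's test rows) and the correlation between actual and predicted
#' 16-bin tuning curves across both conditions.
#'
#' @inheritParams repeated_kfold
#' @param pd_shift Record PD shifts and tuning-curve correlations
#'   (requires exactly two conditions).
#' @param n_dir_bins Direction bins for the tuning curves.
#' @return List: `cv` (a `cv_result`), `shifts` (data frame of per-fold
#'   actual/predicted shifts) and `curves` (per-fold tuning-curve
#'   correlations), the latter two `NULL` unless `pd_shift`.
#' @export
repeated_cv_analysis <- function(dataset, models, K = 5, R = 20, seed = 1L,
                                 neurons = NULL, pd_shift = FALSE,
                                 n_dir_bins = 16) {
  counts <- glm_counts(dataset)
  if (is.null(neurons)) neurons <- colnames(counts) %||% seq_len(ncol(counts))
  trials <- unique(dataset$trial_id)
  if (length(trials) < K) stop_invalid("fewer trials (%d) than folds (%d)",
                                       length(trials), K)
  dt <- dataset_dt(dataset)
  conditions <- if (pd_shift) sort(unique(dataset$condition)) else NULL
  if (pd_shift) {
    stopifnot(length(conditions) == 2)
    theta <- dataset$theta
  }
  # designs are fold-independent except for muscle_pca
  static_design <- list()
  for (m in setdiff(models, "muscle_pca")) {
    static_design[[m]] <- build_design(dataset, m)
  }
  data_df <- dataset_covariates(dataset)

  scores <- vector("list", R * K * length(models))
  shift_rec <- list()
  curve_rec <- list()
  folds <- vector("list", R)
  si <- 0
  with_seed(seed, {
    for (r in seq_len(R)) {
      fold_of <- assign_folds(trials, K)
      folds[[r]] <- fold_of
      for (k in seq_len(K)) {
        test_trials <- trials[fold_of == k]
        te <- dataset$trial_id %in% test_trials
        tr <- !te
        for (m in models) {
          if (m == "muscle_pca") {
            lcols <- grep("^len_", colnames(data_df), value = TRUE)
            dcols <- grep("^dlen_", colnames(data_df), value = TRUE)
            basis <- list(
              lengths = fit_pca_basis(as.matrix(data_df[tr, lcols]), 5),
              dlengths = fit_pca_basis(as.matrix(data_df[tr, dcols]), 5))
            des <- build_design(dataset, m, pca_basis = basis)
          } else {
            des <- static_design[[m]]
          }
          X_tr <- des$X[tr, , drop = FALSE]
          X_te <- des$X[te, , drop = FALSE]
          for (nn in neurons) {
            y_tr <- counts[tr, nn]
            y_te <- counts[te, nn]
            fit <- fit_poisson_glm(X_tr, y_tr, neuron_id = nn)
            pred <- exp(pmin(drop(X_te %*% fit$coefficients), count_cap(dt)))
            null_mean <- max(mean(y_tr), 1e-8)
            pr2 <- tryCatch(pseudo_r2(y_te, pred, null_mean),
                            error = function(e) NA_real_)
            si <- si + 1
            scores[[si]] <- data.frame(
              neuron = nn, model = m, rep = r, fold = k, pr2 = pr2,
              converged = fit$converged, stringsAsFactors = FALSE)
            if (pd_shift) {
              rec <- fold_pd_record(y_te, pred, theta[te],
                                    dataset$condition[te], conditions,
                                    n_dir_bins)
              if (!is.null(rec)) {
                shift_rec[[length(shift_rec) + 1]] <- cbind(
                  data.frame(neuron = nn, model = m, rep = r, fold = k,
                             stringsAsFactors = FALSE), rec$shift)
                curve_rec[[length(curve_rec) + 1]] <- data.frame(
                  neuron = nn, model = m, rep = r, fold = k,
                  curve_cor = rec$curve_cor, stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
    }
  })
  cv <- structure(
    list(scores = do.call(rbind, scores), folds = folds, K = K, R = R,
         seed = seed),
    class = "cv_result")
  list(cv = cv,
       shifts = if (length(shift_rec)) do.call(rbind, shift_rec) else NULL,
       curves = if (length(curve_rec)) do.call(rbind, curve_rec) else NULL)
}

# actual vs model-predicted PD shift and tuning-curve correlation for one
# neuron-model-fold; cosine fits on the fold's test rows per condition
fold_pd_record <- function(y_te, pred, theta, condition, conditions,
                           n_dir_bins) {
  pd_a <- numeric(2); pd_p <- numeric(2)
  means_a <- NULL; means_p <- NULL
  for (ci in 1:2) {
    rows <- condition == conditions[ci]
    if (sum(rows) < 8) return(NULL)
    fa <- tryCatch(fit_cosine(y_te[rows], theta[rows]),
                   error = function(e) NULL)
    fp <- tryCatch(fit_cosine(pred[rows], theta[rows]),
                   error = function(e) NULL)
    if (is.null(fa) || is.null(fp)) return(NULL)
    pd_a[ci] <- fa$PD
    pd_p[ci] <- fp$PD
    bins <- bin_directions(theta[rows], n_dir_bins)
    ma <- tapply(y_te[rows], factor(bins, levels = 0:(n_dir_bins - 1)), mean)
    mp <- tapply(pred[rows], factor(bins, levels = 0:(n_dir_bins - 1)), mean)
    means_a <- c(means_a, ma)
    means_p <- c(means_p, mp)
  }
  ok <- is.finite(means_a) & is.finite(means_p)
  cc <- if (sum(ok) > 3 && stats::sd(means_a[ok]) > 0 &&
            stats::sd(means_p[ok]) > 0) {
    stats::cor(means_a[ok], means_p[ok])
  } else {
    NA_real_
  }
  list(shift = data.frame(actual_shift = pd_shift(pd_a[1], pd_a[2]),
                          predicted_shift = pd_shift(pd_p[1], pd_p[2])),
       curve_cor = cc)
}

#' Pairwise model comparison with the corrected resampled t-test
#'
#' Per neuron, the paired per-fold pseudo-R2 differences between two
#' models are fed to [corrected_resampled_ttest()]; the winner is the
#' model with the higher mean when the corrected p-value clears the
#' Bonferroni-adjusted alpha, otherwise a tie. Neurons with any
#' non-converged fold fit are flagged and excluded.
#'
#' @param cv A [repeated_kfold()] result containing both models.
#' @param pair Character 2-vector: models A and B.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Correction factor (default 6, for the six candidate
#'   encoding models historically compared).
#' @return Object of class `model_comparison`: per-neuron data frame with
#'   mean pR2 of each model, t, p, winner; plus `alpha`, `bonferroni`.
#' @export
compare_models <- function(cv, pair, alpha = 0.05, bonferroni = 6) {
  stopifnot(inherits(cv, "cv_result"), length(pair) == 2)
  s <- cv$scores
  if (!all(pair %in% s$model)) stop_invalid("both models must be present in cv")
  thresh <- alpha / bonferroni
  out <- lapply(unique(s$neuron), function(nn) {
    a <- s[s$neuron == nn & s$model == pair[1], ]
    b <- s[s$neuron == nn & s$model == pair[2], ]
    a <- a[order(a$rep, a$fold), ]
    b <- b[order(b$rep, b$fold), ]
    if (!identical(a$rep, b$rep) || !identical(a$fold, b$fold)) {
      stop_invalid("fold mismatch between models for neuron %s", nn)
    }
    excluded <- any(!a$converged) || any(!b$converged) ||
      any(!is.finite(a$pr2)) || any(!is.finite(b$pr2))
    if (excluded) {
      return(data.frame(neuron = nn, mean_a = NA_real_, mean_b = NA_real_,
                        t_stat = NA_real_, p_value = NA_real_,
                        winner = "excluded", excluded = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- corrected_resampled_ttest(a$pr2 - b$pr2, cv$K, cv$R)
    winner <- if (tt$p_value < thresh) {
      if (tt$mean > 0) pair[1] else pair[2]
    } else {
      "tie"
    }
    data.frame(neuron = nn, mean_a = mean(a$pr2), mean_b = mean(b$pr2),
               t_stat = tt$t_stat, p_value = tt$p_value, winner = winner,
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  structure(
    list(table = do.call(rbind, out), pair = pair, alpha = alpha,
         bonferroni = bonferroni, K = cv$K, R = cv$R),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- table(factor(x$table$winner,
                      levels = c(x$pair, "tie", "excluded")))
  cat(sprintf("Model comparison %s vs %s (alpha %.3g / %d):\n",
              x$pair[1], x$pair[2], x$alpha, x$bonferroni))
  print(tab)
  invisible(x)
}

#' Within- vs across-condition model consistency
#'
#' For each condition, test folds are drawn among that condition's trials;
#' a "within" model is trained on the condition's own training trials and
#' a "both" model on those plus every trial of the other condition. Both
#' are scored by test [pseudo_r2()] on identical test rows. The
#' both-trained score is the neuron's consistency: it stays close to the
#' within score only when one model explains the neuron in both
#' conditions.
#'
#' @param dataset A `binned_dataset` or `trial_windows` with exactly two
#'   condition labels.
#' @param model One encoding model name.
#' @param K,R Cross-validation shape.
#' @param seed Integer seed.
#' @return Object of class `consistency_result`: `scores` (neuron,
#'   condition, rep, fold, within, both) and `summary` (per neuron and
#'   condition mean within/both pR2 and the corrected paired test of
#'   within - both).
#' @export
model_consistency <- function(dataset, model, K = 5, R = 20, seed = 1L) {
  counts <- glm_counts(dataset)
  neurons <- colnames(counts) %||% seq_len(ncol(counts))
  conditions <- sort(unique(dataset$condition))
  if (length(conditions) != 2) stop_invalid("dataset must have exactly 2 conditions")
  des <- build_design(dataset, model)
  cap <- count_cap(dataset_dt(dataset))
  recs <- list()
  with_seed(seed, {
    for (cond in conditions) {
      cond_trials <- unique(dataset$trial_id[dataset$condition == cond])
      other_rows <- dataset$condition != cond
      if (length(cond_trials) < K) {
        stop_invalid("condition '%s' has fewer trials than folds", cond)
      }
      for (r in seq_len(R)) {
        fold_of <- assign_folds(cond_trials, K)
        for (k in seq_len(K)) {
          test_trials <- cond_trials[fold_of == k]
          te <- dataset$trial_id %in% test_trials
          tr_within <- !te & !other_rows
          tr_both <- !te
          X_w <- des$X[tr_within, , drop = FALSE]
          X_b <- des$X[tr_both, , drop = FALSE]
          X_te <- des$X[te, , drop = FALSE]
          for (nn in neurons) {
            fw <- fit_poisson_glm(X_w, counts[tr_within, nn], neuron_id = nn)
            fb <- fit_poisson_glm(X_b, counts[tr_both, nn], neuron_id = nn)
            y_te <- counts[te, nn]
            pw <- exp(pmin(drop(X_te %*% fw$coefficients), cap))
            pb <- exp(pmin(drop(X_te %*% fb$coefficients), cap))
            # both scores share the within-condition training-mean null so
            # they are directly comparable on the same test rows
            null_mean <- max(mean(counts[tr_within, nn]), 1e-8)
            within <- tryCatch(pseudo_r2(y_te, pw, null_mean),
                               error = function(e) NA_real_)
            both <- tryCatch(pseudo_r2(y_te, pb, null_mean),
                             error = function(e) NA_real_)
            recs[[length(recs) + 1]] <- data.frame(
              neuron = nn, condition = cond, rep = r, fold = k,
              within = within, both = both,
              converged = fw$converged && fb$converged,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  scores <- do.call(rbind, recs)
  summ <- do.call(rbind, lapply(split(scores,
                                      list(scores$neuron, scores$condition),
                                      drop = TRUE), function(g) {
    ok <- is.finite(g$within) & is.finite(g$both)
    if (all(ok) && all(g$converged)) {
      tt <- corrected_resampled_ttest(g$within - g$both, K, R)
      data.frame(neuron = g$neuron[1], condition = g$condition[1],
                 within = mean(g$within), both = mean(g$both),
                 t_stat = tt$t_stat, p_value = tt$p_value, excluded = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(neuron = g$neuron[1], condition = g$condition[1],
                 within = mean(g$within[ok]), both = mean(g$both[ok]),
                 t_stat = NA_real_, p_value = NA_real_, excluded = TRUE,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(summ) <- NULL
  structure(list(scores = scores, summary = summ, model = model, K = K,
                 R = R, conditions = conditions),
            class = "consistency_result")
}
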