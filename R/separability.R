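#' Two-class linear discriminant analysis
#'
#' Pooled-within-class-covariance LDA with equal priors (the tasks are
#' 50/50 by design): discriminant weights `w = S^-1 (m1 - m0)` and
#' threshold at the midpoint projection `w . (m0 + m1) / 2`. A singular
#' pooled covariance is regularized by a ridge of `1e-8 * trace / d` on
#' the diagonal, flagged in the result.
#'
#' @param features n x d matrix (or vector for d = 1).
#' @param labels Binary labels (factor, character or numeric; both classes
#'   must be present).
#' @return Object of class `lda_model`: `classes`, `means` (2 x d),
#'   `cov` (pooled), `w`, `threshold`, `priors`, `jittered`.
#' @export
fit_lda <- function(features, labels) {
  X <- as.matrix(features)
  cls <- sort(unique(as.character(labels)))
  if (length(cls) != 2) stop_invalid("need exactly 2 classes, got %d", length(cls))
  y <- as.character(labels)
  X0 <- X[y == cls[1], , drop = FALSE]
  X1 <- X[y == cls[2], , drop = FALSE]
  m0 <- colMeans(X0)
  m1 <- colMeans(X1)
  d <- ncol(X)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S <- matrix(0, d, d)
  if (n0 > 1) S <- S + (n0 - 1) * stats::cov(X0)
  if (n1 > 1) S <- S + (n1 - 1) * stats::cov(X1)
  S <- S / max(n0 + n1 - 2, 1)
  jittered <- FALSE
  w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    jittered <- TRUE
    ridge <- max(1e-8 * sum(diag(S)) / d, 1e-12)
    w <- solve(S + diag(ridge, d), m1 - m0)
  }
  structure(
    list(classes = cls, means = rbind(m0, m1), cov = S, w = as.numeric(w),
         threshold = sum(w * (m0 + m1) / 2), priors = c(0.5, 0.5),
         jittered = jittered),
    class = "lda_model")
}

#' Predict classes from a fitted LDA model
#'
#' @param object An [fit_lda()] model.
#' @param newdata n x d matrix (or vector for d = 1).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  score <- drop(X %*% object$w)
  ifelse(score > object$threshold, object$classes[2], object$classes[1])
}

# stratified trial-level fold assignment: folds balanced within each class
stratified_folds <- function(labels, K) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < K) {
      stop_invalid("class '%s' has fewer trials (%d) than folds (%d)",
                   cl, length(idx), K)
    }
    fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  fold
}

#' Cross-validated LDA separability index
#'
#' Repeated stratified 5-fold cross-validation of a two-class LDA; the
#' separability index is the mean test-set classification accuracy over
#' the `K * R` fold evaluations, with a 95% confidence interval from the
#' corrected resampled variance. Chance is 0.5 for the balanced two-class
#' design.
#'
#' @param features Per-trial features: n x d matrix or length-n vector
#'   (a single neuron's window-averaged firing rate has d = 1).
#' @param labels Per-trial binary labels (e.g. active/passive).
#' @param K,R Cross-validation shape (defaults 5, 20).
#' @param seed Integer seed.
#' @return Object of class `separability_result`: `index`, `ci`
#'   (corrected 95% CI, clamped to [0, 1]), `chance = 0.5`, `accuracy`
#'   (per-fold), `K`, `R`.
#' @export
separability_index <- function(features, labels, K = 5, R = 20, seed = 1L) {
  X <- as.matrix(features)
  y <- as.character(labels)
  stopifnot(nrow(X) == length(y))
  force(K); force(R)
  acc <- numeric(0)
  with_seed(seed, {
    for (r in seq_len(R)) {
      fold <- stratified_folds(y, K)
      for (k in seq_len(K)) {
        te <- fold == k
        model <- fit_lda(X[!te, , drop = FALSE], y[!te])
        pred <- predict(model, X[te, , drop = FALSE])
        acc <- c(acc, mean(pred == y[te]))
      }
    }
  })
  ci <- cv_confint(acc, K, R)
  structure(
    list(index = mean(acc), ci = pmin(pmax(ci, 0), 1), chance = 0.5,
         accuracy = acc, K = K, R = R),
    class = "separability_result")
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("Separability index: %.3f (95%% CI %.3f-%.3f; chance %.2f)\n",
              x$index, x$ci[1], x$ci[2], x$chance))
  invisible(x)
}

#' Separability of the whole-arm kinematics
#'
#' [separability_index()] applied to the 12-dimensional window-averaged
#' whole-arm kinematic vector (hand and elbow position and velocity),
#' classifying movement type (active vs passive).
#'
#' @param windows A [extract_windows()] `trial_windows` object.
#' @param K,R,seed As in [separability_index()].
#' @return A `separability_result`.
#' @export
kinematic_separability <- function(windows, K = 5, R = 20, seed = 1L) {
  stopifnot(inherits(windows, "trial_windows"))
  cols <- c(kinematic_cols$hand, kinematic_cols$hand_v,
            kinematic_cols$elbow, kinematic_cols$elbow_v)
  require_cols(windows$covariates, cols)
  separability_index(as.matrix(windows$covariates[, cols]),
                     windows$condition, K = K, R = R, seed = seed)
}

#' Correlation between model consistency and separability
#'
#' Product-moment correlation across neurons between the both-conditions-
#' trained pseudo-R2 (consistency) and the separability index, with a
#' percentile bootstrap confidence interval over neurons. A negative
#' correlation says that the neurons distinguishing active from passive
#' movements are the ones a single kinematic model cannot explain across
#' conditions.
#'
#' @param consistency Per-neuron both-trained pR2.
#' @param separability Per-neuron separability indices (paired).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List: `correlation`, `ci`, `n`, `n_boot`.
#' @export
consistency_vs_separability <- function(consistency, separability,
                                        n_boot = 10000, level = 0.95,
                                        seed = 1L) {
  consistency <- as.numeric(consistency)
  separability <- as.numeric(separability)
  ok <- is.finite(consistency) & is.finite(separability)
  x <- consistency[ok]; y <- separability[ok]
  n <- length(x)
  if (n < 5) stop_invalid("need at least 5 paired neurons, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(correlation = NA_real_, ci = c(NA_real_, NA_real_), n = n,
                n_boot = n_boot))
  }
  rho <- stats::cor(x, y)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
      else stats::cor(x[idx], y[idx])
    }, 0)
  })
  ci <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(correlation = rho, ci = ci, n = n, n_boot = n_boot)
}
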