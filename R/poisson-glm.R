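#' Fit a Poisson GLM by maximum likelihood
#'
#' Iteratively reweighted least squares for the log-link Poisson model
#' `counts ~ Poisson(exp(X beta))`, the canonical spike-count encoding
#' model. No regularization is applied; fits that fail to converge within
#' `max_iter` iterations (e.g. under quasi-separation) are returned with
#' `converged = FALSE` rather than raising, so cross-validation loops can
#' flag and exclude them. Collinear (aliased) design columns are detected
#' once by a pivoted QR decomposition and carried with coefficient zero.
#'
#' Convergence is declared when the relative change in log-likelihood falls
#' below `tol` (default 1e-8); at convergence the score equations
#' `t(X) %*% (counts - exp(X beta))` hold to high accuracy.
#'
#' @param design A [build_design()] object, or a plain numeric matrix whose
#'   first column is the intercept.
#' @param counts Nonnegative integer response vector (length `nrow(X)`).
#' @param neuron_id Optional label carried into the result.
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @return Object of class `fitted_glm`: named `coefficients`, `model`,
#'   `neuron_id`, `converged`, `iterations`, `loglik` (up to the factorial
#'   constant), `aliased` (names of dropped columns).
#' @export
fit_poisson_glm <- function(design, counts, neuron_id = NA_character_,
                            max_iter = 100, tol = 1e-8) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  model <- if (inherits(design, "design_matrix")) design$model else NA_character_
  check_counts(counts)
  if (length(counts) != nrow(X)) {
    stop_invalid("counts length (%d) does not match design rows (%d)",
                 length(counts), nrow(X))
  }
  if (nrow(X) <= ncol(X)) stop_invalid("need more observations than parameters")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  qrx <- qr(X)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  Xk <- X[, keep, drop = FALSE]

  beta <- numeric(ncol(Xk))
  beta[which(keep == 1)] <- log(mean(counts) + 1e-8)
  eta_cap <- 30  # numerical overflow guard during iteration only
  loglik <- function(eta) sum(counts * eta - exp(pmin(eta, eta_cap)))
  eta <- drop(Xk %*% beta)
  ll_old <- loglik(eta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- exp(pmin(eta, eta_cap))
    w <- pmax(mu, 1e-10)
    z <- eta + (counts - mu) / w
    XtW <- t(Xk * w)
    fit <- tryCatch(solve(XtW %*% Xk, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) {
      A <- XtW %*% Xk
      fit <- solve(A + diag(1e-10 * sum(diag(A)) / ncol(A), ncol(A)),
                   XtW %*% z)
    }
    beta_new <- drop(fit)
    eta_new <- drop(Xk %*% beta_new)
    ll_new <- loglik(eta_new)
    # step-halving keeps IRLS stable when the quadratic step overshoots
    step <- 1
    while (is.na(ll_new) || ll_new < ll_old - 1e-12) {
      step <- step / 2
      if (step < 1e-4) break
      beta_new <- beta + step * (drop(fit) - beta)
      eta_new <- drop(Xk %*% beta_new)
      ll_new <- loglik(eta_new)
    }
    beta <- beta_new
    eta <- eta_new
    if (is.finite(ll_new) && abs(ll_new - ll_old) <=
        tol * (abs(ll_old) + 0.1)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  coefficients <- stats::setNames(numeric(ncol(X)), colnames(X))
  coefficients[keep] <- beta
  structure(
    list(coefficients = coefficients, model = model, neuron_id = neuron_id,
         converged = converged, iterations = iter, loglik = ll_old,
         aliased = aliased),
    class = "fitted_glm")
}

#' @export
print.fitted_glm <- function(x, ...) {
  cat(sprintf("Poisson GLM (%s%s): %d coefficients, %s in %d iterations\n",
              ifelse(is.na(x$model), "custom", x$model),
              ifelse(is.na(x$neuron_id), "", paste0(", neuron ", x$neuron_id)),
              length(x$coefficients),
              ifelse(x$converged, "converged", "NOT converged"),
              x$iterations))
  invisible(x)
}

#' Predict expected spike counts from a fitted GLM
#'
#' `exp(X beta_hat)`, with the linear predictor clipped at `log(50)` counts
#' per bin before exponentiation — the same cap the ground-truth generator
#' applies, protecting against absurd rates under extreme test-fold
#' covariates. Predictions are strictly positive.
#'
#' @param glm A [fit_poisson_glm()] object.
#' @param design A [build_design()] object (same model) or plain matrix.
#' @param dt Duration represented by one row (s); the default 50 ms bin
#'   makes the cap exactly 50 counts per bin. Longer rows (e.g. 120 ms
#'   windows) scale the cap to the same 1000 spikes/s ceiling.
#' @return Vector of predicted counts per bin.
#' @export
predict_rates <- function(glm, design, dt = 0.05) {
  stopifnot(inherits(glm, "fitted_glm"))
  X <- if (inherits(design, "design_matrix")) {
    if (!is.na(glm$model) && design$model != glm$model) {
      stop_invalid("design built for model '%s' but GLM fitted as '%s'",
                   design$model, glm$model)
    }
    design$X
  } else {
    as.matrix(design)
  }
  if (ncol(X) != length(glm$coefficients)) {
    stop_invalid("design has %d columns but GLM has %d coefficients",
                 ncol(X), length(glm$coefficients))
  }
  exp(pmin(drop(X %*% glm$coefficients), count_cap(dt)))
}

# log of the maximum expected count per row: 50 counts per 50 ms bin,
# i.e. a 1000 spikes/s ceiling, rescaled to the row duration
count_cap <- function(dt) log(50 * dt / 0.05)
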