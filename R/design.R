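#' Encoding-model covariate sets
#'
#' The six covariate sets compared by the pipeline, with their design-matrix
#' dimensionality P (including the intercept column):
#'
#' * `hand_only`: 3-D hand position and velocity, shoulder origin (P = 7)
#' * `whole_arm`: hand plus elbow position and velocity (P = 13)
#' * `hand_force`: hand kinematics plus the 6 handle force/torque channels
#'   (P = 13)
#' * `egocentric`: hand position in spherical coordinates (azimuth, polar
#'   angle, radius) about the shoulder, and their time derivatives (P = 7)
#' * `joint`: joint angles and angular velocities (P = 2 x n_joints + 1;
#'   the planar arm has 2 joints, so P = 5)
#' * `muscle_pca`: 5-component PCA projections of surrogate muscle lengths
#'   and of their derivatives (P = 11)
#'
#' `untuned` (intercept-only ground-truth neurons) is additionally accepted
#' by the generator.
#'
#' @return Character vector of model names.
#' @export
encoding_model_names <- function() {
  c("hand_only", "whole_arm", "hand_force", "egocentric", "joint",
    "muscle_pca")
}

kinematic_cols <- list(
  hand = c("hand_x", "hand_y", "hand_z"),
  hand_v = c("hand_vx", "hand_vy", "hand_vz"),
  elbow = c("elbow_x", "elbow_y", "elbow_z"),
  elbow_v = c("elbow_vx", "elbow_vy", "elbow_vz"),
  force = c("fx", "fy", "fz", "tx", "ty", "tz"),
  joint = c("q1", "q2"),
  joint_v = c("dq1", "dq2")
)

require_cols <- function(data, cols) {
  missing <- setdiff(cols, colnames(data))
  if (length(missing)) {
    stop_invalid("missing covariate column(s): %s",
                 paste(missing, collapse = ", "))
  }
}

# remove 2*pi jumps so finite differences of an angle track are smooth
unwrap_angle <- function(theta) {
  if (length(theta) < 2) return(theta)
  theta[1] + c(0, cumsum(wrap_angle(diff(theta))))
}

# per-trial central differences (trials are independent time series)
diff_by_trial <- function(x, dt, trial_id) {
  x <- as.matrix(x)
  out <- x * NA_real_
  for (tr in unique(trial_id)) {
    idx <- which(trial_id == tr)
    out[idx, ] <- central_diff(x[idx, , drop = FALSE], dt)
  }
  out
}

# spherical hand coordinates about the shoulder (assumed at the origin of
# the stored coordinates) and their per-trial finite-difference derivatives
egocentric_covariates <- function(data, dt, trial_id) {
  require_cols(data, c(kinematic_cols$hand))
  x <- data$hand_x; y <- data$hand_y; z <- data$hand_z
  rho <- sqrt(x^2 + y^2 + z^2)
  az <- atan2(y, x)
  pol <- acos(pmin(pmax(ifelse(rho > 0, z / rho, 0), -1), 1))
  daz <- rep(NA_real_, length(az))
  for (tr in unique(trial_id)) {
    idx <- which(trial_id == tr)
    daz[idx] <- central_diff(unwrap_angle(az[idx]), dt)
  }
  cbind(ego_az = az, ego_pol = pol, ego_rho = rho,
        ego_daz = daz,
        ego_dpol = diff_by_trial(pol, dt, trial_id)[, 1],
        ego_drho = diff_by_trial(rho, dt, trial_id)[, 1])
}

# non-intercept covariate matrix for one model on a standard covariate table
covariate_matrix <- function(data, model, dt, trial_id = data$trial_id,
                             pca_basis = NULL) {
  ck <- kinematic_cols
  switch(model,
    untuned = matrix(0, nrow(data), 0),
    hand_only = {
      require_cols(data, c(ck$hand, ck$hand_v))
      as.matrix(data[, c(ck$hand, ck$hand_v)])
    },
    whole_arm = {
      require_cols(data, c(ck$hand, ck$hand_v, ck$elbow, ck$elbow_v))
      as.matrix(data[, c(ck$hand, ck$hand_v, ck$elbow, ck$elbow_v)])
    },
    hand_force = {
      require_cols(data, c(ck$hand, ck$hand_v, ck$force))
      as.matrix(data[, c(ck$hand, ck$hand_v, ck$force)])
    },
    egocentric = egocentric_covariates(data, dt, trial_id),
    joint = {
      require_cols(data, c(ck$joint, ck$joint_v))
      as.matrix(data[, c(ck$joint, ck$joint_v)])
    },
    muscle_pca = {
      lcols <- grep("^len_", colnames(data), value = TRUE)
      dcols <- grep("^dlen_", colnames(data), value = TRUE)
      if (length(lcols) < 5 || length(dcols) < 5) {
        stop_invalid("missing covariate column(s): muscle length signals (len_*/dlen_*)")
      }
      if (is.null(pca_basis)) {
        pca_basis <- list(
          lengths = fit_pca_basis(as.matrix(data[, lcols]), 5),
          dlengths = fit_pca_basis(as.matrix(data[, dcols]), 5))
      }
      pl <- project_pca(pca_basis$lengths, as.matrix(data[, lcols]))
      pd <- project_pca(pca_basis$dlengths, as.matrix(data[, dcols]))
      colnames(pl) <- paste0("len_", colnames(pl))
      colnames(pd) <- paste0("dlen_", colnames(pd))
      cbind(pl, pd)
    },
    stop_invalid("unknown encoding model '%s'", model)
  )
}

#' Build the design matrix for an encoding model
#'
#' Prepends the intercept column to the model's covariate block (column
#' order as documented in [encoding_model_names()]). For `muscle_pca`, the
#' PCA bases are fit on the dataset itself unless `pca_basis` is supplied;
#' the cross-validation engine always supplies bases fit on the training
#' fold only, so no test data leaks into the projection.
#'
#' @param dataset A [bin_signals()] dataset, a window table from
#'   [extract_windows()], or any data frame with the standard covariate
#'   columns plus `trial_id`.
#' @param model One of [encoding_model_names()].
#' @param pca_basis Optional list with `lengths` and `dlengths`
#'   [fit_pca_basis()] objects (muscle model only).
#' @return Object of class `design_matrix`: list with `X` (T x P, first
#'   column the intercept), `model`, `covariates` (column names).
#' @export
build_design <- function(dataset, model, pca_basis = NULL) {
  data <- dataset_covariates(dataset)
  dt <- dataset_dt(dataset)
  Z <- covariate_matrix(data, model, dt, data$trial_id, pca_basis)
  if (any(!is.finite(Z))) stop_invalid("non-finite covariates in design matrix")
  X <- cbind(intercept = 1, Z)
  structure(list(X = X, model = model, covariates = colnames(X)),
            class = "design_matrix")
}

# accessors letting build_design work on several container shapes
dataset_covariates <- function(dataset) {
  if (inherits(dataset, "binned_dataset")) {
    cbind(dataset$covariates, trial_id = dataset$trial_id)
  } else if (inherits(dataset, "trial_windows")) {
    cbind(dataset$covariates, trial_id = dataset$trial_id)
  } else if (is.data.frame(dataset)) {
    if (is.null(dataset$trial_id)) dataset$trial_id <- 1L
    dataset
  } else {
    stop_invalid("unsupported dataset type for build_design")
  }
}

dataset_dt <- function(dataset) {
  if (inherits(dataset, "binned_dataset")) {
    dataset$bin_width
  } else if (inherits(dataset, "trial_windows")) {
    dataset$window
  } else {
    attr(dataset, "dt") %||% 1
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a PCA basis
#'
#' Principal axes of the mean-centered signals, via the singular value
#' decomposition ([stats::prcomp()]). If the signals have rank below
#' `n_components`, the basis retains fewer components with a warning.
#'
#' @param signals T x M numeric matrix.
#' @param n_components Number of components to retain (default 5).
#' @return Object of class `pca_basis`: `mean` (M-vector), `loadings`
#'   (M x k, orthonormal columns), `explained` (fractions of total
#'   variance, nonincreasing).
#' @export
fit_pca_basis <- function(signals, n_components = 5) {
  signals <- as.matrix(signals)
  if (any(!is.finite(signals))) stop_invalid("non-finite PCA input")
  if (nrow(signals) <= n_components && nrow(signals) <= ncol(signals)) {
    stop_invalid("too few rows (%d) to fit a %d-component PCA basis",
                 nrow(signals), n_components)
  }
  p <- stats::prcomp(signals, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  tot <- sum(ev)
  rank <- sum(ev > max(ev) * 1e-12)
  k <- min(n_components, rank, ncol(signals))
  if (k < n_components) {
    warning(sprintf("signal rank %d < %d requested components; retaining %d",
                    rank, n_components, k))
  }
  structure(
    list(mean = p$center, loadings = p$rotation[, seq_len(k), drop = FALSE],
         explained = ev[seq_len(k)] / tot, eigenvalues = ev),
    class = "pca_basis")
}

#' Project signals onto a PCA basis
#'
#' @param basis A [fit_pca_basis()] object.
#' @param signals T x M matrix in the basis' original signal space.
#' @return T x k matrix of component scores.
#' @export
project_pca <- function(basis, signals) {
  stopifnot(inherits(basis, "pca_basis"))
  signals <- as.matrix(signals)
  scores <- sweep(signals, 2, basis$mean) %*% basis$loadings
  colnames(scores) <- paste0("pc", seq_len(ncol(scores)))
  scores
}
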