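#' Ground-truth Poisson neuron
#'
#' A generative neuron whose expected spike count per analysis bin is
#' `exp(intercept + gain_condition * (x %*% coefficients))`, with the linear
#' predictor clipped at `log(50)` counts per bin before exponentiation. The
#' condition gains implement efference-copy-like modulation: a gain applied
#' to the tuned (non-intercept) part of the drive that depends on whether
#' the movement is active or passive. Conditions other than
#' "active"/"passive" (e.g. the two workspaces) always use gain 1, so
#' workspace differences in firing arise only through the kinematics.
#'
#' @param neuron_id Label.
#' @param covariate_set One of [encoding_model_names()] or `"untuned"`.
#' @param intercept Log expected count per analysis bin at zero covariates.
#' @param coefficients Numeric vector, log-count change per covariate unit;
#'   length must match the covariate set's non-intercept dimensionality.
#' @param active_gain,passive_gain Nonnegative multipliers on the tuned
#'   drive during active / passive trials.
#' @return Object of class `gt_neuron`.
#' @export
ground_truth_neuron <- function(neuron_id, covariate_set, intercept,
                                coefficients = numeric(0),
                                active_gain = 1, passive_gain = 1) {
  stopifnot(covariate_set %in% c(encoding_model_names(), "untuned"),
            is.finite(intercept), active_gain >= 0, passive_gain >= 0)
  structure(
    list(neuron_id = as.character(neuron_id), covariate_set = covariate_set,
         intercept = intercept, coefficients = as.numeric(coefficients),
         active_gain = active_gain, passive_gain = passive_gain),
    class = "gt_neuron")
}

# per-covariate-column coefficient SDs used by neuron_population();
# chosen once to give severalfold firing-rate modulation over the tasks'
# kinematic ranges (positions ~0.2 m, speeds ~0.3 m/s)
default_coef_sd <- function(colname) {
  if (grepl("^(hand|elbow)_v", colname)) return(4)
  if (grepl("^(hand|elbow)_[xyz]$", colname)) return(3)
  if (grepl("^f[xyz]$", colname)) return(0.4)
  if (grepl("^t[xyz]$", colname)) return(2)
  if (grepl("^d?q[0-9]$", colname)) {
    return(if (grepl("^d", colname)) 0.6 else 1.5)
  }
  if (grepl("^ego_d", colname)) return(if (grepl("rho", colname)) 3 else 0.6)
  if (grepl("^ego_", colname)) return(if (grepl("rho", colname)) 5 else 1.5)
  if (grepl("^dlen_", colname)) return(4)
  if (grepl("^len_", colname)) return(40)
  1
}

covariate_set_names <- function(covariate_set, n_muscles = 6) {
  ck <- kinematic_cols
  switch(covariate_set,
    untuned = character(0),
    hand_only = c(ck$hand, ck$hand_v),
    whole_arm = c(ck$hand, ck$hand_v, ck$elbow, ck$elbow_v),
    hand_force = c(ck$hand, ck$hand_v, ck$force),
    egocentric = c("ego_az", "ego_pol", "ego_rho",
                   "ego_daz", "ego_dpol", "ego_drho"),
    joint = c(ck$joint, ck$joint_v),
    muscle_pca = c(paste0("len_pc", 1:5), paste0("dlen_pc", 1:5)),
    stop_invalid("unknown covariate set '%s'", covariate_set))
}

#' Generate a population of ground-truth neurons
#'
#' Draws intercepts from baseline firing rates log-uniform on
#' `baseline_hz`, and coefficients from independent zero-mean normals whose
#' SDs (per covariate column) give physiologically plausible severalfold
#' rate modulation across the workspace. `coef_scale` rescales all
#' coefficient SDs at once; `zero_cols` forces named covariate columns to
#' zero coefficient (e.g. velocity-only neurons).
#'
#' @param n Number of neurons.
#' @param covariate_set Ground-truth covariate set for all neurons.
#' @param bin_width Analysis bin width (s) converting baseline rates to
#'   per-bin intercepts.
#' @param baseline_hz Length-2 range of baseline firing rates (spikes/s).
#' @param coef_scale Global multiplier on coefficient SDs.
#' @param zero_cols Covariate column names whose coefficients are fixed at 0.
#' @param coef_sd_override Named numeric vector replacing the default SD
#'   for specific covariate columns (e.g. boosting elbow terms to build a
#'   proximal-limb-dominated population, mirroring the proximal bias of
#'   area 2 receptive fields).
#' @param fixed_magnitude If TRUE, each neuron's coefficient vector is
#'   rescaled to the same overall magnitude (the root-mean-square expected
#'   under the column SDs), randomizing tuning direction but matching
#'   modulation depth across the population. Useful when a contrast (e.g.
#'   condition gating) should not be confounded with tuning strength.
#' @param active_gain,passive_gain Condition gains (scalars, applied to all
#'   neurons).
#' @param prefix Neuron id prefix.
#' @param seed Integer seed.
#' @return List of [ground_truth_neuron()] objects.
#' @export
neuron_population <- function(n, covariate_set, bin_width = 0.05,
                              baseline_hz = c(10, 40), coef_scale = 1,
                              zero_cols = character(0),
                              coef_sd_override = NULL,
                              fixed_magnitude = FALSE,
                              active_gain = 1, passive_gain = 1,
                              prefix = covariate_set, seed = 1L) {
  force(baseline_hz); force(active_gain); force(passive_gain)
  cols <- covariate_set_names(covariate_set)
  sds <- vapply(cols, default_coef_sd, 0)
  if (!is.null(coef_sd_override)) {
    hit <- intersect(names(coef_sd_override), cols)
    sds[hit] <- coef_sd_override[hit]
  }
  sds <- sds * coef_scale
  sds[cols %in% zero_cols] <- 0
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      base <- exp(stats::runif(1, log(baseline_hz[1]), log(baseline_hz[2])))
      coefs <- stats::rnorm(length(cols), 0, sds)
      if (fixed_magnitude && any(sds > 0)) {
        coefs <- coefs * sqrt(sum(sds^2)) / sqrt(sum(coefs^2))
      }
      ground_truth_neuron(
        neuron_id = sprintf("%s_%03d", prefix, i),
        covariate_set = covariate_set,
        intercept = log(base * bin_width),
        coefficients = coefs,
        active_gain = active_gain, passive_gain = passive_gain)
    })
  })
}

condition_gain <- function(neuron, condition) {
  g <- rep(1, length(condition))
  g[condition == "active"] <- neuron$active_gain
  g[condition == "passive"] <- neuron$passive_gain
  g
}

#' Generate Poisson spike counts from ground-truth neurons
#'
#' Draws counts row-by-row as Poisson with mean
#' `exp(min(eta, log(50))) * dt / bin_width`, where
#' `eta = intercept + gain * (x %*% coefficients)`. The clip caps the
#' expected count at 50 per analysis bin — identically to the clip applied
#' by [predict_rates()] — and the `dt / bin_width` factor rescales the
#' per-bin mean to the sampling resolution at which counts are drawn (so
#' simulation-rate samples sum to the intended per-bin counts).
#'
#' @param neurons List of [ground_truth_neuron()] objects.
#' @param covariates Data frame of covariate columns (standard names), one
#'   row per sample or bin.
#' @param dt Duration represented by one row (s).
#' @param bin_width Analysis bin width (s) the intercepts refer to.
#' @param condition Optional per-row condition labels (for active/passive
#'   gains).
#' @param trial_id Optional per-row trial ids (needed for derivative-based
#'   covariate sets).
#' @param seed Optional integer seed.
#' @return Integer matrix, rows x neurons, with neuron ids as column names.
#' @export
generate_spike_counts <- function(neurons, covariates, dt, bin_width = dt,
                                  condition = NULL, trial_id = NULL,
                                  seed = NULL) {
  stopifnot(length(neurons) > 0, is.data.frame(covariates))
  force(dt); force(bin_width)
  if (is.null(condition)) condition <- rep("", nrow(covariates))
  if (is.null(trial_id)) {
    trial_id <- covariates$trial_id %||% rep(1L, nrow(covariates))
  }
  draw <- function() {
    counts <- matrix(0L, nrow(covariates), length(neurons))
    cache <- list()
    for (j in seq_along(neurons)) {
      nj <- neurons[[j]]
      set <- nj$covariate_set
      if (is.null(cache[[set]])) {
        cache[[set]] <- covariate_matrix(covariates, set, dt, trial_id)
      }
      Z <- cache[[set]]
      if (length(nj$coefficients) != ncol(Z)) {
        stop_invalid("neuron '%s': %d coefficients but covariate set '%s' has %d columns",
                     nj$neuron_id, length(nj$coefficients), set, ncol(Z))
      }
      drive <- if (ncol(Z)) drop(Z %*% nj$coefficients) else 0
      eta <- nj$intercept + condition_gain(nj, condition) * drive
      mu <- exp(pmin(eta, log(50))) * dt / bin_width
      counts[, j] <- stats::rpois(nrow(covariates), mu)
    }
    colnames(counts) <- vapply(neurons, `[[`, "", "neuron_id")
    counts
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
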