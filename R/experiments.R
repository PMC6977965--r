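#' Assemble a validated experiment configuration
#'
#' Bundles task, arm, population and analysis settings for one experiment
#' run. Analysis defaults mirror the study design the package emulates:
#' K = 5 folds, R = 20 repeats, alpha = 0.05 with a Bonferroni factor of
#' 6, 1000 bootstrap iterations, 95th-percentile tuning criterion.
#'
#' @param experiment `"two_workspace"` or `"active_passive"`.
#' @param task A [task_config()].
#' @param geometry An [arm_geometry()].
#' @param neurons List of [ground_truth_neuron()] objects.
#' @param models Models to fit and compare (first two are the headline
#'   pair).
#' @param K,R Cross-validation shape.
#' @param alpha,bonferroni Significance settings for model comparisons.
#' @param n_boot Bootstrap iterations for PD and tuning tests.
#' @param seed Master seed; per-stage streams are derived from it.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("two_workspace", "active_passive"),
                              task = task_config(),
                              geometry = arm_geometry(),
                              neurons,
                              models = c("hand_only", "whole_arm"),
                              K = 5, R = 20, alpha = 0.05, bonferroni = 6,
                              n_boot = 1000, seed = 1L) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(task, "task_config"), inherits(geometry, "arm_geometry"),
            length(neurons) > 0, all(models %in% encoding_model_names()),
            K >= 2, R >= 1, alpha > 0, alpha < 1, bonferroni >= 1,
            n_boot >= 1)
  structure(
    list(experiment = experiment, task = task, geometry = geometry,
         neurons = neurons, models = models, K = K, R = R, alpha = alpha,
         bonferroni = bonferroni, n_boot = n_boot, seed = as.integer(seed)),
    class = "experiment_config")
}

bundle_meta <- function(ec, stage_seeds) {
  hashable <- list(experiment = ec$experiment, task = unclass(ec$task),
                   geometry = unclass(ec$geometry),
                   neurons = lapply(ec$neurons, unclass),
                   models = ec$models, K = ec$K, R = ec$R,
                   alpha = ec$alpha, bonferroni = ec$bonferroni,
                   n_boot = ec$n_boot, seed = ec$seed)
  list(experiment = ec$experiment, seed = ec$seed,
       stage_seeds = stage_seeds, config_hash = config_hash(hashable),
       package_version = as.character(utils::packageVersion("reachenc")))
}

#' Run the two-workspace encoding-model experiment end to end
#'
#' simulate -> bin -> repeated-CV model fits -> pseudo-R2 comparison ->
#' tuning-curve correlation -> PD shifts and cVAF -> cross-workspace model
#' consistency. All stages draw their seeds deterministically from the
#' master seed, so a config re-run reproduces every table.
#'
#' @param ec An [experiment_config()] with `experiment = "two_workspace"`.
#' @param consistency_R Repeats for the (descriptive) cross-workspace
#'   consistency stage; fewer than the main CV by default to keep the
#'   stage's cost proportionate.
#' @param verbose Print stage progress.
#' @return Object of class `report_bundle` with tables: `cv_scores`,
#'   `comparison`, `tuning` (per-neuron tuned flags and depths per
#'   workspace), `pd_shifts` (per neuron x model), `cvaf` (per model with
#'   CI), `curve_correlation`, `consistency`.
#' @export
run_two_workspace_experiment <- function(ec, consistency_R = 5,
                                         verbose = interactive()) {
  stopifnot(inherits(ec, "experiment_config"),
            ec$experiment == "two_workspace")
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- list(simulate = derive_seed(ec$seed, "simulate"),
                cv = derive_seed(ec$seed, "cv"),
                tuning = derive_seed(ec$seed, "tuning"),
                consistency = derive_seed(ec$seed, "consistency"))
  say("stage simulate: %d trials", ec$task$n_trials)
  session <- simulate_two_workspace_session(ec$task, ec$geometry, ec$neurons,
                                            seed = seeds$simulate)
  ds <- bin_signals(session)
  say("stage cv: %d bins x %d neurons, models %s", nrow(ds$counts),
      ncol(ds$counts), paste(ec$models, collapse = "+"))
  eng <- repeated_cv_analysis(ds, ec$models, K = ec$K, R = ec$R, seed = seeds$cv,
                   pd_shift = TRUE)
  comparison <- compare_models(eng$cv, ec$models[1:2], alpha = ec$alpha,
                               bonferroni = ec$bonferroni)
  say("stage tuning: shuffle-null significance per workspace")
  conditions <- sort(unique(ds$condition))
  tuned_tab <- do.call(rbind, lapply(colnames(ds$counts), function(nn) {
    row <- data.frame(neuron = nn, stringsAsFactors = FALSE)
    for (ci in seq_along(conditions)) {
      rows <- ds$condition == conditions[ci]
      ts <- tryCatch(
        tuning_significance(ds$counts[rows, nn], ds$theta[rows],
                            n_boot = ec$n_boot,
                            seed = derive_seed(seeds$tuning,
                                               paste(nn, ci))),
        error = function(e) list(tuned = NA, depth = NA_real_))
      row[[paste0("tuned_", conditions[ci])]] <- ts$tuned
      row[[paste0("depth_", conditions[ci])]] <- ts$depth
    }
    row
  }))
  tuned_both <- tuned_tab$neuron[!is.na(tuned_tab[[2]]) &
                                   !is.na(tuned_tab[[4]]) &
                                   tuned_tab[[2]] & tuned_tab[[4]]]
  say("stage pd_shift: %d/%d neurons tuned in both workspaces",
      length(tuned_both), nrow(tuned_tab))
  if (!length(tuned_both)) {
    warning("no neuron passed the tuned-in-both-workspaces filter; ",
            "PD-shift summary uses all neurons")
    tuned_both <- tuned_tab$neuron
  }
  shifts <- summarize_pd_shifts(eng$shifts, tuned_both, ec$K, ec$R)
  curve_cor <- stats::aggregate(curve_cor ~ neuron + model,
                                data = eng$curves, FUN = mean,
                                na.action = stats::na.omit)
  say("stage consistency: cross-workspace, %d repeats", consistency_R)
  cons <- model_consistency(ds, ec$models[min(2, length(ec$models))],
                            K = ec$K, R = consistency_R,
                            seed = seeds$consistency)
  meta <- bundle_meta(ec, seeds)
  tables <- list(cv_scores = eng$cv$scores, comparison = comparison$table,
                 tuning = tuned_tab, pd_shifts = shifts$per_neuron,
                 cvaf = shifts$per_model, curve_correlation = curve_cor,
                 consistency = cons$summary)
  tables <- lapply(tables, function(t) {
    t$config_hash <- meta$config_hash
    t
  })
  structure(list(tables = tables, meta = meta, session = session,
                 dataset = ds, cv = eng$cv, comparison = comparison,
                 consistency = cons),
            class = "report_bundle")
}

#' Run the active/passive experiment end to end
#'
#' simulate center-out -> movement-onset detection -> 120 ms windows ->
#' kinematic separability -> per-neuron separability indices -> within- vs
#' both-condition model fits -> consistency-vs-separability correlation.
#'
#' @param ec An [experiment_config()] with `experiment = "active_passive"`.
#' @param verbose Print stage progress.
#' @return A `report_bundle` with tables: `windows` (per-trial summary),
#'   `separability` (per neuron, with the kinematic index attached),
#'   `consistency`, `correlation`.
#' @export
run_active_passive_experiment <- function(ec, verbose = interactive()) {
  stopifnot(inherits(ec, "experiment_config"),
            ec$experiment == "active_passive")
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- list(simulate = derive_seed(ec$seed, "simulate"),
                separability = derive_seed(ec$seed, "separability"),
                consistency = derive_seed(ec$seed, "consistency"),
                correlation = derive_seed(ec$seed, "correlation"))
  say("stage simulate: %d center-out trials", ec$task$n_trials)
  session <- simulate_center_out_session(ec$task, ec$geometry, ec$neurons,
                                         seed = seeds$simulate)
  onsets <- session_onsets(session)
  windows <- extract_windows(session, onsets)
  say("stage separability: kinematic + %d neurons", ncol(windows$rates))
  kin_sep <- kinematic_separability(windows, K = ec$K, R = ec$R,
                                    seed = derive_seed(seeds$separability,
                                                       "kinematic"))
  sep_tab <- do.call(rbind, lapply(colnames(windows$rates), function(nn) {
    s <- separability_index(windows$rates[, nn], windows$condition,
                            K = ec$K, R = ec$R,
                            seed = derive_seed(seeds$separability, nn))
    data.frame(neuron = nn, index = s$index, ci_lo = s$ci[1],
               ci_hi = s$ci[2], chance = s$chance,
               kinematic_index = kin_sep$index, stringsAsFactors = FALSE)
  }))
  say("stage consistency: %s model, within vs both conditions",
      ec$models[min(2, length(ec$models))])
  cons <- model_consistency(windows, ec$models[min(2, length(ec$models))],
                            K = ec$K, R = ec$R, seed = seeds$consistency)
  both_by_neuron <- stats::aggregate(both ~ neuron, data = cons$summary,
                                     FUN = mean)
  merged <- merge(both_by_neuron, sep_tab, by = "neuron")
  corr <- consistency_vs_separability(merged$both, merged$index,
                                      n_boot = ec$n_boot * 10,
                                      seed = seeds$correlation)
  meta <- bundle_meta(ec, seeds)
  tables <- list(
    windows = data.frame(trial_id = windows$trial_id,
                         condition = windows$condition,
                         direction = windows$direction),
    separability = sep_tab,
    consistency = cons$summary,
    correlation = data.frame(correlation = corr$correlation,
                             ci_lo = corr$ci[1], ci_hi = corr$ci[2],
                             n = corr$n))
  tables <- lapply(tables, function(t) {
    t$config_hash <- meta$config_hash
    t
  })
  structure(list(tables = tables, meta = meta, session = session,
                 windows = windows, consistency = cons,
                 kinematic_separability = kin_sep, correlation = corr),
            class = "report_bundle")
}
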