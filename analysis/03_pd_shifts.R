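#!/usr/bin/env Rscript
# Preferred-direction analysis of the two-workspace run: shuffle-null
# tuning significance per workspace, actual vs model-predicted PD shifts
# between the workspaces, and the circular VAF of each model's shift
# predictions. Run analysis/02_two_workspace_models.R first.

suppressPackageStartupMessages(library(reachenc))

ses <- load_session("results/sessions/two_workspace")
ds <- bin_signals(ses)
shifts <- utils::read.table("results/two_workspace/fold_pd_shifts.tsv",
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
curves <- utils::read.table("results/two_workspace/fold_curve_cor.tsv",
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)

message("-- tuning significance (shuffle null, 95th percentile) --")
tuned <- vapply(colnames(ds$counts), function(nn) {
  all(vapply(unique(ds$condition), function(cc) {
    rows <- ds$condition == cc
    tuning_significance(ds$counts[rows, nn], ds$theta[rows], n_boot = 200,
                        seed = derive_seed(72, paste(nn, cc)))$tuned
  }, TRUE))
}, TRUE)
message(sprintf("%d/%d neurons significantly tuned in both workspaces",
                sum(tuned), length(tuned)))

K <- 5
R <- max(shifts$rep)
sh <- summarize_pd_shifts(shifts, names(tuned)[tuned], K = K, R = R)
print(sh$per_model)
hand <- sh$per_neuron[sh$per_neuron$model == "hand_only", ]
arm <- sh$per_neuron[sh$per_neuron$model == "whole_arm", ]
message(sprintf(
  "mean |actual shift| %.1f deg; hand-only predicts %.1f deg, whole-arm tracks actual (cVAF %.2f vs %.2f)",
  mean(abs(arm$actual_shift)) * 180 / pi,
  mean(abs(hand$predicted_shift)) * 180 / pi,
  sh$per_model$mean_cvaf[sh$per_model$model == "whole_arm"],
  sh$per_model$mean_cvaf[sh$per_model$model == "hand_only"]))

cc <- stats::aggregate(curve_cor ~ model, data = curves, FUN = mean)
message("mean actual-vs-predicted tuning-curve correlation by model:")
print(cc)

utils::write.table(sh$per_neuron, "results/two_workspace/pd_shifts.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(sh$per_model, "results/two_workspace/cvaf.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
message("tables written under results/two_workspace/")
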