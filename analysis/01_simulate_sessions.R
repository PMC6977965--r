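#!/usr/bin/env Rscript
# Generate the two synthetic sessions the downstream analyses consume:
#  - a two-workspace random-target session with whole-arm-encoding neurons
#    (elbow drive comparable to hand drive, mirroring the proximal-limb
#    bias of area 2), and
#  - a center-out active/passive session with a mixed population: half
#    condition-blind velocity-tuned neurons, half "efference-copy-like"
#    neurons whose tuned drive is gated by movement type (gain 2 active,
#    0.5 passive), at matched modulation depth.
# Sessions are written as plain-text tables under results/sessions/.

suppressPackageStartupMessages(library(reachenc))

seed <- 20240915
geom <- arm_geometry()

message("-- two-workspace session --")
ws_cfg <- task_config(n_trials = 150, rng_seed = seed)
ws_pop <- neuron_population(
  24, "whole_arm",
  coef_sd_override = c(elbow_x = 8, elbow_y = 8, elbow_z = 8,
                       elbow_vx = 8, elbow_vy = 8, elbow_vz = 8),
  seed = derive_seed(seed, "ws_pop"))
ws <- simulate_two_workspace_session(ws_cfg, geom, ws_pop,
                                     seed = derive_seed(seed, "ws_sim"))
print(ws)
message(sprintf("  mean firing rate: %.1f spikes/s",
                mean(ws$counts) / ws$sim_dt))
save_session(ws, "results/sessions/two_workspace", "two_workspace")

message("-- center-out active/passive session --")
co_cfg <- task_config(n_trials = 300, movement_duration = 0.4,
                      rng_seed = seed)
mk <- function(prefix, stage, ag, pg) {
  neuron_population(10, "hand_only",
                    zero_cols = c("hand_x", "hand_y", "hand_z"),
                    coef_scale = 2.5, baseline_hz = c(20, 50),
                    fixed_magnitude = TRUE, active_gain = ag,
                    passive_gain = pg, prefix = prefix,
                    seed = derive_seed(seed, stage))
}
co_pop <- c(mk("blind", "co_blind", 1, 1), mk("gated", "co_gated", 2, 0.5))
co <- simulate_center_out_session(co_cfg, geom, co_pop,
                                  seed = derive_seed(seed, "co_sim"))
print(co)
sp <- sqrt(co$samples$hand_vx^2 + co$samples$hand_vy^2)
message(sprintf("  peak hand speed: %.2f m/s (active), %.2f m/s (passive)",
                max(sp[co$samples$condition == "active"]),
                max(sp[co$samples$condition == "passive"])))
save_session(co, "results/sessions/center_out", "center_out")

message("sessions written under results/sessions/")
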