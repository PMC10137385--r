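#!/usr/bin/env Rscript
# Step 1 — simulate the balanced stick at the calibrated operating point.
#
# Integrates the stochastic delay equation for the vertical displacement
# angle (tau = 10 steps, R0 = 5, sigma = 10, L = 49% of the environment
# width) and records one trajectory plus a small ensemble summary.
# Outputs: results/trajectory.csv (+ .json sidecar), printed narrative.

suppressPackageStartupMessages(library(stickbalance))
dir.create("results", showWarnings = FALSE)

params <- stick_params()
print(params)

traj <- integrate_stick(params, integrator_config(seed = 1))
print(traj)
write_trajectory_csv(traj, "results/trajectory.csv")

runs <- run_ensemble(params, integrator_config(seed = 1), 20)
falls <- vapply(runs, `[[`, 0, "fall_time")
cat(sprintf(
  "Ensemble of 20 runs: every stick eventually falls; survival %0.f-%0.f time units (median %.0f).\n",
  min(falls), max(falls), median(falls)))
cat("The trajectory balances intermittently before toppling — the regime the\n")
cat("stylized-facts analysis (step 3) feeds on.\n")

# numerical sanity: first-order error contraction under dt halving
theta_at <- function(dt) {
  p <- stick_params(R0 = 5.2, sigma = 0, tau_steps = round(0.1 / dt))
  tr <- integrate_stick(p, integrator_config(dt = dt,
                                             t_max_steps = round(5 / dt) + 1,
                                             seed = 1))
  tr$theta[length(tr$theta)]
}
e1 <- abs(theta_at(0.02) - theta_at(0.01))
e2 <- abs(theta_at(0.01) - theta_at(0.005))
cat(sprintf("dt-halving error contraction at t = 5 (noise-free): %.2fx\n",
            e1 / e2))
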