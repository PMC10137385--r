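#!/usr/bin/env Rscript
# Step 2 — noise-free regime analysis and critical thresholds.
#
# Locates the critical feedback gain R0*(tau) by bisection on simulations
# (departure-from-upright criterion), compares the tau = 0 threshold with
# the analytic fold g/L, verifies the linear-stability oracle, and maps
# the three regimes. Outputs: results/thresholds.json,
# results/regime_map_sigma0.csv, results/regime_map_sigma10.csv.

suppressPackageStartupMessages(library(stickbalance))
dir.create("results", showWarnings = FALSE)

gl <- stick_params()$g / stick_length(stick_params())
cat(sprintf("Analytic fold of the linearized model: g/L = %.5f\n", gl))

thresholds <- lapply(c(0, 5, 10), function(ts) {
  th <- find_critical_R0(ts, bracket = c(4.0, 5.0), tol = 1e-6)
  print(th)
  th
})
jsonlite::write_json(lapply(thresholds, unclass), "results/thresholds.json",
                     auto_unbox = TRUE, digits = NA)
r0s <- vapply(thresholds, `[[`, 0, "R0_star")
cat(sprintf("tau = 0 threshold sits %.2f%% below the fold; thresholds %s with delay.\n",
            100 * (gl - r0s[1]) / gl,
            if (all(diff(r0s) > 0)) "increase strictly" else "do NOT increase"))

# linear-stability oracle at the operating point and beyond the window
for (R0 in c(4.5, 4.95, 5, 6)) {
  r <- rightmost_root(stick_params(R0 = R0, tau_steps = 10))
  cat(sprintf("rightmost root at R0 = %.2f: %+.4f %+.4fi  (%s)\n",
              R0, Re(r), Im(r),
              if (Re(r) < 0) "stable" else "unstable"))
}

map0 <- sweep_regimes(c(0, 5, 10, 15), seq(4.0, 6.0, by = 0.5), sigma = 0,
                      config = integrator_config(fall_angle = 0.15, seed = 1))
print(map0)
write_regime_map_csv(map0, "results/regime_map_sigma0.csv")

# with sigma = 10 exact thresholds vanish; the interesting window survives
map10 <- sweep_regimes(c(2, 10), c(3, 5, 5.2, 7), sigma = 10,
                       config = integrator_config(seed = 2))
print(map10)
write_regime_map_csv(map10, "results/regime_map_sigma10.csv")
cat("Under noise the stick always falls eventually, but survival inside\n")
cat("4 < R0 < 6 is far longer — the window the operating point sits in.\n")
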