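# stickbalance

Human stick balancing as a model for financial self-regulation:
simulation and stylized-facts analysis of an inverted pendulum under
delayed, noisy feedback.

## The problem

Balancing a stick on a fingertip means stabilizing an unstable state
through a feedback loop with sensorimotor delay and neural noise. The
vertical displacement angle θ (θ = 0 upright) obeys the stochastic delay
differential equation

    θ''(t) = -(γ/m) θ'(t) + (g/L) sin θ(t) - (R₀ + ξ(t)) θ(t - τ)

where the corrective force is proportional feedback on the delayed angle
θ(t−τ) and ξ(t) is zero-mean Gaussian white noise of amplitude σ acting
on the gain. The package is for researchers in computational
neuroscience / econophysics who want to (i) map the dynamical regimes of
this equation — repeller, spiral node, spiral repeller — and the critical
gain R₀\*(τ) where the upright state loses stability, and (ii) test the
analogy between this control loop and financial markets: with a suitable
dose of noise, one-step changes of the angular velocity
ΔV(t) = θ'(t) − θ'(t−1) reproduce the canonical stylized facts of daily
price returns — fat-tailed distributions (quantified by the entropic
index q of a q-Gaussian fit, y = A[1−(1−q)Bx²]^(1/(1−q)), with q = 1 the
Gaussian), vanishing raw autocorrelation, and volatility clustering.

The package provides, as plain R functions over light S3 objects:

* `integrate_stick()`, `run_ensemble()` — seeded Euler integration of
  the delay equation (compiled core), with fall detection;
* `classify_regime()`, `find_critical_R0()`, `rightmost_root()`,
  `sweep_regimes()` — regime taxonomy, simulated thresholds by
  bisection, and an analytic linear-stability oracle via the
  characteristic equation λ² + (γ/m)λ − g/L + R₀e^(−λτ) = 0;
* `velocity_returns()`, `normalize_and_pool()`, `empirical_pdf()`,
  `fit_qgaussian()`, `sample_qgaussian()`, `acf_returns()` — the
  stylized-facts statistics;
* `read_price_csv()`, `price_to_returns()` — Yahoo-style daily close
  CSVs to log returns;
* `generate_garch()`, `generate_iid_gaussian()` — synthetic financial
  stand-ins (volatility clustering / null model);
* `run_stylized_facts_report()` — the end-to-end comparison with
  three boolean flags per source.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `04_financial_comparison.R`) that runs the full study
and writes its tables under `results/`.

## Worked example

Twenty noisy balancing runs at the calibrated operating point
(τ = 10 steps, R₀ = 5, σ = 10, L = 49% of the environment width), pooled
returns, q-Gaussian fit, and the zero-delay threshold:

```r
library(stickbalance)

p <- stick_params()
p
#> Stick-balancing parameters
#>   L = 2.0394 (49% of env width 4.162), g/L = 4.8054
#>   gamma = 0.5, m = 1, R0 = 5, sigma = 10
#>   tau = 10 steps, theta(0) = 0.06

integrate_stick(p, integrator_config(seed = 1))
#> Stick trajectory: 4978 samples, dt = 0.01
#>   fell at t = 49.77

runs   <- run_ensemble(p, integrator_config(seed = 1), 20)
pooled <- normalize_and_pool(lapply(runs, velocity_returns))
fit_qgaussian(empirical_pdf(pooled))
#> q-Gaussian fit: q = 2.1701, A = 1.238, B = 18.98 (rss = 1.48e+03, converged)

find_critical_R0(0, bracket = c(4, 5), tol = 1e-6)
#> Critical gain at tau = 0 steps: R0* = 4.787382 (bracket [4.787381, 4.787382], 20 bisections)
```

The stick balances intermittently for ~50 time units before falling; the
pooled, z-scored velocity returns are strongly non-Gaussian (q ≈ 2.2,
deep in the power-law-tail regime typical of financial returns), and the
simulated critical gain at zero delay sits within 0.4% of the analytic
fold g/L = 4.805.

The full comparison report runs every source through identical
statistics:

```r
run_stylized_facts_report(list(sources = list(
  simulated = list(n_runs = 20, seed = 1),
  synthetic = list(generator = "garch", n = 100000, seed = 2))))
#> Stylized-facts report
#>   simulated  n =   48497  q = 2.170  ex.kurt =   9.07  rawACF in-band = 0.99  |r| ACF+ = 10/10
#>              flags: fat_tails=TRUE no_autocorrelation=TRUE volatility_clustering=TRUE
#>   synthetic  n =  100000  q = 1.089  ex.kurt =   0.34  rawACF in-band = 0.99  |r| ACF+ = 10/10
#>              flags: fat_tails=FALSE no_autocorrelation=TRUE volatility_clustering=TRUE
```

The simulated source carries all three financial stylized facts; the
GARCH stand-in shows volatility clustering with uncorrelated raw
returns; an i.i.d. Gaussian source (`generator = "gaussian"`) raises no
flags. A small synthetic daily price file ships in
`inst/extdata/synthetic_prices_example.csv` for trying the financial
path; `analysis/04_financial_comparison.R` reads any directory of real
Yahoo-style CSVs via the `REAL_PRICE_DIR` environment variable.

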