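test_that("upright equilibrium with no noise is a fixed point", {
  p <- stick_params(theta0 = 0, sigma = 0)
  tr <- integrate_stick(p, integrator_config(t_max_steps = 2000, seed = 1))
  expect_false(tr$fell)
  expect_true(all(tr$theta == 0))
  expect_true(all(tr$omega == 0))
})

test_that("uncontrolled inverted pendulum escapes monotonically and falls", {
  cfg <- integrator_config(seed = 1)
  for (gamma in c(0.5, 0)) {
    p <- stick_params(R0 = 0, sigma = 0, gamma = gamma)
    tr <- integrate_stick(p, cfg)
    expect_true(tr$fell)
    expect_true(is.finite(tr$fall_time))
    expect_true(all(diff(abs(tr$theta)) >= 0))
    expect_gte(abs(tr$theta[length(tr$theta)]), cfg$fall_angle)
  }
})

test_that("no delay, no noise matches the closed-form damped oscillator", {
  # linearized equation: theta'' + 0.5 theta' + (R0 - g/L) theta = 0,
  # theta(0) = 0.06, theta'(0) = 0; underdamped closed form as oracle
  p <- stick_params(R0 = 10, sigma = 0, tau_steps = 0)
  dt <- 1e-3
  cfg <- integrator_config(dt = dt, t_max_steps = 5000, seed = 1)
  tr <- integrate_stick(p, cfg)
  k <- p$R0 - g_over_L(p)
  a <- p$gamma / p$m / 2
  wd <- sqrt(k - a^2)
  exact <- exp(-a * tr$t) *
    (p$theta0 * cos(wd * tr$t) + (a * p$theta0 / wd) * sin(wd * tr$t))
  expect_false(tr$fell)
  expect_lt(max(abs(tr$theta - exact)), 0.01 * max(abs(exact)))
})

test_that("calibrated noisy operating point is intermittent and falls", {
  tr <- integrate_stick(stick_params(), integrator_config(seed = 5))
  expect_true(tr$fell)
  expect_gt(length(tr$t), 500)          # survives many steps first
  n <- length(tr$theta)
  expect_true(all(abs(tr$theta[-n]) < tr$config$fall_angle))
  expect_gte(abs(tr$theta[n]), tr$config$fall_angle)
  # spiral excursions in phase space: repeated sign changes of theta
  expect_gt(sum(diff(sign(tr$theta)) != 0), 4)
})

test_that("trajectory sampling grid is uniform and metadata consistent", {
  tr <- integrate_stick(stick_params(), integrator_config(seed = 3))
  expect_length(tr$theta, length(tr$t))
  expect_length(tr$omega, length(tr$t))
  expect_equal(diff(tr$t), rep(tr$config$dt, length(tr$t) - 1))
  expect_equal(tr$fall_time, tr$t[length(tr$t)])
})

test_that("integration is byte-identical under a fixed seed", {
  p <- stick_params()
  cfg <- integrator_config(seed = 42)
  expect_identical(integrate_stick(p, cfg), integrate_stick(p, cfg))
})

test_that("noise-free solution converges at first order in dt", {
  theta_at <- function(dt) {
    p <- stick_params(R0 = 5.2, sigma = 0, tau_steps = round(0.1 / dt))
    cfg <- integrator_config(dt = dt, t_max_steps = round(5 / dt) + 1,
                             seed = 1)
    tr <- integrate_stick(p, cfg)
    tr$theta[length(tr$theta)]
  }
  e1 <- abs(theta_at(0.02) - theta_at(0.01))
  e2 <- abs(theta_at(0.01) - theta_at(0.005))
  e3 <- abs(theta_at(0.005) - theta_at(0.0025))
  expect_gte(e1 / e2, 1.8)
  expect_gte(e2 / e3, 1.8)
})

test_that("invalid parameters and configs are rejected before integration", {
  expect_error(stick_params(L_frac = 0), "L_frac")
  expect_error(stick_params(L_frac = 1.2), "L_frac")
  expect_error(stick_params(sigma = -1), "sigma")
  expect_error(stick_params(tau_steps = 2.5), "tau_steps")
  expect_error(integrator_config(dt = 0), "dt")
  expect_error(integrator_config(fall_angle = 4), "fall_angle")
  expect_error(
    integrate_stick(stick_params(tau_steps = 50),
                    integrator_config(t_max_steps = 20)),
    "tau_steps")
})

test_that("ensemble of one reproduces a single run with the derived seed", {
  p <- stick_params()
  cfg <- integrator_config(seed = 9)
  ens <- run_ensemble(p, cfg, n_runs = 1)
  cfg1 <- cfg
  cfg1$seed <- stickbalance:::derive_run_seed(9, 1)
  expect_identical(ens[[1]], integrate_stick(p, cfg1))
})

test_that("ensemble runs are independent, reproducible and extendable", {
  p <- stick_params()
  cfg <- integrator_config(seed = 7)
  ens5 <- run_ensemble(p, cfg, n_runs = 5)
  falls <- vapply(ens5, `[[`, 0, "fall_time")
  expect_length(unique(falls), 5)       # all-pairs distinct
  ens8 <- run_ensemble(p, cfg, n_runs = 8)
  expect_identical(ens8[1:5], ens5)     # run i depends only on (seed, i)
  expect_error(run_ensemble(p, cfg, n_runs = 0), "n_runs")
})

test_that("pooled returns count equals the sum of per-run return counts", {
  ens <- run_ensemble(stick_params(), integrator_config(seed = 2), 20)
  pooled <- normalize_and_pool(lapply(ens, velocity_returns))
  expect_length(pooled$values,
                sum(vapply(ens, function(r) length(r$omega) - 1L, 0L)))
})

test_that("trajectory CSV export round-trips with a JSON sidecar", {
  tr <- integrate_stick(stick_params(),
                        integrator_config(seed = 4, t_max_steps = 2000))
  path <- file.path(withr::local_tempdir(), "traj.csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_equal(names(df), c("t", "theta", "omega"))
  expect_equal(df$theta, tr$theta)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$params$R0, 5)
  expect_equal(meta$fell, tr$fell)
})
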