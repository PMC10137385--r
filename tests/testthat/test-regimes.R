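# departure-from-upright criterion used throughout the noise-free
# bifurcation analysis
bifurcation_config <- function(seed = 1) {
  integrator_config(fall_angle = 0.15, seed = seed)
}

test_that("noise-free probes at tau = 10 steps show the three regimes", {
  cfg <- bifurcation_config()
  labels <- vapply(c(4.5, 4.95, 6), function(R0) {
    classify_regime(integrate_stick(stick_params(R0 = R0, sigma = 0),
                                    cfg))$label
  }, "")
  expect_equal(labels, c("REPELLER", "SPIRAL_NODE", "SPIRAL_REPELLER"))
})

test_that("low gain and short delay under noise is an immediate repeller", {
  tr <- integrate_stick(stick_params(R0 = 3, tau_steps = 2),
                        integrator_config(seed = 1))
  lab <- classify_regime(tr)
  expect_equal(lab$label, "REPELLER")
  expect_true(lab$evidence$fell)
})

test_that("too-short trajectories classify as UNDETERMINED", {
  tr <- integrate_stick(stick_params(R0 = 6, sigma = 0, tau_steps = 0),
                        integrator_config(t_max_steps = 5, seed = 1))
  expect_equal(classify_regime(tr)$label, "UNDETERMINED")
})

test_that("rightmost root solves the exact characteristic equation", {
  char_residual <- function(p, lambda, dt = 0.01) {
    gl <- p$g / stick_length(p)
    Mod(lambda^2 + (p$gamma / p$m) * lambda - gl +
          p$R0 * exp(-lambda * p$tau_steps * dt))
  }
  for (R0 in c(4.2, 5, 6, 9)) {
    for (ts in c(3, 10, 25)) {
      p <- stick_params(R0 = R0, tau_steps = ts)
      expect_lt(char_residual(p, rightmost_root(p)), 1e-8)
    }
  }
})

test_that("tau = 0 reduces to the quadratic with a fold at R0 = g/L", {
  p_fold <- stick_params(R0 = g_over_L(), tau_steps = 0)
  expect_lt(Mod(rightmost_root(p_fold)), 1e-10)
  # above the fold: stable; below: unstable
  expect_lt(Re(rightmost_root(stick_params(R0 = 5.5, tau_steps = 0))), 0)
  expect_gt(Re(rightmost_root(stick_params(R0 = 4.5, tau_steps = 0))), 0)
})

test_that("without feedback the unstable root is delay-independent", {
  expected <- (-0.5 + sqrt(0.25 + 4 * g_over_L())) / 2
  for (ts in c(0, 7, 40)) {
    r <- rightmost_root(stick_params(R0 = 0, tau_steps = ts))
    expect_equal(Re(r), expected, tolerance = 1e-10)
    expect_equal(Im(r), 0)
  }
})

test_that("collocation orders 64 and 128 agree after polishing", {
  p <- stick_params(R0 = 5, tau_steps = 10)
  r64 <- rightmost_root(p, order = 64)
  r128 <- rightmost_root(p, order = 128)
  expect_lt(Mod(r64 - r128), 1e-6)
})

test_that("the operating point is linearly stable but R0 = 6 is not", {
  expect_lt(Re(rightmost_root(stick_params(R0 = 5, tau_steps = 10))), 0)
  expect_gt(Re(rightmost_root(stick_params(R0 = 6, tau_steps = 10))), 0)
})

test_that("bisection converges within the iteration bound", {
  th <- find_critical_R0(0, bracket = c(4.0, 5.0), tol = 1e-3)
  expect_lte(th$iterations, ceiling(log2(1.0 / 1e-3)))
  expect_lte(th$bracket[2] - th$bracket[1], 1e-3)
  expect_gt(th$R0_star, th$bracket[1] - 1e-12)
  expect_lt(th$R0_star, th$bracket[2] + 1e-12)
})

test_that("a bracket with no fall/survive transition is rejected", {
  expect_error(find_critical_R0(0, bracket = c(6, 7), tol = 1e-3),
               "straddle")
})

test_that("noise-free tau = 0 sweep row splits exactly at the fold", {
  gl <- g_over_L()
  R0_grid <- c(4.0, 4.4, 5.2, 6.0)
  map <- sweep_regimes(0, R0_grid, sigma = 0, config = bifurcation_config())
  labs <- map$labels[1, ]
  expect_equal(unname(labs[R0_grid < gl]), rep("REPELLER", 2))
  expect_true(all(labs[R0_grid > gl] == "SPIRAL_NODE"))
  expect_false(any(labs == "SPIRAL_REPELLER"))
})

test_that("noisy sweep shows longer survival inside the complex window", {
  map <- sweep_regimes(2, c(3, 5.2), sigma = 10,
                       config = integrator_config(seed = 3))
  expect_gt(map$survival[1, 2], 5 * map$survival[1, 1])
})

test_that("degenerate sweep grids are rejected", {
  expect_error(sweep_regimes(numeric(0), c(5), sigma = 0), "non-empty")
  expect_error(sweep_regimes(c(0), numeric(0), sigma = 0), "non-empty")
})

test_that("regime map exports as long-format CSV", {
  map <- sweep_regimes(c(0, 10), c(4.0, 5.2), sigma = 0,
                       config = bifurcation_config())
  path <- file.path(withr::local_tempdir(), "map.csv")
  write_regime_map_csv(map, path)
  df <- read.csv(path)
  expect_equal(names(df), c("tau", "R0", "sigma", "label", "survival_time"))
  expect_equal(nrow(df), 4)
  expect_equal(df$label[df$tau == 0 & df$R0 == 4.0],
               unname(map$labels["tau0", "R0_4"]))
})
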