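#' Integrate the stochastic delayed-feedback stick-balancing equation
#'
#' Numerically integrates
#' \deqn{\ddot\theta = -(\gamma/m)\,\dot\theta + (g/L)\sin\theta -
#'   (R_0 + \xi(t))\,\theta(t-\tau)}
#' by explicit Euler stepping on \eqn{(\theta, \dot\theta)}, with the
#' delayed angle read from the stored trajectory (method of steps) and a
#' fresh noise draw \eqn{\xi \sim N(0, \sigma^2)} held constant over each
#' step. The pre-history on \eqn{[-\tau, 0]} is the constant function
#' \eqn{\theta \equiv \theta_0}, \eqn{\dot\theta \equiv 0}.
#'
#' Integration stops at the first sample with
#' `|theta| >= config$fall_angle` (the violating sample is kept, so a
#' fallen trajectory ends with it) or after `config$t_max_steps` steps.
#' A numerically non-finite state is flagged as an overflow and treated
#' as a fall at the offending step.
#'
#' @param params A [stick_params()] object.
#' @param config An [integrator_config()] object; `config$seed` makes the
#'   run fully reproducible.
#'
#' @return An object of class `stick_trajectory`: a list with uniformly
#'   spaced `t`, the samples `theta` and `omega` (\eqn{\dot\theta}),
#'   logical `fell`, `fall_time` (`NA` if the stick never fell within the
#'   horizon), logical `overflow`, and the `params` and `config` used.
#' @examples
#' traj <- integrate_stick(stick_params(), integrator_config(seed = 42))
#' traj$fell
#' @export
integrate_stick <- function(params, config = integrator_config()) {
  stopifnot(inherits(params, "stick_params"),
            inherits(config, "integrator_config"))
  if (config$t_max_steps < params$tau_steps + 2) {
    stop("t_max_steps must be at least tau_steps + 2")
  }
  set.seed(config$seed)
  raw <- sdde_integrate_cpp(
    theta0 = params$theta0,
    gamma_m = params$gamma / params$m,
    g_over_L = params$g / stick_length(params),
    R0 = params$R0,
    noise_sd = noise_sd_effective(params, config),
    tau_steps = params$tau_steps,
    dt = config$dt,
    t_max_steps = config$t_max_steps,
    fall_angle = config$fall_angle
  )
  n <- length(raw$theta)
  structure(
    list(t = config$dt * (seq_len(n) - 1),
         theta = raw$theta,
         omega = raw$omega,
         fell = raw$fell,
         fall_time = if (raw$fell) config$dt * raw$fall_step else NA_real_,
         overflow = raw$overflow,
         params = params,
         config = config),
    class = "stick_trajectory"
  )
}

#' @export
print.stick_trajectory <- function(x, ...) {
  cat(sprintf("Stick trajectory: %d samples, dt = %g\n",
              length(x$t), x$config$dt))
  if (x$fell) {
    cat(sprintf("  fell at t = %g%s\n", x$fall_time,
                if (x$overflow) " (numerical overflow)" else ""))
  } else {
    cat("  survived to the horizon\n")
  }
  invisible(x)
}

# Deterministic per-run seed: run i depends only on (seed, i), so
# ensembles are order-independent and extendable.
derive_run_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Run an ensemble of independent stick-balancing trajectories
#'
#' Repeats [integrate_stick()] with per-run seeds derived deterministically
#' from `(config$seed, i)`, so identical inputs reproduce identical output
#' and run `i` does not depend on `n_runs`.
#'
#' @inheritParams integrate_stick
#' @param n_runs Number of independent runs (default 20, the ensemble size
#'   over which pooled return statistics stabilize).
#' @return A list of `stick_trajectory` objects of length `n_runs`.
#' @export
run_ensemble <- function(params, config = integrator_config(), n_runs = 20) {
  stopifnot("n_runs must be >= 1" =
              is.numeric(n_runs) && n_runs >= 1 && n_runs == round(n_runs))
  lapply(seq_len(n_runs), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_run_seed(config$seed, i)
    integrate_stick(params, cfg_i)
  })
}

#' Export a trajectory as CSV plus a JSON sidecar
#'
#' Writes the samples as a `t,theta,omega` CSV and the parameters,
#' integrator settings, seed and fall time as a JSON file next to it.
#'
#' @param trajectory A `stick_trajectory`.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "stick_trajectory"))
  utils::write.csv(
    data.frame(t = trajectory$t, theta = trajectory$theta,
               omega = trajectory$omega),
    path, row.names = FALSE)
  meta <- list(
    params = unclass(trajectory$params),
    config = unclass(trajectory$config),
    fell = trajectory$fell,
    fall_time = trajectory$fall_time,
    overflow = trajectory$overflow
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
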