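#' Physical and control parameters of the balanced stick
#'
#' Bundles every constant of the delayed-feedback inverted-pendulum model:
#' the equation of motion integrated by [integrate_stick()] is
#' \deqn{\ddot\theta = -(\gamma/m)\,\dot\theta + (g/L)\sin\theta -
#'   r_0(t)\,\theta(t-\tau), \qquad r_0(t) = R_0 + \xi(t),}
#' where \eqn{\theta} is the vertical displacement angle (0 = upright) and
#' \eqn{\xi(t)} is zero-mean Gaussian white noise of amplitude `sigma`
#' perturbing the proportional feedback gain.
#'
#' The stick length is specified as a fraction `L_frac` of the simulation
#' environment width, so the physical length is `L = L_frac * env_width`.
#' The default `env_width` is calibrated so that at `L_frac = 0.49` the
#' gravitational stiffness is `g/L = 4.805`, which is exactly the analytic
#' zero-delay stability threshold of the linearized model (the gain below
#' which the upright state is a repeller).
#'
#' @param L_frac Stick length as a fraction of the environment width, in
#'   `(0, 1]`. Default 0.49.
#' @param env_width Width of the simulation environment (length units).
#'   Default 4.162 (see Details).
#' @param g Gravitational acceleration (length/time^2). Default 9.8.
#' @param m Stick mass. Default 1.
#' @param gamma Damping coefficient \eqn{\gamma} (per time). Default 0.5.
#' @param R0 Constant part of the feedback gain. Default 5.
#' @param sigma Noise amplitude of the gain perturbation \eqn{\xi(t)}
#'   (interpreted per `integrator_config()`'s `sigma_as`). Default 10.
#' @param tau_steps Feedback delay \eqn{\tau} expressed as an integer
#'   number of integration steps. Default 10 (0.1 time units at the
#'   default `dt = 0.01`).
#' @param theta0 Initial vertical displacement angle (radians).
#'   Default 0.06.
#'
#' @return An object of class `stick_params`.
#' @seealso [integrator_config()], [integrate_stick()]
#' @examples
#' p <- stick_params()
#' p$g / stick_length(p)   # gravitational stiffness g/L
#' @export
stick_params <- function(L_frac = 0.49, env_width = 4.162, g = 9.8, m = 1,
                         gamma = 0.5, R0 = 5, sigma = 10, tau_steps = 10,
                         theta0 = 0.06) {
  stopifnot(
    "L_frac must be in (0, 1]" = is.numeric(L_frac) && length(L_frac) == 1 &&
      L_frac > 0 && L_frac <= 1,
    "env_width must be > 0" = is.numeric(env_width) && env_width > 0,
    "g must be > 0" = is.numeric(g) && g > 0,
    "m must be > 0" = is.numeric(m) && m > 0,
    "gamma must be >= 0" = is.numeric(gamma) && gamma >= 0,
    "R0 must be a finite number" = is.numeric(R0) && is.finite(R0),
    "sigma must be >= 0" = is.numeric(sigma) && sigma >= 0,
    "tau_steps must be a non-negative integer" =
      is.numeric(tau_steps) && tau_steps >= 0 && tau_steps == round(tau_steps),
    "theta0 must be a finite number" = is.numeric(theta0) && is.finite(theta0)
  )
  structure(
    list(L_frac = L_frac, env_width = env_width, g = g, m = m, gamma = gamma,
         R0 = R0, sigma = sigma, tau_steps = as.integer(tau_steps),
         theta0 = theta0),
    class = "stick_params"
  )
}

#' @describeIn stick_params Physical stick length `L = L_frac * env_width`.
#' @param params A `stick_params` object.
#' @export
stick_length <- function(params) {
  stopifnot(inherits(params, "stick_params"))
  params$L_frac * params$env_width
}

#' @export
print.stick_params <- function(x, ...) {
  cat("Stick-balancing parameters\n")
  cat(sprintf("  L = %.4f (%.0f%% of env width %.3f), g/L = %.4f\n",
              stick_length(x), 100 * x$L_frac, x$env_width,
              x$g / stick_length(x)))
  cat(sprintf("  gamma = %g, m = %g, R0 = %g, sigma = %g\n",
              x$gamma, x$m, x$R0, x$sigma))
  cat(sprintf("  tau = %d steps, theta(0) = %g\n", x$tau_steps, x$theta0))
  invisible(x)
}

#' Numerical settings for the stick integrator
#'
#' @param dt Integration step size (time units). Default 0.01; the delay
#'   `tau_steps` in [stick_params()] is counted in these steps.
#' @param t_max_steps Maximum number of integration steps. Default 1e5.
#' @param fall_angle `|theta|` threshold (radians) at which the stick is
#'   declared fallen. Default `pi/2`.
#' @param seed Integer seed for the per-step noise draws.
#' @param sigma_as How to interpret the `sigma` field of [stick_params()]:
#'   `"sd"` (default) treats it as the standard deviation of the per-step
#'   gain perturbation, `"variance"` as its variance (standard deviation
#'   `sqrt(sigma)`).
#' @param noise_scaling `"per-step"` (default) holds each noise draw
#'   constant over the step with no step-size rescaling; `"sqrt-dt"`
#'   applies Euler--Maruyama scaling (effective per-step standard
#'   deviation `sd/sqrt(dt)`), making the noise intensity step-size
#'   invariant in the white-noise limit.
#'
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.01, t_max_steps = 100000L,
                              fall_angle = pi / 2, seed = 1L,
                              sigma_as = c("sd", "variance"),
                              noise_scaling = c("per-step", "sqrt-dt")) {
  sigma_as <- match.arg(sigma_as)
  noise_scaling <- match.arg(noise_scaling)
  stopifnot(
    "dt must be > 0" = is.numeric(dt) && length(dt) == 1 && dt > 0,
    "t_max_steps must be a positive integer" =
      is.numeric(t_max_steps) && t_max_steps >= 1 &&
      t_max_steps == round(t_max_steps),
    "fall_angle must be in (0, pi]" =
      is.numeric(fall_angle) && fall_angle > 0 && fall_angle <= pi,
    "seed must be a single integer" =
      is.numeric(seed) && length(seed) == 1 && seed == round(seed)
  )
  structure(
    list(dt = dt, t_max_steps = as.integer(t_max_steps),
         fall_angle = fall_angle, seed = as.integer(seed),
         sigma_as = sigma_as, noise_scaling = noise_scaling),
    class = "integrator_config"
  )
}

#' @export
print.integrator_config <- function(x, ...) {
  cat(sprintf(
    "Integrator config: dt = %g, horizon = %d steps, fall at |theta| >= %.4f\n",
    x$dt, x$t_max_steps, x$fall_angle))
  cat(sprintf("  seed = %d, sigma as %s, noise scaling %s\n",
              x$seed, x$sigma_as, x$noise_scaling))
  invisible(x)
}

# effective per-step standard deviation of the gain noise
noise_sd_effective <- function(params, config) {
  sd <- if (config$sigma_as == "variance") sqrt(params$sigma) else params$sigma
  if (config$noise_scaling == "sqrt-dt") sd <- sd / sqrt(config$dt)
  sd
}
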