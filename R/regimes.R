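#' Classify the phase-space regime of a trajectory
#'
#' Labels a trajectory with one of the three behaviors seen in the
#' noise-free parametric study of the delayed-feedback pendulum:
#' \describe{
#'   \item{REPELLER}{the stick falls after fewer than two oscillations —
#'     direct escape from the upright state.}
#'   \item{SPIRAL_NODE}{the stick survives to the horizon with oscillatory
#'     decay: at least two sign changes of \eqn{\theta - \theta^*} and a
#'     negative envelope slope.}
#'   \item{SPIRAL_REPELLER}{the stick falls after at least two
#'     oscillations with a growing envelope.}
#'   \item{UNDETERMINED}{mixed evidence (e.g., survival without a
#'     detectable oscillation trend), or fewer than 10 samples.}
#' }
#' The reference angle \eqn{\theta^*} is 0 for fallen trajectories and
#' the mean of the final quarter for surviving ones (the equilibrium
#' approached need not be the initial point). The envelope slope is the
#' least-squares slope of `log |peak amplitude|` over successive local
#' maxima of \eqn{|\theta - \theta^*|}; at least two peaks are required.
#' One full oscillation counts two sign changes.
#'
#' @param trajectory A `stick_trajectory`.
#' @return An object of class `regime_label`: `label` plus an `evidence`
#'   list (survival time, sign changes, oscillations, envelope slope,
#'   number of peaks).
#' @export
classify_regime <- function(trajectory) {
  stopifnot(inherits(trajectory, "stick_trajectory"))
  n <- length(trajectory$theta)
  if (n < 10) {
    return(regime_label("UNDETERMINED",
                        list(survival_time = trajectory$t[n],
                             diagnostic = "trajectory too short")))
  }
  fell <- trajectory$fell
  theta_star <- if (fell) 0 else {
    mean(trajectory$theta[seq.int(ceiling(3 * n / 4), n)])
  }
  x <- trajectory$theta - theta_star
  sgn <- sign(x)
  sgn <- sgn[sgn != 0]
  sign_changes <- sum(diff(sgn) != 0)
  oscillations <- sign_changes / 2

  ax <- abs(x)
  peak_idx <- which(ax[-c(1, n)] >= ax[-c(n - 1, n)] &
                      ax[-c(1, n)] > ax[-c(1, 2)]) + 1
  peak_idx <- peak_idx[ax[peak_idx] > 0]
  env_slope <- NA_real_
  if (length(peak_idx) >= 2) {
    env_slope <- unname(stats::coef(stats::lm(
      log(ax[peak_idx]) ~ trajectory$t[peak_idx]))[2])
  }
  evidence <- list(survival_time = trajectory$t[n],
                   fell = fell,
                   sign_changes = sign_changes,
                   oscillations = oscillations,
                   envelope_slope = env_slope,
                   n_peaks = length(peak_idx))
  label <- if (fell) {
    if (oscillations < 2) "REPELLER"
    else if (!is.na(env_slope) && env_slope > 0) "SPIRAL_REPELLER"
    else "UNDETERMINED"
  } else {
    if (sign_changes >= 2 && !is.na(env_slope) && env_slope < 0)
      "SPIRAL_NODE"
    else "UNDETERMINED"
  }
  regime_label(label, evidence)
}

regime_label <- function(label, evidence) {
  stopifnot(label %in% c("REPELLER", "SPIRAL_NODE", "SPIRAL_REPELLER",
                         "UNDETERMINED"))
  structure(list(label = label, evidence = evidence),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s (survival %.4g, %d sign changes, envelope slope %.3g)\n",
              x$label, x$evidence$survival_time,
              x$evidence$sign_changes %||% NA,
              x$evidence$envelope_slope %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chebyshev differentiation matrix on N+1 points of [-1, 1]
# (nodes cos(j pi / N), j = 0..N, so x[1] = 1, x[N+1] = -1)
cheb_diff <- function(N) {
  x <- cos(pi * (0:N) / N)
  c_ <- c(2, rep(1, N - 1), 2) * (-1)^(0:N)
  X <- matrix(x, N + 1, N + 1)
  dX <- X - t(X)
  D <- (c_ %o% (1 / c_)) / (dX + diag(N + 1))
  D - diag(rowSums(D))
}

stick_char_fn <- function(params, dt) {
  gl <- params$g / stick_length(params)
  gm <- params$gamma / params$m
  tau <- params$tau_steps * dt
  R0 <- params$R0
  list(
    f = function(l) l^2 + gm * l - gl + R0 * exp(-l * tau),
    df = function(l) 2 * l + gm - R0 * tau * exp(-l * tau),
    gl = gl, gm = gm, tau = tau, R0 = R0
  )
}

#' Rightmost characteristic root of the linearized noise-free model
#'
#' Linearizing the noise-free delay equation about the upright state
#' (\eqn{\sin\theta \to \theta}, \eqn{\sigma = 0}) gives the
#' characteristic equation
#' \deqn{\lambda^2 + (\gamma/m)\lambda - g/L + R_0 e^{-\lambda\tau} = 0.}
#' The root of maximal real part decides linear stability:
#' `Re(lambda) < 0` iff the upright state is asymptotically stable. Roots
#' are seeded by the eigenvalues of a pseudospectral (Chebyshev
#' collocation) discretization of the delay operator and polished by
#' Newton iteration on the exact characteristic function, so the answer
#' is accurate to near machine precision.
#'
#' @param params A [stick_params()] object; `sigma` is ignored (treated
#'   as 0) and the delay is `tau_steps * dt` time units.
#' @param dt Step size defining the delay in time units. Default 0.01.
#' @param order Collocation order of the seeding discretization.
#'   Default 64.
#' @return A single complex number, the rightmost root.
#' @examples
#' p <- stick_params(R0 = 5, tau_steps = 10)
#' Re(rightmost_root(p))  # < 0: linearly stable at the operating point
#' @export
rightmost_root <- function(params, dt = 0.01, order = 64) {
  stopifnot(inherits(params, "stick_params"), dt > 0, order >= 8)
  ch <- stick_char_fn(params, dt)
  # no delay term in play: exact quadratic
  if (ch$tau == 0 || ch$R0 == 0) {
    disc <- sqrt(as.complex(ch$gm^2 - 4 * (ch$R0 * (ch$tau == 0) - ch$gl)))
    roots <- c(-ch$gm + disc, -ch$gm - disc) / 2
    return(roots[which.max(Re(roots))])
  }
  N <- as.integer(order)
  # collocation of x'(t) = L0 x(t) + L1 x(t - tau) on [-tau, 0]
  D <- cheb_diff(N) * (2 / ch$tau)  # nodes run from t = 0 down to t = -tau
  I2 <- diag(2)
  M <- kronecker(D, I2)
  L0 <- matrix(c(0, ch$gl, 1, -ch$gm), 2, 2)
  L1 <- matrix(c(0, -ch$R0, 0, 0), 2, 2)
  M[1:2, ] <- 0
  M[1:2, 1:2] <- L0
  M[1:2, (2 * N + 1):(2 * N + 2)] <- M[1:2, (2 * N + 1):(2 * N + 2)] + L1
  ev <- eigen(M, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  cand <- utils::head(ev[Re(ev) > max(Re(ev)) - 5], 24)

  polished <- c()
  for (l0 in cand) {
    l <- l0
    ok <- FALSE
    for (it in 1:60) {
      step <- ch$f(l) / ch$df(l)
      if (!is.finite(Re(step)) || !is.finite(Im(step))) break
      l <- l - step
      if (Mod(step) < 1e-13 * max(1, Mod(l))) { ok <- TRUE; break }
    }
    if (ok && Mod(ch$f(l)) < 1e-8) polished <- c(polished, l)
  }
  if (length(polished) == 0) {
    stop(sprintf(
      "rightmost_root: Newton polishing failed at R0 = %g, tau = %g",
      ch$R0, ch$tau))
  }
  polished[which.max(Re(polished))]
}

#' Locate the critical feedback gain by bisection on simulations
#'
#' Bisects on `R0` with the noise-free fall/survive criterion at the fixed
#' horizon `config$t_max_steps`: below the critical gain \eqn{R_0^*} the
#' stick falls, above it the trajectory survives to the horizon. The
#' bracket must straddle the transition.
#'
#' Because the pendulum is nonlinear, feedback gains slightly below the
#' fold `g/L` do not topple the stick all the way over: it settles into a
#' stable tilted equilibrium \eqn{(g/L)\sin\theta^* = R_0\theta^*} whose
#' tilt grows as the gain drops. The bifurcation analysis therefore uses
#' a departure-from-upright criterion — the stick has "fallen" once
#' \eqn{|\theta|} leaves a narrow cone (default 0.15 rad) around vertical
#' — so the measured threshold tracks the loss of stability of the
#' upright state itself. (The default physical fall angle \eqn{\pi/2} of
#' [integrator_config()] would instead measure where the *tilted*
#' equilibria pass \eqn{\pi/2}, several percent below the fold.)
#'
#' @param tau_steps Delay in integration steps.
#' @param bracket Numeric `c(low, high)` bracket for `R0`.
#' @param tol Bisection tolerance on `R0` (final bracket width).
#'   Default 1e-5.
#' @param params Template [stick_params()]; `sigma` is forced to 0 and
#'   `R0`/`tau_steps` are overridden during the search.
#' @param config An [integrator_config()]; its horizon, step size and
#'   fall angle define the operational meaning of "falls" vs "never
#'   falls". Defaults to the departure-from-upright criterion
#'   (`fall_angle = 0.15`).
#' @return An object of class `threshold_result`: `tau_steps`, `R0_star`
#'   (bracket midpoint), final `bracket`, `tol`, `criterion`,
#'   `iterations`.
#' @export
find_critical_R0 <- function(tau_steps, bracket, tol = 1e-5,
                             params = stick_params(),
                             config = integrator_config(fall_angle = 0.15)) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2], tol > 0)
  falls_at <- function(R0) {
    p <- stick_params(L_frac = params$L_frac, env_width = params$env_width,
                      g = params$g, m = params$m, gamma = params$gamma,
                      R0 = R0, sigma = 0, tau_steps = tau_steps,
                      theta0 = params$theta0)
    integrate_stick(p, config)$fell
  }
  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- falls_at(lo)
  f_hi <- falls_at(hi)
  if (f_lo == f_hi) {
    stop(sprintf(
      "bracket (%g, %g) does not straddle the fall/survive transition (both %s)",
      lo, hi, if (f_lo) "fall" else "survive"))
  }
  it <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (falls_at(mid) == f_lo) lo <- mid else hi <- mid
    it <- it + 1
  }
  structure(
    list(tau_steps = as.integer(tau_steps), R0_star = (lo + hi) / 2,
         bracket = c(lo, hi), tol = tol,
         criterion = sprintf(
           "noise-free fall before vs survival to %d steps of dt = %g, |theta| >= %g",
           config$t_max_steps, config$dt, config$fall_angle),
         iterations = it),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "Critical gain at tau = %d steps: R0* = %.6f (bracket [%.6f, %.6f], %d bisections)\n",
    x$tau_steps, x$R0_star, x$bracket[1], x$bracket[2], x$iterations))
  invisible(x)
}

#' Write a threshold result as JSON
#' @param threshold A `threshold_result`.
#' @param path Output path.
#' @export
write_threshold_json <- function(threshold, path) {
  stopifnot(inherits(threshold, "threshold_result"))
  jsonlite::write_json(unclass(threshold), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Sweep regimes over a (tau, R0) grid
#'
#' Classifies every grid point with [classify_regime()]. For `sigma > 0`
#' single runs are ambiguous, so each point takes the majority label over
#' `n_runs_vote` independent runs (ties resolve to `UNDETERMINED`).
#'
#' @param tau_grid Integer vector of delays (steps), non-empty.
#' @param R0_grid Numeric vector of feedback gains, non-empty.
#' @param sigma Noise amplitude used everywhere in the sweep.
#' @param params Template [stick_params()] for the constants not swept.
#' @param config An [integrator_config()]; per-cell seeds derive from
#'   `config$seed` so the sweep is reproducible.
#' @param n_runs_vote Runs per cell when `sigma > 0`. Default 5.
#' @return An object of class `regime_map`: `tau_grid`, `R0_grid`,
#'   `sigma`, `labels` (matrix `|tau| x |R0|`) and `survival` (matrix of
#'   mean survival times).
#' @export
sweep_regimes <- function(tau_grid, R0_grid, sigma = 0,
                          params = stick_params(),
                          config = integrator_config(), n_runs_vote = 5) {
  if (length(tau_grid) == 0 || length(R0_grid) == 0) {
    stop("tau_grid and R0_grid must be non-empty")
  }
  labels <- matrix(NA_character_, length(tau_grid), length(R0_grid),
                   dimnames = list(paste0("tau", tau_grid),
                                   paste0("R0_", R0_grid)))
  survival <- labels
  storage.mode(survival) <- "double"
  cell <- 0L
  for (i in seq_along(tau_grid)) {
    for (j in seq_along(R0_grid)) {
      cell <- cell + 1L
      p <- stick_params(L_frac = params$L_frac,
                        env_width = params$env_width, g = params$g,
                        m = params$m, gamma = params$gamma,
                        R0 = R0_grid[j], sigma = sigma,
                        tau_steps = tau_grid[i], theta0 = params$theta0)
      n_runs <- if (sigma > 0) n_runs_vote else 1
      cfg <- config
      cfg$seed <- derive_run_seed(config$seed, cell * 1000L)
      runs <- run_ensemble(p, cfg, n_runs)
      labs <- vapply(runs, function(r) classify_regime(r)$label, "")
      tab <- sort(table(labs), decreasing = TRUE)
      labels[i, j] <- if (length(tab) > 1 && tab[1] == tab[2])
        "UNDETERMINED" else names(tab)[1]
      survival[i, j] <- mean(vapply(runs, function(r) r$t[length(r$t)], 0))
    }
  }
  structure(
    list(tau_grid = tau_grid, R0_grid = R0_grid, sigma = sigma,
         labels = labels, survival = survival),
    class = "regime_map"
  )
}

#' @export
print.regime_map <- function(x, ...) {
  cat(sprintf("Regime map: %d tau x %d R0 grid at sigma = %g\n",
              length(x$tau_grid), length(x$R0_grid), x$sigma))
  print(x$labels)
  invisible(x)
}

#' Write a regime map as long-format CSV
#'
#' Columns `tau,R0,sigma,label,survival_time`, one row per grid cell.
#'
#' @param map A `regime_map`.
#' @param path Output path.
#' @export
write_regime_map_csv <- function(map, path) {
  stopifnot(inherits(map, "regime_map"))
  long <- expand.grid(tau = map$tau_grid, R0 = map$R0_grid,
                      KEEP.OUT.ATTRS = FALSE)
  long$sigma <- map$sigma
  long$label <- mapply(function(i, j) map$labels[i, j],
                       match(long$tau, map$tau_grid),
                       match(long$R0, map$R0_grid))
  long$survival_time <- mapply(function(i, j) map$survival[i, j],
                               match(long$tau, map$tau_grid),
                               match(long$R0, map$R0_grid))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
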