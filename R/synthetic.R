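#' GARCH(1,1) parameters
#'
#' The minimal conditional-heteroskedasticity generator showing both
#' stylized facts the pipeline must detect: fat tails and volatility
#' clustering with uncorrelated raw returns. The variance recursion is
#' \eqn{h_t = \omega + \alpha r_{t-1}^2 + \beta h_{t-1}}, with
#' unconditional variance \eqn{\omega / (1 - \alpha - \beta)}.
#'
#' @param omega Baseline variance, `> 0`. Default 0.1.
#' @param alpha ARCH coefficient, `>= 0`. Default 0.1.
#' @param beta GARCH coefficient, `>= 0`. Default 0.8.
#' @param nu Degrees of freedom of Student-t innovations (`> 2`), or
#'   `Inf` (default) for normal innovations; `nu = 4` fattens the tails.
#' @return An object of class `garch_params`.
#' @export
garch_params <- function(omega = 0.1, alpha = 0.1, beta = 0.8, nu = Inf) {
  stopifnot(omega > 0, alpha >= 0, beta >= 0, nu > 2)
  if (alpha + beta >= 1) {
    stop("alpha + beta must be < 1 for covariance stationarity; got ",
         alpha + beta)
  }
  structure(list(omega = omega, alpha = alpha, beta = beta, nu = nu),
            class = "garch_params")
}

#' Generate a GARCH(1,1) return series
#'
#' \eqn{r_t = \sqrt{h_t}\, z_t} with
#' \eqn{h_t = \omega + \alpha r_{t-1}^2 + \beta h_{t-1}} and unit-variance
#' i.i.d. innovations (normal, or scaled Student-t with `nu` degrees of
#' freedom). The recursion starts at the unconditional variance and a
#' burn-in is discarded so the retained sample is stationary.
#'
#' @param params A [garch_params()] object.
#' @param n Retained series length, `>= 1`.
#' @param seed Integer seed; output is deterministic given `seed`.
#' @param burn_in Steps discarded before recording. Default 1000.
#' @return A [returns_series()] with `source = "synthetic"`.
#' @export
generate_garch <- function(params, n, seed = 1L, burn_in = 1000L) {
  stopifnot(inherits(params, "garch_params"), n >= 1, burn_in >= 0)
  set.seed(seed)
  total <- n + burn_in
  z <- if (is.infinite(params$nu)) {
    stats::rnorm(total)
  } else {
    stats::rt(total, df = params$nu) * sqrt((params$nu - 2) / params$nu)
  }
  h <- params$omega / (1 - params$alpha - params$beta)
  r <- numeric(total)
  r[1] <- sqrt(h) * z[1]
  for (t in 2:total) {
    h <- params$omega + params$alpha * r[t - 1]^2 + params$beta * h
    r[t] <- sqrt(h) * z[t]
  }
  returns_series(r[(burn_in + 1):total], source = "synthetic")
}

#' Generate an i.i.d. standard-normal return series
#'
#' The null model against which the stylized-fact flags are calibrated:
#' no fat tails, no autocorrelation, no volatility clustering.
#'
#' @param n Series length, `>= 1`.
#' @param seed Integer seed.
#' @return A [returns_series()] with `source = "synthetic"`.
#' @export
generate_iid_gaussian <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  returns_series(stats::rnorm(n), source = "synthetic")
}
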