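#' A one-dimensional return series
#'
#' Light container shared by simulated angular-velocity returns, financial
#' log returns and synthetic generator output, carrying normalization
#' metadata so pooled comparisons are traceable.
#'
#' @param values Numeric vector of finite return values.
#' @param source One of `"simulated"`, `"financial"`, `"synthetic"`.
#' @param normalized Has a z-score normalization been applied?
#' @param norm_mean,norm_sd The normalization constants applied (the mean
#'   subtracted and the standard deviation divided by), `NA` if none.
#' @return An object of class `returns_series`.
#' @export
returns_series <- function(values, source = c("simulated", "financial",
                                              "synthetic"),
                           normalized = FALSE, norm_mean = NA_real_,
                           norm_sd = NA_real_) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("returns_series values must all be finite")
  }
  structure(
    list(values = values, source = source, normalized = normalized,
         norm_mean = norm_mean, norm_sd = norm_sd),
    class = "returns_series"
  )
}

#' @export
print.returns_series <- function(x, ...) {
  cat(sprintf("Returns series (%s): n = %d%s\n", x$source, length(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Angular-velocity returns of a stick trajectory
#'
#' The simulation's analogue of a price return: the one-step difference
#' of the angular velocity, `omega[i+1] - omega[i]`.
#'
#' @param trajectory A `stick_trajectory` with at least 2 samples.
#' @return An unnormalized [returns_series()] of length
#'   `length(omega) - 1` with `source = "simulated"`.
#' @export
velocity_returns <- function(trajectory) {
  stopifnot(inherits(trajectory, "stick_trajectory"))
  if (length(trajectory$omega) < 2) {
    stop("trajectory must have at least 2 samples to form returns")
  }
  returns_series(diff(trajectory$omega), source = "simulated")
}

#' Pool return series and z-score the pooled sample
#'
#' Concatenates the series and applies a single z-score normalization to
#' the pooled values (per-series pre-normalization is deliberately not
#' applied; every series enters on its native scale, as when returns from
#' repeated runs of one experiment are cumulated).
#'
#' @param series_list A list of [returns_series()] objects (a single
#'   `returns_series` is accepted), each with positive standard deviation.
#' @return A normalized `returns_series`; the source is inherited when
#'   unique across inputs, otherwise the first series' source.
#' @export
normalize_and_pool <- function(series_list) {
  if (inherits(series_list, "returns_series")) {
    series_list <- list(series_list)
  }
  stopifnot(length(series_list) >= 1,
            all(vapply(series_list, inherits, TRUE, "returns_series")))
  for (i in seq_along(series_list)) {
    if (stats::sd(series_list[[i]]$values) <= 0) {
      stop("series ", i, " has zero variance and cannot be normalized")
    }
  }
  pooled <- unlist(lapply(series_list, `[[`, "values"), use.names = FALSE)
  m <- mean(pooled)
  s <- stats::sd(pooled)
  src <- unique(vapply(series_list, `[[`, "", "source"))
  returns_series((pooled - m) / s,
                 source = if (length(src) == 1) src else src[1],
                 normalized = TRUE, norm_mean = m, norm_sd = s)
}

#' Empirical probability density of a return series
#'
#' Histogram density on `n_bins` equally spaced bins over a symmetric
#' range of `span_sds` reference scales either side of the sample median.
#' The reference scale is `min(sd, 3 * mad)`: for Gaussian-like data this
#' equals the standard deviation, while for very heavy-tailed samples
#' (whose sample SD is dominated by a few extreme draws and can exceed the
#' core width by many orders of magnitude) the MAD cap keeps the histogram
#' resolved around the body of the distribution. Densities are normalized
#' by the total sample size, so they integrate to one minus the
#' out-of-range fraction, which is reported.
#'
#' @param series A [returns_series()] with at least 100 values.
#' @param n_bins Odd number of bins (the central bin sits on the median).
#'   Default 61.
#' @param span_sds Half-range in reference-scale units. Default 10.
#' @return An object of class `empirical_pdf`: `bin_centers`, `density`,
#'   `counts`, `bin_width`, `n_samples`, `out_of_range` (fraction of
#'   samples beyond the binned range), `center` and `scale` used.
#' @export
empirical_pdf <- function(series, n_bins = 61, span_sds = 10) {
  stopifnot(inherits(series, "returns_series"))
  x <- series$values
  if (length(x) < 100) stop("need at least 100 samples; got ", length(x))
  if (n_bins %% 2 != 1 || n_bins < 3) {
    stop("n_bins must be an odd integer >= 3")
  }
  stopifnot(span_sds > 0)
  s_sd <- stats::sd(x)
  if (s_sd <= 0) stop("degenerate series: zero variance")
  ctr <- stats::median(x)
  s <- min(s_sd, 3 * stats::mad(x, center = ctr))
  if (s <= 0) s <- s_sd
  breaks <- ctr + seq(-span_sds * s, span_sds * s, length.out = n_bins + 1)
  inside <- x >= breaks[1] & x <= breaks[n_bins + 1]
  h <- graphics::hist(x[inside], breaks = breaks, plot = FALSE)
  w <- breaks[2] - breaks[1]
  structure(
    list(bin_centers = h$mids,
         density = h$counts / (length(x) * w),
         counts = h$counts,
         bin_width = w,
         n_samples = length(x),
         out_of_range = 1 - sum(inside) / length(x),
         center = ctr, scale = s),
    class = "empirical_pdf"
  )
}

#' @export
print.empirical_pdf <- function(x, ...) {
  cat(sprintf(
    "Empirical PDF: %d bins of width %.4g over [%.4g, %.4g], n = %d (%.2f%% out of range)\n",
    length(x$bin_centers), x$bin_width,
    x$bin_centers[1] - x$bin_width / 2,
    x$bin_centers[length(x$bin_centers)] + x$bin_width / 2,
    x$n_samples, 100 * x$out_of_range))
  invisible(x)
}

#' Sample autocorrelation of raw or absolute returns
#'
#' Standard sample autocorrelation
#' \eqn{\rho(k) = \sum (x_t-\bar x)(x_{t+k}-\bar x) / \sum (x_t-\bar x)^2}
#' of the series or of its absolute values. The absolute-return ACF is the
#' standard diagnostic for volatility clustering: persistent positive
#' values mean large magnitudes follow large magnitudes.
#'
#' @param series A [returns_series()].
#' @param max_lag Largest lag, `1 <= max_lag < length(series)`.
#'   Default 100.
#' @param absolute Apply `abs()` before computing? Default `FALSE`.
#' @return An object of class `acf_result`: `lags` (0..`max_lag`), `rho`,
#'   `absolute`, `n`.
#' @export
acf_returns <- function(series, max_lag = 100, absolute = FALSE) {
  stopifnot(inherits(series, "returns_series"),
            max_lag >= 1, max_lag == round(max_lag))
  x <- series$values
  if (length(x) <= max_lag) {
    stop("series length (", length(x), ") must exceed max_lag (",
         max_lag, ")")
  }
  if (absolute) x <- abs(x)
  if (stats::var(x) == 0) {
    stop("zero variance after ",
         if (absolute) "taking absolute values" else "no transform",
         "; autocorrelation undefined")
  }
  rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)
  structure(
    list(lags = 0:max_lag, rho = rho, absolute = absolute, n = length(x)),
    class = "acf_result"
  )
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("ACF of %s returns, lags 0..%d (n = %d)\n",
              if (x$absolute) "absolute" else "raw",
              max(x$lags), x$n))
  invisible(x)
}

#' Excess kurtosis of a return series
#'
#' Population-moment estimate `mean((x - m)^4) / var^2 - 3`; zero for a
#' Gaussian, positive for fat-tailed series.
#'
#' @param series A [returns_series()] or numeric vector.
#' @return A single number.
#' @export
excess_kurtosis <- function(series) {
  x <- if (inherits(series, "returns_series")) series$values else series
  m <- mean(x)
  v <- mean((x - m)^2)
  mean((x - m)^4) / v^2 - 3
}

#' @describeIn empirical_pdf Write the PDF as a two-column `x,density` CSV.
#' @param pdf An `empirical_pdf`.
#' @param path Output path.
#' @export
write_pdf_csv <- function(pdf, path) {
  stopifnot(inherits(pdf, "empirical_pdf"))
  utils::write.csv(data.frame(x = pdf$bin_centers, density = pdf$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' @describeIn acf_returns Write the ACF as a two-column `lag,rho` CSV.
#' @param acf_result An `acf_result`.
#' @param path Output path.
#' @export
write_acf_csv <- function(acf_result, path) {
  stopifnot(inherits(acf_result, "acf_result"))
  utils::write.csv(data.frame(lag = acf_result$lags, rho = acf_result$rho),
                   path, row.names = FALSE)
  invisible(path)
}
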