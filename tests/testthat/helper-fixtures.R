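# shared fixtures, built in code at test time

# pooled, z-scored angular-velocity returns at the calibrated operating
# point (tau = 10 steps, R0 = 5, sigma = 10, L = 49%), cached per seed
# so several tests can share one ensemble
.pooled_cache <- new.env(parent = emptyenv())
calibrated_pooled <- function(seed, n_runs = 20) {
  key <- paste0("s", seed, "_n", n_runs)
  if (is.null(.pooled_cache[[key]])) {
    runs <- run_ensemble(stick_params(), integrator_config(seed = seed),
                         n_runs)
    .pooled_cache[[key]] <- normalize_and_pool(
      lapply(runs, velocity_returns))
  }
  .pooled_cache[[key]]
}

# minimal trajectory stub for return-definition tests
fake_trajectory <- function(omega) {
  structure(list(t = seq_along(omega) - 1, theta = numeric(length(omega)),
                 omega = omega, fell = FALSE, fall_time = NA_real_),
            class = "stick_trajectory")
}

# write a small price CSV and return its path
write_price_fixture <- function(dates, close, dir = NULL,
                                name = "prices.csv",
                                header = c("Date", "Close")) {
  path <- if (is.null(dir)) tempfile(fileext = ".csv")
          else file.path(dir, name)
  df <- data.frame(a = dates, b = close)
  names(df) <- header
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

g_over_L <- function(params = stick_params()) {
  params$g / stick_length(params)
}
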