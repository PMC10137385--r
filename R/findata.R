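#' Read a daily close-price series from a CSV file
#'
#' Reads Yahoo-Finance-style CSV files with a date column and a closing
#' price column. Rows with missing or non-positive close are dropped (with
#' a message giving the count), dates are parsed as ISO-8601
#' (`yyyy-mm-dd`) or `dd/mm/yyyy` (whichever format matches more rows),
#' out-of-order rows are sorted ascending with a warning, and duplicate
#' dates are rejected.
#'
#' @param path CSV file with a header row.
#' @param name Series identifier (e.g., a ticker); defaults to the file
#'   name without extension.
#' @param date_col,close_col Header names of the date and closing-price
#'   columns. Defaults `"Date"`, `"Close"`.
#' @return An object of class `price_series`: `name`, `dates` (strictly
#'   increasing `Date` vector), `close` (positive prices).
#' @export
read_price_csv <- function(path, name = NULL, date_col = "Date",
                           close_col = "Close") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(date_col, close_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s (columns: %s)",
                   col, path, paste(names(df), collapse = ", ")))
    }
  }
  raw_dates <- as.character(df[[date_col]])
  iso <- as.Date(raw_dates, format = "%Y-%m-%d")
  dmy <- as.Date(raw_dates, format = "%d/%m/%Y")
  dates <- if (sum(!is.na(iso)) >= sum(!is.na(dmy))) iso else dmy
  close <- suppressWarnings(as.numeric(df[[close_col]]))

  usable <- !is.na(dates) & !is.na(close) & close > 0
  dropped <- sum(!usable)
  if (dropped > 0) {
    message(sprintf("%s: dropped %d row(s) with missing/unparsable/non-positive values",
                    name, dropped))
  }
  dates <- dates[usable]
  close <- close[usable]
  if (length(dates) == 0) stop("no usable rows in ", path)
  if (anyDuplicated(dates)) {
    stop("duplicate dates in ", path, ": ",
         paste(utils::head(dates[duplicated(dates)], 3), collapse = ", "))
  }
  if (is.unsorted(dates)) {
    warning(name, ": rows out of date order; sorting ascending")
    o <- order(dates)
    dates <- dates[o]
    close <- close[o]
  }
  structure(list(name = name, dates = dates, close = close),
            class = "price_series")
}

#' @export
print.price_series <- function(x, ...) {
  cat(sprintf("Price series '%s': %d trading days, %s to %s\n",
              x$name, length(x$close), x$dates[1],
              x$dates[length(x$dates)]))
  invisible(x)
}

#' Daily log returns of a price series
#'
#' \eqn{r_t = \ln(\mathrm{close}_t) - \ln(\mathrm{close}_{t-1})} over
#' consecutive rows; non-trading gaps (weekends, holidays) are ignored,
#' as is conventional for daily data.
#'
#' @param series A [read_price_csv()] result with at least 2 prices.
#' @return An unnormalized [returns_series()] of length `n - 1` with
#'   `source = "financial"`.
#' @export
price_to_returns <- function(series) {
  stopifnot(inherits(series, "price_series"))
  if (length(series$close) < 2) {
    stop("need at least 2 prices to form returns")
  }
  if (any(series$close <= 0)) stop("non-positive price in series")
  returns_series(diff(log(series$close)), source = "financial")
}
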