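#' Uniformly sampled time series
#'
#' Light container pairing a numeric signal with its sampling rate. All
#' estimators in the package accept either a plain numeric vector (when the
#' sampling rate is irrelevant, e.g. for scaling exponents) or an `mf_ts`.
#'
#' @param values numeric vector of finite sample values.
#' @param fs sampling rate in Hz (positive).
#' @return An object of class `mf_ts`: a list with elements `values` and `fs`.
#' @examples
#' x <- mf_ts(sin(2 * pi * 10 * (0:999) / 250), fs = 250)
#' x
#' @export
mf_ts <- function(values, fs) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("'values' must be non-empty")
  if (!all(is.finite(values))) stop("'values' must all be finite")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  structure(list(values = values, fs = fs), class = "mf_ts")
}

#' @export
print.mf_ts <- function(x, ...) {
  cat(sprintf("<mf_ts> %d samples @ %g Hz (%.3f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' @export
plot.mf_ts <- function(x, ...) {
  t <- seq_along(x$values) / x$fs
  graphics::plot(t, x$values, type = "l", xlab = "time [s]",
                 ylab = "amplitude", ...)
  invisible(x)
}

# Accept numeric or mf_ts; return plain numeric values.
ts_values <- function(x) {
  if (inherits(x, "mf_ts")) x$values else as.numeric(x)
}

# Sampling rate of x, falling back to `fs` for plain vectors.
ts_fs <- function(x, fs = NULL) {
  if (inherits(x, "mf_ts")) return(x$fs)
  if (is.null(fs)) stop("sampling rate 'fs' required for plain numeric input")
  fs
}

#' Read / write single- or multi-channel time-series CSV
#'
#' The on-disk format is a first line `fs=<Hz>` followed by one row per
#' sample; multi-channel recordings use one comma-separated column per
#' channel. Values round-trip exactly (written with full precision).
#'
#' @param path file path.
#' @return `read_timeseries_csv`: an `mf_ts` for single-channel files, or a
#'   list of `mf_ts` (one per channel) for multi-channel files.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("^fs=([0-9.eE+-]+)$", trimws(header)))[[1]]
  if (length(m) != 2) stop("malformed header: expected 'fs=<Hz>', got ", header)
  fs <- as.numeric(m[2])
  dat <- utils::read.csv(path, skip = 1, header = FALSE)
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    stop("non-numeric sample values in ", path)
  }
  if (ncol(dat) == 1) return(mf_ts(dat[[1]], fs))
  lapply(dat, mf_ts, fs = fs)
}

#' @param x an `mf_ts`, a numeric vector (with `fs`), or a list of `mf_ts`
#'   sharing one sampling rate (written as one column per channel).
#' @param fs sampling rate in Hz, required when `x` is a plain vector.
#' @rdname read_timeseries_csv
#' @export
write_timeseries_csv <- function(x, path, fs = NULL) {
  if (is.list(x) && !inherits(x, "mf_ts")) {
    rates <- vapply(x, function(ch) ts_fs(ch, fs), numeric(1))
    if (length(unique(rates)) != 1) {
      stop("channels written jointly must share one sampling rate")
    }
    fs <- rates[1]
    cols <- lapply(x, ts_values)
    n <- unique(lengths(cols))
    if (length(n) != 1) stop("channels must have equal length")
    body <- do.call(cbind, cols)
  } else {
    fs <- ts_fs(x, fs)
    body <- matrix(ts_values(x), ncol = 1)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%.10g", fs), con)
  chr <- apply(body, 2, function(col) sprintf("%.17g", col))
  utils::write.table(chr, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read event annotations (onset/offset seconds) from CSV
#'
#' Expects columns `onset_s` and `offset_s`. Each event must satisfy
#' `0 <= onset_s < offset_s`.
#'
#' @param path file path.
#' @param duration_s optional recording duration; events must end within it.
#' @return data.frame with columns `onset_s`, `offset_s`.
#' @export
read_events_csv <- function(path, duration_s = NULL) {
  ev <- utils::read.csv(path)
  validate_events(ev, duration_s)
}

validate_events <- function(events, duration_s = NULL) {
  if (!all(c("onset_s", "offset_s") %in% names(events))) {
    stop("events need columns 'onset_s' and 'offset_s'")
  }
  events <- events[, c("onset_s", "offset_s")]
  bad <- !(events$onset_s >= 0 & events$onset_s < events$offset_s)
  if (any(bad)) stop("invalid event intervals (need 0 <= onset < offset)")
  if (!is.null(duration_s) && any(events$offset_s > duration_s + 1e-9)) {
    stop("event extends beyond the recording (duration ", duration_s, " s)")
  }
  events
}
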