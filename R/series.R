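#' Concentration time series
#'
#' The package's common currency is a tidy tibble with one row per instrument
#' sample and columns `timestamp` (POSIXct, strictly increasing), `value`
#' (concentration in the channel's native unit: #/cc for particle counts,
#' ug/m^3 for black carbon, ppm for CO2), `channel`, `location` and a
#' per-sample `quality` flag.
#'
#' @param timestamp POSIXct (or coercible) sample instants, strictly increasing.
#' @param value Numeric concentrations. Negative or non-finite values are kept
#'   but flagged `"error"`.
#' @param channel One of `"co2"`, `"total_ufp"`, `"aircraft_ufp"`,
#'   `"cpc_total"`, `"bc"`.
#' @param location One of `"indoor"`, `"outdoor"`, `"mixed"`. A `"mixed"`
#'   series must be demultiplexed with [demux_valve()] before analysis.
#' @param quality Optional character vector of per-sample flags
#'   (`"ok"`, `"error"`, `"trimmed"`, `"substituted"`); derived from `value`
#'   when omitted.
#' @return A tibble with columns `timestamp`, `value`, `channel`, `location`,
#'   `quality`.
#' @examples
#' concentration_series(
#'   timestamp = as.POSIXct("2021-06-15 08:00:00", tz = "UTC") + (0:5) * 10,
#'   value = c(410, 415, -1, 420, NA, 418),
#'   channel = "co2", location = "indoor"
#' )
#' @export
concentration_series <- function(timestamp, value, channel, location,
                                 quality = NULL) {
  channel <- arg_match0(channel, CHANNELS)
  location <- arg_match0(location, LOCATIONS)
  timestamp <- as.POSIXct(timestamp)
  if (length(timestamp) != length(value)) {
    abort("`timestamp` and `value` must have equal length.")
  }
  if (anyNA(timestamp)) abort("`timestamp` contains missing values.")
  if (is.unsorted(timestamp, strictly = TRUE)) {
    bad <- which(diff(as.numeric(timestamp)) <= 0)[1] + 1L
    abort(sprintf("timestamps must be strictly increasing (violated at row %d)", bad))
  }
  value <- as.numeric(value)
  if (is.null(quality)) {
    quality <- ifelse(is.finite(value) & value >= 0, "ok", "error")
  } else {
    stopifnot(length(quality) == length(value), all(quality %in% QUALITIES))
  }
  tibble(
    timestamp = timestamp, value = value,
    channel = channel, location = location, quality = quality
  )
}

CHANNELS <- c("co2", "total_ufp", "aircraft_ufp", "cpc_total", "bc")
LOCATIONS <- c("indoor", "outdoor", "mixed")
QUALITIES <- c("ok", "error", "trimmed", "substituted")

# Validate that `x` is a concentration-series tibble; returns it invisibly.
check_series <- function(x, arg = caller_arg(x)) {
  need <- c("timestamp", "value", "channel", "location", "quality")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf(
      "`%s` must be a concentration series tibble with columns %s",
      arg, paste(need, collapse = ", ")
    ))
  }
  invisible(x)
}

# Median sampling interval in seconds.
sampling_dt <- function(series) {
  if (nrow(series) < 2) return(NA_real_)
  median(diff(as.numeric(series$timestamp)))
}

#' Read an instrument time-series file
#'
#' Reads a delimited text export from a monitoring instrument into a
#' concentration-series tibble. Column names vary by instrument dialect and
#' are mapped via `timestamp_col`/`value_col`. Values that fail to parse or
#' are negative are kept but flagged `"error"` so downstream substitution
#' (e.g. [substitute_cpc()]) can see the gaps.
#'
#' @param path Path to a delimited text file with a header row.
#' @param channel,location Channel and location labels for the series (see
#'   [concentration_series()]).
#' @param timestamp_col,value_col Names of the timestamp and value columns.
#' @param tz Timezone all timestamps are normalised to (default `"UTC"`).
#' @param delim Field delimiter (default comma).
#' @return A concentration-series tibble.
#' @export
read_series <- function(path, channel, location,
                        timestamp_col = "timestamp", value_col = "value",
                        tz = "UTC", delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  for (col in c(timestamp_col, value_col)) {
    if (!col %in% names(raw)) {
      abort(sprintf("column '%s' not found in %s", col, path))
    }
  }
  ts_raw <- raw[[timestamp_col]]
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS")
  parses <- lapply(fmts, function(f) {
    suppressWarnings(as.POSIXct(ts_raw, tz = tz, format = f))
  })
  n_ok <- vapply(parses, function(p) sum(!is.na(p)), integer(1))
  ts <- parses[[which.max(n_ok)]]
  if (anyNA(ts)) {
    # numeric epoch-seconds dialect
    ts_num <- suppressWarnings(as.numeric(ts_raw))
    if (length(ts_num) > 0 && !anyNA(ts_num)) {
      ts <- as.POSIXct(ts_num, origin = "1970-01-01", tz = tz)
    } else {
      bad <- which(is.na(ts))[1]
      abort(sprintf("unparseable timestamp at data row %d of %s: '%s'",
                    bad, path, ts_raw[bad]))
    }
  }
  if (length(ts) == 0) abort(sprintf("no parsable rows in %s", path))
  if (is.unsorted(ts, strictly = TRUE)) {
    bad <- which(diff(as.numeric(ts)) <= 0)[1] + 1L
    abort(sprintf("non-monotone timestamps in %s at data row %d", path, bad))
  }
  val <- suppressWarnings(as.numeric(raw[[value_col]]))
  concentration_series(ts, val, channel = channel, location = location)
}

#' Write a concentration series to CSV
#'
#' Writes `timestamp` (ISO-8601, UTC) and `value` columns; the on-disk dialect
#' round-trips through [read_series()]. Used by the simulator to emit
#' instrument-format files.
#'
#' @param series Concentration-series tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  check_series(series)
  out <- tibble(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = series$value
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Valve-switch sampling schedule
#'
#' Describes alternating indoor/outdoor sampling through a solenoid timer
#' valve: the inlet switches location every `period` seconds, and the first
#' `trim_head` seconds after each switch are discarded to purge air mixed
#' across the switch. The alternation cycle starts at `phase_origin` with the
#' `indoor_first` location.
#'
#' @param phase_origin POSIXct instant at which an indoor (or outdoor, if
#'   `indoor_first = FALSE`) interval begins; typically a whole hour
#'   (switches at hh:00:00, hh:05:00, ...).
#' @param period Interval length in seconds (default 300, i.e. 5 min).
#' @param trim_head Seconds discarded at each interval start (default 120).
#' @param indoor_first Does the cycle start indoor? Default `TRUE`.
#' @return A `valve_schedule` object.
#' @export
valve_schedule <- function(phase_origin, period = 300, trim_head = 120,
                           indoor_first = TRUE) {
  phase_origin <- as.POSIXct(phase_origin)
  stopifnot(length(phase_origin) == 1, !is.na(phase_origin))
  if (period <= 0) abort("`period` must be positive")
  if (trim_head < 0 || trim_head >= period) {
    abort("`trim_head` must lie in [0, period)")
  }
  structure(
    list(phase_origin = phase_origin, period = period,
         trim_head = trim_head, indoor_first = isTRUE(indoor_first)),
    class = "valve_schedule"
  )
}

#' @export
print.valve_schedule <- function(x, ...) {
  cat(sprintf(
    "<valve_schedule> %g-s alternation from %s (%s first), trim %g s\n",
    x$period, format(x$phase_origin, "%Y-%m-%d %H:%M:%S %Z"),
    if (x$indoor_first) "indoor" else "outdoor", x$trim_head
  ))
  invisible(x)
}
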