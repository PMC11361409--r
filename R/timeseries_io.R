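#' Demultiplex a valve-switched series into indoor and outdoor series
#'
#' With a single instrument sampling alternately through indoor and outdoor
#' inlets, every sample belongs to exactly one location determined by its
#' position in the alternation cycle. Samples falling within `trim_head`
#' seconds of a valve switch are flagged `"trimmed"`: air from the previous
#' inlet may still be purging through the line, so they are excluded from
#' analysis but retained for audit.
#'
#' @param series A concentration-series tibble with `location = "mixed"`.
#' @param schedule A [valve_schedule()].
#' @return A list with elements `indoor` and `outdoor`, each a
#'   concentration-series tibble. Every input sample appears in exactly one
#'   output.
#' @examples
#' t0 <- as.POSIXct("2021-06-15 09:00:00", tz = "UTC")
#' mixed <- concentration_series(t0 + seq(0, 1190, 10), rep(7, 120),
#'                               channel = "total_ufp", location = "mixed")
#' parts <- demux_valve(mixed, valve_schedule(t0))
#' table(parts$indoor$quality)
#' @export
demux_valve <- function(series, schedule) {
  check_series(series)
  stopifnot(inherits(schedule, "valve_schedule"))
  if (!all(series$location == "mixed")) {
    abort("`series` must have location 'mixed'; already-demultiplexed input?")
  }
  span <- diff(range(as.numeric(series$timestamp)))
  cycle <- 2 * schedule$period
  if (span < cycle) {
    abort(sprintf("series spans %.0f s, shorter than one full %d-s alternation cycle",
                  span, cycle))
  }
  elapsed <- as.numeric(series$timestamp) - as.numeric(schedule$phase_origin)
  pos <- elapsed %% cycle
  in_first <- pos < schedule$period
  is_indoor <- if (schedule$indoor_first) in_first else !in_first
  offset <- pos %% schedule$period
  trimmed <- offset < schedule$trim_head

  assign_one <- function(keep, loc) {
    out <- series[keep, , drop = FALSE]
    out$location <- loc
    tr <- trimmed[keep] & out$quality == "ok"
    out$quality[tr] <- "trimmed"
    as_tibble(out)
  }
  list(
    indoor = assign_one(is_indoor, "indoor"),
    outdoor = assign_one(!is_indoor, "outdoor")
  )
}

#' Fill NanoScan error gaps with CPC measurements
#'
#' The scanning sizer occasionally develops operating errors; during those
#' gaps the condensation particle counter's total count is substituted for
#' the total particle concentration. Substitution applies only to the total
#' channel — the CPC is not size-resolved, so size-bin channels (e.g. the
#' aircraft-origin bin) are never filled this way.
#'
#' @param nanoscan Total-UFP concentration series (channel `"total_ufp"`).
#' @param cpc CPC series (channel `"cpc_total"`), same location.
#' @param tol Matching tolerance in seconds: an error sample is filled from
#'   the nearest ok CPC sample no further than `tol` away (default 30).
#' @return The `nanoscan` series with error samples replaced by CPC values
#'   (flagged `"substituted"`) where a match exists; unmatched gaps keep
#'   `"error"`.
#' @export
substitute_cpc <- function(nanoscan, cpc, tol = 30) {
  check_series(nanoscan)
  check_series(cpc)
  if (any(nanoscan$channel == "aircraft_ufp")) {
    abort("substitution is not applicable to size-resolved channels")
  }
  t_cpc <- as.numeric(cpc$timestamp[cpc$quality == "ok"])
  v_cpc <- cpc$value[cpc$quality == "ok"]
  if (length(t_cpc) == 0) return(nanoscan)
  if (max(t_cpc) < min(as.numeric(nanoscan$timestamp)) ||
      min(t_cpc) > max(as.numeric(nanoscan$timestamp))) {
    abort("`nanoscan` and `cpc` do not overlap in time")
  }
  out <- nanoscan
  idx_err <- which(out$quality == "error")
  if (length(idx_err) == 0) return(out)
  t_err <- as.numeric(out$timestamp[idx_err])
  # nearest ok CPC sample for each error instant
  pos <- findInterval(t_err, t_cpc)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(t_cpc))
  d_lo <- abs(t_err - t_cpc[lo])
  d_hi <- abs(t_err - t_cpc[hi])
  nearest <- ifelse(d_lo <= d_hi, lo, hi)
  dist <- pmin(d_lo, d_hi)
  ok <- dist <= tol
  out$value[idx_err[ok]] <- v_cpc[nearest[ok]]
  out$quality[idx_err[ok]] <- "substituted"
  out
}

#' Average a concentration series over fixed windows
#'
#' Computes per-window means over usable (`ok` or `substituted`) samples in
#' half-open windows `[start, start + length)` aligned to the hour. Coverage
#' is the fraction of the window represented by usable samples at the series'
#' native sampling interval; low-coverage windows are flagged not usable and
#' excluded by downstream analyses.
#'
#' @param series Concentration-series tibble.
#' @param length Window length in seconds (default 1800, i.e. 30 min).
#' @param min_coverage Minimum coverage for a window to be usable
#'   (default 0.5).
#' @param origin Optional POSIXct window-grid origin; defaults to the series
#'   start floored to the hour.
#' @return A tibble with one row per non-empty window: `window_start`,
#'   `mean`, `n`, `coverage`, `usable`.
#' @export
window_average <- function(series, length = 1800, min_coverage = 0.5,
                           origin = NULL) {
  check_series(series)
  stopifnot(length > 0, min_coverage >= 0, min_coverage <= 1)
  use <- series$quality %in% c("ok", "substituted")
  if (!any(use)) abort("series has no usable samples")
  dt <- sampling_dt(series)
  if (is.na(dt) || dt <= 0) dt <- length # single sample: treat as full window
  t_num <- as.numeric(series$timestamp[use])
  if (is.null(origin)) {
    origin <- floor(min(as.numeric(series$timestamp)) / 3600) * 3600
  } else {
    origin <- as.numeric(as.POSIXct(origin))
  }
  win <- origin + floor((t_num - origin) / length) * length
  agg <- tibble(window = win, value = series$value[use]) |>
    group_by(.data$window) |>
    summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  tz <- attr(series$timestamp, "tzone")
  tibble(
    window_start = as.POSIXct(agg$window, origin = "1970-01-01",
                              tz = if (is.null(tz)) "UTC" else tz),
    mean = agg$mean,
    n = agg$n,
    coverage = pmin(1, agg$n * dt / length),
    usable = pmin(1, agg$n * dt / length) >= min_coverage
  )
}

#' Ingest a session's instrument files into one tidy table
#'
#' Convenience wrapper over [read_series()], [demux_valve()] and
#' [substitute_cpc()] driven by a configuration list (typically parsed from
#' YAML/JSON): reads every declared file, demultiplexes valve-switched
#' series, applies CPC substitution to the total-UFP channel where a CPC
#' series is present, and row-binds everything into one long table.
#'
#' @param config A list with elements `files` (a list of records with fields
#'   `path`, `channel`, `location`, and optionally `timestamp_col`,
#'   `value_col`), optional `tz`, and optional `valve` (fields
#'   `phase_origin`, `period`, `trim_head`, `indoor_first`) used for files
#'   with `location = "mixed"`.
#' @return A long tibble (`timestamp`, `channel`, `location`, `value`,
#'   `quality`).
#' @export
ingest_session <- function(config) {
  stopifnot(is.list(config), is.list(config$files))
  tz <- config$tz %||% "UTC"
  sched <- NULL
  if (!is.null(config$valve)) {
    v <- config$valve
    sched <- valve_schedule(
      as.POSIXct(v$phase_origin, tz = tz),
      period = v$period %||% 300,
      trim_head = v$trim_head %||% 120,
      indoor_first = v$indoor_first %||% TRUE
    )
  }
  parts <- list()
  for (f in config$files) {
    s <- read_series(f$path, channel = f$channel, location = f$location,
                     timestamp_col = f$timestamp_col %||% "timestamp",
                     value_col = f$value_col %||% "value", tz = tz)
    if (f$location == "mixed") {
      if (is.null(sched)) {
        abort(sprintf("file %s is valve-switched but config has no `valve` entry",
                      f$path))
      }
      dm <- demux_valve(s, sched)
      parts <- c(parts, list(dm$indoor, dm$outdoor))
    } else {
      parts <- c(parts, list(s))
    }
  }
  all <- bind_rows(parts)
  # CPC substitution per location where both channels are present
  for (loc in unique(all$location)) {
    nano <- all[all$channel == "total_ufp" & all$location == loc, ]
    cpc <- all[all$channel == "cpc_total" & all$location == loc, ]
    if (nrow(nano) > 0 && nrow(cpc) > 0 && any(nano$quality == "error")) {
      filled <- substitute_cpc(nano, cpc)
      all <- bind_rows(
        all[!(all$channel == "total_ufp" & all$location == loc), ],
        filled
      )
    }
  }
  arrange(all, .data$channel, .data$location, .data$timestamp) |>
    select("timestamp", "channel", "location", "value", "quality")
}
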