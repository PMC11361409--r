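#' Single-zone configuration
#'
#' Physical parameters of the classroom treated as one well-mixed zone.
#' Indoor concentration follows the mass balance
#' \deqn{dC_{in}/dt = P a C_{out} - (a + k_{dep} + CADR/V)\, C_{in}}
#' where `a` is the outdoor air-exchange rate, `P` the envelope penetration
#' factor, `k_dep` the first-order surface deposition rate and CADR the
#' clean-air delivery rate of a portable filter (0 when off).
#'
#' @param volume Room volume, m^3.
#' @param aer Outdoor air-exchange rate `a`, 1/h.
#' @param deposition Deposition rate `k_dep`, 1/h (default 0.5, a typical
#'   indoor UFP value; use 0 for gases such as CO2).
#' @param penetration Envelope penetration factor `P` in (0, 1] (default 1).
#' @param cadr Clean-air delivery rate, m^3/h (default 0 = no filter). Use
#'   [cfm_to_m3h()] for units quoted in CFM.
#' @return A `zone_config` object.
#' @examples
#' zone_config(volume = 250, aer = 1.5, cadr = cfm_to_m3h(500))
#' @export
zone_config <- function(volume, aer, deposition = 0.5, penetration = 1,
                        cadr = 0) {
  stopifnot(volume > 0, aer >= 0, deposition >= 0,
            penetration > 0, penetration <= 1, cadr >= 0)
  structure(list(volume = volume, aer = aer, deposition = deposition,
                 penetration = penetration, cadr = cadr),
            class = "zone_config")
}

#' Model-implied steady-state indoor/outdoor ratio
#'
#' For constant outdoor concentration and constant removal terms, the mass
#' balance settles at indoor/outdoor = `P a / (a + k_dep + CADR/V)` — the
#' model-implied infiltration factor.
#'
#' @param zone A [zone_config()].
#' @param cadr Optional CADR override (m^3/h), e.g. 0 to evaluate the
#'   filter-off state of a zone configured with a filter.
#' @return The dimensionless steady-state ratio.
#' @export
steady_state_ratio <- function(zone, cadr = NULL) {
  stopifnot(inherits(zone, "zone_config"))
  cadr <- cadr %||% zone$cadr
  loss <- zone$aer + zone$deposition + cadr / zone$volume
  if (loss == 0) return(NaN)
  zone$penetration * zone$aer / loss
}

#' Outdoor source configuration for the simulator
#'
#' Statistical structure of the synthetic outdoor particle series: a
#' baseline, a sinusoidal diurnal traffic cycle, Poisson-arriving aircraft
#' plumes that decay exponentially, and multiplicative lognormal instrument
#' noise. Defaults describe an urban near-airport site where the study-wide
#' median outdoor concentration is about 5000 #/cc.
#'
#' @param baseline Baseline concentration, #/cc (default 5000).
#' @param diurnal_amplitude Peak-to-trough amplitude of the diurnal cycle,
#'   #/cc (default 2000, peaking in the morning traffic hours).
#' @param plume_rate Aircraft plume arrival rate, events/h (default 3).
#' @param plume_peak Added concentration at plume onset, #/cc (default 15000).
#' @param plume_decay Plume decay rate, 1/h (default 20 — individual plumes
#'   wash out within minutes).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise, in [0, 1) (default 0.2).
#' @return An `outdoor_source_config` object.
#' @export
outdoor_source_config <- function(baseline = 5000, diurnal_amplitude = 2000,
                                  plume_rate = 3, plume_peak = 15000,
                                  plume_decay = 20, noise_cv = 0.2) {
  stopifnot(baseline >= 0, diurnal_amplitude >= 0, plume_rate >= 0,
            plume_peak >= 0, plume_decay >= 0, noise_cv >= 0, noise_cv < 1)
  structure(list(baseline = baseline, diurnal_amplitude = diurnal_amplitude,
                 plume_rate = plume_rate, plume_peak = plume_peak,
                 plume_decay = plume_decay, noise_cv = noise_cv),
            class = "outdoor_source_config")
}

#' Simulate an outdoor concentration series
#'
#' @param config An [outdoor_source_config()].
#' @param duration_h Simulated span, hours.
#' @param dt Sampling interval, seconds (default 10, the instruments' native
#'   resolution).
#' @param seed Optional integer seed for reproducibility.
#' @param start Series start instant (default a fixed 2021 study date, so
#'   identical seeds give bit-identical series).
#' @param channel Channel label for the output (default `"total_ufp"`).
#' @return An outdoor concentration-series tibble; the number of plume
#'   events and their onset times are stored in attributes `n_plumes` and
#'   `plume_times`.
#' @export
simulate_outdoor <- function(config = outdoor_source_config(), duration_h,
                             dt = 10, seed = NULL,
                             start = as.POSIXct("2021-06-15 00:00:00", tz = "UTC"),
                             channel = "total_ufp") {
  stopifnot(inherits(config, "outdoor_source_config"),
            duration_h > 0, dt > 0)
  with_seed(seed, {
    t_s <- seq(0, duration_h * 3600 - dt, by = dt)
    times <- start + t_s
    hod <- (as.numeric(times) / 3600) %% 24
    # diurnal cycle peaking at 08:00 local
    diurnal <- config$diurnal_amplitude / 2 * (1 + sin(2 * pi * (hod - 2) / 24))
    n_plumes <- rpois(1, config$plume_rate * duration_h)
    plume_t <- sort(runif(n_plumes, 0, duration_h * 3600))
    plumes <- numeric(length(t_s))
    for (t0 in plume_t) {
      after <- t_s >= t0
      plumes[after] <- plumes[after] +
        config$plume_peak * exp(-config$plume_decay * (t_s[after] - t0) / 3600)
    }
    value <- config$baseline + diurnal + plumes
    if (config$noise_cv > 0) {
      s2 <- log(1 + config$noise_cv^2)
      value <- value * rlnorm(length(value), meanlog = -s2 / 2, sdlog = sqrt(s2))
    }
    out <- concentration_series(times, value, channel = channel,
                                location = "outdoor")
    attr(out, "n_plumes") <- n_plumes
    attr(out, "plume_times") <- start + plume_t
    out
  })
}

# CADR active at each instant (numeric seconds since epoch), given optional
# on-intervals. NULL intervals mean the zone's CADR applies throughout.
cadr_at <- function(t_num, zone, hepa_intervals) {
  if (is.null(hepa_intervals)) return(rep(zone$cadr, length(t_num)))
  on <- rep(FALSE, length(t_num))
  for (iv in hepa_intervals) {
    on <- on | (t_num >= as.numeric(as.POSIXct(iv[[1]])) &
                  t_num < as.numeric(as.POSIXct(iv[[2]])))
  }
  ifelse(on, zone$cadr, 0)
}

#' Simulate the indoor response to an outdoor series
#'
#' Integrates the single-zone mass balance driven by the outdoor series.
#' Each step applies the exact exponential solution with the outdoor
#' concentration held constant over the step (not a naive Euler update), so
#' the step size does not bias the steady state. The indoor series starts at
#' the steady state implied by the first outdoor sample.
#'
#' @param outdoor Outdoor concentration-series tibble.
#' @param zone A [zone_config()].
#' @param hepa_intervals Optional list of `(start, end)` pairs (POSIXct or
#'   coercible) during which the zone's CADR is active; `NULL` (default)
#'   applies `zone$cadr` for the whole span.
#' @param dt Integration step, seconds; defaults to the outdoor sampling
#'   interval and must not exceed it.
#' @return An indoor concentration-series tibble on the integration grid,
#'   with ground truth (`zone` parameters and the filter-on/off steady-state
#'   ratios) in attribute `truth`.
#' @export
simulate_indoor <- function(outdoor, zone, hepa_intervals = NULL, dt = NULL) {
  check_series(outdoor)
  stopifnot(inherits(zone, "zone_config"))
  native <- sampling_dt(outdoor)
  dt <- dt %||% native
  if (!is.na(native) && dt > native + 1e-9) {
    abort(sprintf("integration step dt = %g s exceeds outdoor sampling interval %g s",
                  dt, native))
  }
  t_out <- as.numeric(outdoor$timestamp)
  t_grid <- seq(t_out[1], t_out[length(t_out)], by = dt)
  # zero-order hold of the outdoor series onto the integration grid
  c_out <- outdoor$value[findInterval(t_grid, t_out)]
  cadr_t <- cadr_at(t_grid, zone, hepa_intervals)
  loss_h <- zone$aer + zone$deposition + cadr_t / zone$volume # 1/h
  gain_h <- zone$penetration * zone$aer                        # 1/h

  c_in <- numeric(length(t_grid))
  c_in[1] <- if (loss_h[1] > 0) gain_h * c_out[1] / loss_h[1] else c_out[1]
  dt_h <- dt / 3600
  for (i in seq_len(length(t_grid) - 1)) {
    L <- loss_h[i]
    if (L > 0) {
      css <- gain_h * c_out[i] / L
      c_in[i + 1] <- css + (c_in[i] - css) * exp(-L * dt_h)
    } else {
      c_in[i + 1] <- c_in[i] + gain_h * c_out[i] * dt_h
    }
  }
  tz <- attr(outdoor$timestamp, "tzone")
  out <- concentration_series(
    as.POSIXct(t_grid, origin = "1970-01-01", tz = if (is.null(tz)) "UTC" else tz),
    c_in, channel = outdoor$channel[1], location = "indoor"
  )
  attr(out, "truth") <- list(
    aer = zone$aer, deposition = zone$deposition,
    penetration = zone$penetration, cadr = zone$cadr, volume = zone$volume,
    steady_state_ratio = steady_state_ratio(zone),
    steady_state_ratio_off = steady_state_ratio(zone, cadr = 0)
  )
  out
}

#' Simulate a monitoring session with known ground truth
#'
#' Generates one outdoor series and its indoor response for a
#' filter-off/filter-on deployment, mirroring the field protocol of
#' measuring ~24 h before and ~24 h after switching a portable HEPA unit on.
#'
#' @param zone A [zone_config()] whose `cadr` is the filter-on CADR.
#' @param source An [outdoor_source_config()].
#' @param hours_off,hours_on Hours of filter-off and filter-on operation
#'   (defaults 24 and 24).
#' @param dt Sampling/integration step, seconds (default 10).
#' @param seed Optional integer seed.
#' @param start Session start instant.
#' @return A list with `outdoor`, `indoor`, `hepa_on_time` (instant the
#'   filter switches on), `hepa_intervals`, and `truth` (one-row tibble with
#'   the zone parameters and both steady-state ratios).
#' @export
simulate_session <- function(zone, source = outdoor_source_config(),
                             hours_off = 24, hours_on = 24, dt = 10,
                             seed = NULL,
                             start = as.POSIXct("2021-06-15 00:00:00", tz = "UTC")) {
  stopifnot(hours_off > 0, hours_on >= 0)
  outdoor <- simulate_outdoor(source, duration_h = hours_off + hours_on,
                              dt = dt, seed = seed, start = start)
  hepa_on <- start + hours_off * 3600
  intervals <- if (hours_on > 0) list(c(hepa_on, start + (hours_off + hours_on) * 3600))
  indoor <- simulate_indoor(outdoor, zone, hepa_intervals = intervals, dt = dt)
  list(
    outdoor = outdoor, indoor = indoor, hepa_on_time = hepa_on,
    hepa_intervals = intervals,
    truth = tibble(
      aer = zone$aer, deposition = zone$deposition,
      penetration = zone$penetration, cadr = zone$cadr, volume = zone$volume,
      ratio_off = steady_state_ratio(zone, cadr = 0),
      ratio_on = steady_state_ratio(zone),
      effectiveness = 1 - steady_state_ratio(zone) / steady_state_ratio(zone, cadr = 0)
    )
  )
}

#' Overlay instrument measurement noise on a simulated series
#'
#' [simulate_indoor()] returns the physical concentration; what an
#' instrument records additionally carries multiplicative noise
#' (proportional to signal) and an additive noise floor from counting
#' statistics and electronics. The floor is what decouples a measured
#' indoor series from the outdoor driver when filtration pushes the signal
#' toward the instrument's detection limit.
#'
#' @param series Concentration-series tibble.
#' @param cv Coefficient of variation of multiplicative lognormal noise
#'   (default 0).
#' @param floor_sd Standard deviation of the additive Gaussian noise floor,
#'   in the series' units (default 0). Values are clipped at zero.
#' @param seed Optional integer seed.
#' @return The series with noisy values.
#' @export
add_instrument_noise <- function(series, cv = 0, floor_sd = 0, seed = NULL) {
  check_series(series)
  stopifnot(cv >= 0, cv < 1, floor_sd >= 0)
  with_seed(seed, {
    v <- series$value
    if (cv > 0) {
      s2 <- log(1 + cv^2)
      v <- v * rlnorm(length(v), meanlog = -s2 / 2, sdlog = sqrt(s2))
    }
    if (floor_sd > 0) v <- pmax(0, v + rnorm(length(v), 0, floor_sd))
    series$value <- v
    series
  })
}

#' Simulate a dry-ice CO2 elevation-and-decay experiment
#'
#' Emulates the field protocol for measuring the outdoor air-exchange rate:
#' CO2 is raised to a multiple of background with dry ice while mixing fans
#' run, sources are then removed, and the concentration decays exponentially
#' toward background at the air-exchange rate (CO2 is a gas tracer: no
#' deposition and no HEPA removal). Two room monitors are emitted (one at
#' room centre, one near the outside wall) with a configurable inter-monitor
#' bias, plus a constant-background outdoor series; all carry additive
#' Gaussian noise.
#'
#' @param zone A [zone_config()]; only `aer` matters for the decay.
#' @param background Ambient outdoor CO2, ppm (default 420).
#' @param peak_multiple Peak as a multiple of background; the protocol calls
#'   for at least 4, and a warning is issued below that (default 4).
#' @param noise_sd Additive Gaussian noise, ppm (default 5).
#' @param dt Sampling interval, seconds (default 10).
#' @param seed Optional integer seed.
#' @param ramp_min Minutes of linear ramp-up to peak (default 20).
#' @param decay_h Hours of recorded decay; default runs 1.2 times the
#'   one-third-elevation time `ln(3)/aer`, with a 1.5-h minimum.
#' @param monitor_bias Relative bias of the wall monitor versus the centre
#'   monitor (default 0).
#' @param start Experiment start instant.
#' @return A `decay_experiment` list: `room_monitors` (named list of two CO2
#'   series), `outdoor` series, `decay_start`, `decay_end`, and the true
#'   `aer`.
#' @export
simulate_co2_experiment <- function(zone, background = 420, peak_multiple = 4,
                                    noise_sd = 5, dt = 10, seed = NULL,
                                    ramp_min = 20, decay_h = NULL,
                                    monitor_bias = 0,
                                    start = as.POSIXct("2021-06-15 07:00:00", tz = "UTC")) {
  stopifnot(inherits(zone, "zone_config"), zone$aer > 0, background > 0)
  if (peak_multiple < 4) {
    warn(sprintf("peak_multiple = %g is below the protocol's minimum of 4", peak_multiple))
  }
  decay_h <- decay_h %||% max(1.5, 1.2 * log(3) / zone$aer)
  with_seed(seed, {
    peak <- background * peak_multiple
    ramp_s <- ramp_min * 60
    t_s <- seq(0, ramp_s + decay_h * 3600, by = dt)
    decay_start <- start + ramp_s
    clean <- ifelse(
      t_s <= ramp_s,
      background + (peak - background) * t_s / ramp_s,
      background + (peak - background) * exp(-zone$aer * (t_s - ramp_s) / 3600)
    )
    times <- start + t_s
    mk <- function(scale) {
      concentration_series(
        times, clean * scale + rnorm(length(clean), 0, noise_sd),
        channel = "co2", location = "indoor"
      )
    }
    structure(
      list(
        room_monitors = list(center = mk(1), wall = mk(1 + monitor_bias)),
        outdoor = concentration_series(
          times, background + rnorm(length(times), 0, noise_sd),
          channel = "co2", location = "outdoor"
        ),
        decay_start = decay_start,
        decay_end = times[length(times)],
        aer = zone$aer
      ),
      class = "decay_experiment"
    )
  })
}

#' Assemble a CO2 decay experiment from measured series
#'
#' @param room_monitors A single CO2 concentration series or a (optionally
#'   named) list of them.
#' @param outdoor Ambient CO2: a concentration series or a single ppm value.
#' @param decay_start Instant the CO2 sources were removed.
#' @param decay_end Instant ventilation conditions changed (door opened,
#'   re-entry).
#' @return A `decay_experiment` object for [fit_decay()].
#' @export
decay_experiment <- function(room_monitors, outdoor, decay_start, decay_end) {
  if (is.data.frame(room_monitors)) room_monitors <- list(room_monitors)
  stopifnot(length(room_monitors) >= 1)
  lapply(room_monitors, check_series)
  decay_start <- as.POSIXct(decay_start)
  decay_end <- as.POSIXct(decay_end)
  if (!decay_start < decay_end) abort("`decay_start` must precede `decay_end`")
  structure(
    list(room_monitors = room_monitors, outdoor = outdoor,
         decay_start = decay_start, decay_end = decay_end, aer = NULL),
    class = "decay_experiment"
  )
}

#' Generate synthetic near-school flight tracks with known ground truth
#'
#' Builds straight-line arrival (descending) and departure (climbing) tracks
#' around a school site. Each flight is constructed either to pass through
#' the exposure geofence (closest approach inside the radius at an altitude
#' below the ceiling) or to miss it (passing far to the side, or overhead
#' above the ceiling), so whether it should be counted is known by
#' construction rather than recomputed.
#'
#' @param site A list or one-row data frame with `latitude` and `longitude`
#'   (degrees).
#' @param n_arrivals,n_departures Number of arrival and departure tracks.
#' @param seed Optional integer seed.
#' @param prob_near Probability a flight is constructed to pass through the
#'   geofence (default 0.5); ignored when `through_fence` is given.
#' @param through_fence Force all flights through (`TRUE`) or away from
#'   (`FALSE`) the geofence; `NULL` (default) randomises per flight.
#' @param airports Airport labels sampled per flight (default SEA, BFI, RNT).
#' @param alt_ceiling,radius_m Geofence the construction targets (defaults
#'   750 m and one mile); constructed with margins so the stored truth is
#'   unambiguous.
#' @return A tibble of track points (`flight_id`, `airport`, `operation`,
#'   `time`, `latitude`, `longitude`, `altitude_m`) with the per-flight
#'   ground truth tibble (`flight_id`, `airport`, `operation`, `near`) in
#'   attribute `truth`.
#' @export
generate_flight_tracks <- function(site, n_arrivals, n_departures,
                                   seed = NULL, prob_near = 0.5,
                                   through_fence = NULL,
                                   airports = c("SEA", "BFI", "RNT"),
                                   alt_ceiling = 750, radius_m = MILE_M) {
  stopifnot(n_arrivals >= 0, n_departures >= 0)
  n <- n_arrivals + n_departures
  empty <- tibble(flight_id = character(), airport = character(),
                  operation = character(), time = as.POSIXct(character(), tz = "UTC"),
                  latitude = numeric(), longitude = numeric(),
                  altitude_m = numeric())
  if (n == 0) {
    attr(empty, "truth") <- tibble(flight_id = character(), airport = character(),
                                   operation = character(), near = logical())
    return(empty)
  }
  lat0 <- site$latitude
  lon0 <- site$longitude
  with_seed(seed, {
    op <- c(rep("arrival", n_arrivals), rep("departure", n_departures))
    apt <- sample(airports, n, replace = TRUE)
    near <- if (is.null(through_fence)) {
      as.logical(rbinom(n, 1, prob_near))
    } else {
      rep(isTRUE(through_fence), n)
    }
    t0 <- as.POSIXct("2019-06-01 00:00:00", tz = "UTC")
    n_pts <- 21L
    pts <- vector("list", n)
    for (i in seq_len(n)) {
      brg <- runif(1, 0, 2 * pi)      # bearing from site to closest approach
      if (near[i]) {
        d0 <- runif(1, 0, 0.85) * radius_m
        alt0 <- runif(1, 50, 0.9 * alt_ceiling)
      } else if (runif(1) < 0.5) {
        d0 <- runif(1, 1.2, 4) * radius_m   # low but far to the side
        alt0 <- runif(1, 50, 0.9 * alt_ceiling)
      } else {
        d0 <- runif(1, 0, 0.85) * radius_m  # overhead but high
        alt0 <- runif(1, 1.1 * alt_ceiling, 3 * alt_ceiling)
      }
      # track runs perpendicular to the site bearing, so d0 is the closest approach
      s <- seq(-2000, 2000, length.out = n_pts)
      dir <- brg + pi / 2
      dx <- d0 * sin(brg) + s * sin(dir)
      dy <- d0 * cos(brg) + s * cos(dir)
      lat <- lat0 + dy / EARTH_RADIUS_M * 180 / pi
      lon <- lon0 + dx / (EARTH_RADIUS_M * cos(lat0 * pi / 180)) * 180 / pi
      # V-shaped glide/climb profile with its minimum at closest approach
      alt <- alt0 + 0.08 * abs(s)
      pts[[i]] <- tibble(
        flight_id = sprintf("F%04d", i), airport = apt[i], operation = op[i],
        time = t0 + (i - 1) * 3600 + seq_len(n_pts) * 5,
        latitude = lat, longitude = lon, altitude_m = alt
      )
    }
    out <- bind_rows(pts)
    attr(out, "truth") <- tibble(
      flight_id = sprintf("F%04d", seq_len(n)),
      airport = apt, operation = op, near = near
    )
    out
  })
}
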