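# Shared fixtures for the test suite. Everything is generated in code; no
# files are read from disk except those a test writes itself.

T0 <- as.POSIXct("2021-06-15 09:00:00", tz = "UTC")

# Constant-valued series at 10-s resolution.
const_series <- function(value, n, channel = "total_ufp",
                         location = "outdoor", dt = 10, start = T0) {
  concentration_series(start + seq(0, by = dt, length.out = n),
                       rep(value, n), channel = channel, location = location)
}

# The study's filter-on zone: 250 m^3 room, AER 1.5/h, UFP deposition
# 0.5/h, portable HEPA at 500 CFM (849.5 m^3/h). True removal
# effectiveness 1 - 2.0/5.398.
study_zone <- function() {
  zone_config(volume = 250, aer = 1.5, deposition = 0.5, penetration = 1,
              cadr = cfm_to_m3h(500))
}

# Run one simulated before/after deployment and estimate effectiveness by
# both routes. Returns the two effectiveness tibbles plus the truth row.
run_effectiveness_session <- function(seed, hours_off = 24, hours_on = 24) {
  zone <- study_zone()
  sess <- simulate_session(zone, hours_off = hours_off, hours_on = hours_on,
                           seed = seed)
  iw <- window_average(sess$indoor)
  ow <- window_average(sess$outdoor)
  before_i <- iw[iw$window_start + 1800 <= sess$hepa_on_time, ]
  before_o <- ow[ow$window_start + 1800 <= sess$hepa_on_time, ]
  after_i <- iw[iw$window_start >= sess$hepa_on_time, ]
  after_o <- ow[ow$window_start >= sess$hepa_on_time, ]
  inf_off <- compute_infiltration(before_i, before_o, "off", seed = seed + 1)
  inf_on <- compute_infiltration(after_i, after_o, "on", seed = seed + 2)
  design <- build_design(iw, ow, sess$hepa_intervals, school = "S1")
  fit <- fit_loglog(design)
  list(
    ratio = compute_effectiveness(inf_off, inf_on, seed = seed + 3),
    regression = regression_effectiveness(fit),
    inf_off = inf_off, inf_on = inf_on, fit = fit,
    truth = sess$truth
  )
}

# Exact one-sided rank-sum p-value by exhaustive enumeration of which ranks
# the 'before' group occupies (independent of stats::wilcox.test).
enumerate_ranksum_p <- function(before, after) {
  pooled <- c(before, after)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(before)]) - length(before) * (length(before) + 1) / 2
  combos <- utils::combn(length(pooled), length(before))
  w_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - length(before) * (length(before) + 1) / 2
  })
  mean(w_all >= w_obs)
}
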