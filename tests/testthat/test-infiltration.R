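windows_from <- function(values, start = T0) {
  tibble::tibble(
    window_start = start + seq_along(values) * 1800,
    mean = values, n = 180, coverage = 1, usable = TRUE
  )
}

test_that("compute_infiltration returns identity and zero ratios exactly", {
  out_w <- windows_from(rep(1000, 12))
  ident <- compute_infiltration(windows_from(rep(1000, 12)), out_w, "off",
                                n_boot = 200, seed = 1)
  expect_equal(ident$point, 1)
  expect_equal(ident$median, 1)
  zero <- compute_infiltration(windows_from(rep(0, 12)), out_w, "on",
                               n_boot = 200, seed = 1)
  expect_equal(zero$point, 0)
  expect_error(
    compute_infiltration(windows_from(1:3), windows_from(rep(1000, 3)), "off"),
    "usable aligned windows"
  )
  # near-zero outdoor windows are excluded by the denominator floor
  sparse <- compute_infiltration(
    windows_from(rep(10, 12)), windows_from(c(rep(1000, 8), rep(1, 4))), "off",
    n_boot = 200, seed = 1
  )
  expect_equal(sparse$n_windows, 8)
})

test_that("windowed ratios on simulated data recover the steady-state truth", {
  out <- const_series(1000, 24 * 360, dt = 10)
  zone <- zone_config(volume = 250, aer = 1, deposition = 0.5, cadr = 850)
  ind <- simulate_indoor(out, zone)
  est <- compute_infiltration(window_average(ind), window_average(out), "on",
                              n_boot = 500, seed = 2)
  expect_equal(est$point, 0.204, tolerance = 0.03 / 0.204)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
})

test_that("effectiveness reproduces the worked before/after examples", {
  expect_equal(round(100 * compute_effectiveness(0.54, 0.09)$effectiveness), 83)
  expect_equal(round(100 * compute_effectiveness(0.74, 0.20)$effectiveness), 73)
  expect_equal(compute_effectiveness(0.4, 0.4)$effectiveness, 0)
  expect_error(compute_effectiveness(0, 0.1), "undefined")
})

test_that("effectiveness of an estimate against itself is zero", {
  out_w <- windows_from(rep(1000, 10))
  est_off <- compute_infiltration(windows_from(runif(10, 300, 600)), out_w,
                                  "off", n_boot = 200, seed = 3)
  est_on <- est_off
  est_on$hepa_state <- "on"
  eff <- compute_effectiveness(est_off, est_on, n_boot = 200, seed = 4)
  expect_equal(eff$effectiveness, 0)
  expect_true(eff$ci_low <= 0 && 0 <= eff$ci_high)
})

test_that("infiltration statistics are invariant to common rescaling", {
  set.seed(5)
  iv <- runif(20, 100, 500)
  ov <- runif(20, 800, 2000)
  a <- compute_infiltration(windows_from(iv), windows_from(ov), "off",
                            n_boot = 300, seed = 6)
  b <- compute_infiltration(windows_from(7 * iv), windows_from(7 * ov), "off",
                            n_boot = 300, seed = 6)
  expect_equal(b$point, a$point)
  expect_equal(b$ci_low, a$ci_low)
  expect_equal(wilcoxon_compare(7 * iv, 7 * ov)$p_value,
               wilcoxon_compare(iv, ov)$p_value)
  expect_equal(io_correlation(windows_from(7 * iv), windows_from(7 * ov))$r,
               io_correlation(windows_from(iv), windows_from(ov))$r)
})

test_that("wilcoxon_compare matches exhaustive rank enumeration", {
  before <- c(5, 6, 7, 8)
  after <- c(1, 2, 3, 4)
  res <- wilcoxon_compare(before, after)
  expect_equal(res$p_value, 1 / 70)
  expect_equal(res$p_value, enumerate_ranksum_p(before, after))
  # a second, non-extreme configuration against the same oracle
  b2 <- c(2, 4, 6, 9)
  a2 <- c(1, 3, 5, 7)
  expect_equal(wilcoxon_compare(b2, a2)$p_value, enumerate_ranksum_p(b2, a2))

  # identical samples cannot show separation
  same <- c(0.2, 0.3, 0.4, 0.5)
  expect_gte(wilcoxon_compare(same, same)$p_value, 0.5)
  expect_warning(res0 <- wilcoxon_compare(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(res0$p_value, 1)
  expect_error(wilcoxon_compare(1:3, 1:6), "at least 4")
})

test_that("io_correlation detects linear coupling and degenerate inputs", {
  set.seed(11)
  ov <- runif(20, 1000, 9000)
  expect_equal(io_correlation(windows_from(0.5 * ov), windows_from(ov))$r, 1)
  expect_warning(
    r0 <- io_correlation(windows_from(rep(5, 20)), windows_from(ov)),
    "zero variance"
  )
  expect_true(is.na(r0$r))
})

test_that("strong filtration decouples the measured indoor signal from outdoor", {
  # filtration collapses the indoor signal toward the instrument noise
  # floor, which is what breaks the measured indoor/outdoor coupling; a
  # calm day (diurnal cycle only) at 1-min sampling with a NanoScan-like
  # floor shows it clearly
  src <- outdoor_source_config(plume_rate = 0, noise_cv = 0.15)
  out <- simulate_outdoor(src, duration_h = 24, dt = 60, seed = 14)
  ow <- window_average(out)
  zone_off <- zone_config(volume = 250, aer = 1.5)          # ratio 0.75
  zone_on <- zone_config(volume = 250, aer = 1.5, cadr = 3667) # ratio 0.09
  measure <- function(zone, seed) {
    add_instrument_noise(simulate_indoor(out, zone), cv = 0.1, floor_sd = 500,
                         seed = seed)
  }
  r_off <- io_correlation(window_average(measure(zone_off, 141)), ow)$r
  r_on <- io_correlation(window_average(measure(zone_on, 142)), ow)$r
  expect_gt(r_off, r_on)
  expect_gt(r_off, 0.5)
})

test_that("lag_persistence tracks re-coupling after filter switch-off", {
  # indoor as a slightly delayed copy of a smooth outdoor signal: r near 1
  out <- simulate_outdoor(
    outdoor_source_config(noise_cv = 0, plume_rate = 6, plume_decay = 2),
    duration_h = 5, seed = 15
  )
  lagged <- out
  lagged$value <- dplyr::lag(out$value, 3, default = out$value[1])
  lagged$location <- "indoor"
  tbl <- lag_persistence(lagged, out, hepa_off_time = T0 - 9 * 3600 + 3600,
                         horizon = 3600)
  expect_gt(median(tbl$r, na.rm = TRUE), 0.8)

  # independent white noise: negligible correlation in most windows
  set.seed(16)
  n <- 1800
  t <- T0 + seq(0, by = 10, length.out = n)
  wn1 <- concentration_series(t, 1000 + rnorm(n, 0, 50), "total_ufp", "indoor")
  wn2 <- concentration_series(t, 1000 + rnorm(n, 0, 50), "total_ufp", "outdoor")
  tbl2 <- lag_persistence(wn1, wn2, hepa_off_time = t[1], horizon = 7200 - 1800)
  expect_gt(mean(abs(tbl2$r) < 2 / sqrt(180), na.rm = TRUE), 0.7)

  # simulator switch-off: indoor re-couples over the first hour
  zone <- study_zone()
  sess_out <- simulate_outdoor(duration_h = 10, seed = 17)
  off_time <- T0 - 9 * 3600 + 4 * 3600
  ind <- simulate_indoor(sess_out, zone,
                         hepa_intervals = list(c(sess_out$timestamp[1], off_time)))
  expect_warning(
    tbl3 <- lag_persistence(ind, sess_out, hepa_off_time = off_time,
                            horizon = 10 * 3600),
    "truncated"
  )
  expect_true(attr(tbl3, "truncated"))
  late <- tbl3$r[tbl3$elapsed_min >= 60]
  early <- tbl3$r[tbl3$elapsed_min <= 15]
  expect_gt(mean(late, na.rm = TRUE), mean(early, na.rm = TRUE))
})
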