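test_that("read_series parses a delimited file and flags bad values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,value",
    "2021-06-15T09:00:00,1",
    "2021-06-15T09:00:10,2",
    "2021-06-15T09:00:20,3"
  ), path)
  s <- read_series(path, channel = "total_ufp", location = "outdoor")
  expect_equal(nrow(s), 3)
  expect_equal(s$value, c(1, 2, 3))
  expect_true(all(s$quality == "ok"))

  writeLines(c(
    "timestamp,value",
    "2021-06-15T09:00:00,1",
    "2021-06-15T09:00:10,-5",
    "2021-06-15T09:00:20,bad",
    "2021-06-15T09:00:30,4"
  ), path)
  s <- read_series(path, channel = "total_ufp", location = "outdoor")
  expect_equal(s$quality, c("ok", "error", "error", "ok"))

  writeLines(c(
    "timestamp,value",
    "2021-06-15T09:00:10,1",
    "2021-06-15T09:00:00,2"
  ), path)
  expect_error(read_series(path, "total_ufp", "outdoor"), "non-monotone.*row 2")
})

test_that("simulator-written files round-trip through read_series", {
  s <- simulate_outdoor(duration_h = 1, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  back <- read_series(path, channel = "total_ufp", location = "outdoor")
  expect_equal(as.numeric(back$timestamp), as.numeric(s$timestamp))
  expect_equal(back$value, s$value, tolerance = 1e-12)
})

test_that("demux_valve assigns intervals and trims switch heads", {
  # 20 min of constant 7 at 10-s resolution, 5-min alternation, 2-min trim
  mixed <- const_series(7, 120, location = "mixed")
  parts <- demux_valve(mixed, valve_schedule(T0))
  mins <- function(s) as.numeric(difftime(s$timestamp, T0, units = "mins"))

  ind_ok <- parts$indoor[parts$indoor$quality == "ok", ]
  out_ok <- parts$outdoor[parts$outdoor$quality == "ok", ]
  expect_true(all(
    (mins(ind_ok) >= 2 & mins(ind_ok) < 5) | (mins(ind_ok) >= 12 & mins(ind_ok) < 15)
  ))
  expect_true(all(
    (mins(out_ok) >= 7 & mins(out_ok) < 10) | (mins(out_ok) >= 17 & mins(out_ok) < 20)
  ))
  expect_true(all(ind_ok$value == 7) && all(out_ok$value == 7))
  # the first 2 min of each 5-min interval are flagged trimmed
  ind_tr <- parts$indoor[parts$indoor$quality == "trimmed", ]
  expect_true(all(mins(ind_tr) %% 5 < 2))

  expect_error(demux_valve(const_series(7, 30, location = "mixed"),
                           valve_schedule(T0)),
               "shorter than one full")
})

test_that("demux partitions the input: every sample lands in exactly one output", {
  set.seed(4)
  n <- 360
  mixed <- concentration_series(T0 + seq(0, by = 10, length.out = n),
                                runif(n, 10, 100), "total_ufp", "mixed")
  parts <- demux_valve(mixed, valve_schedule(T0, indoor_first = FALSE))
  expect_equal(nrow(parts$indoor) + nrow(parts$outdoor), n)
  expect_length(intersect(as.numeric(parts$indoor$timestamp),
                          as.numeric(parts$outdoor$timestamp)), 0)
  # ok input samples come back as ok or trimmed, values untouched
  both <- dplyr::bind_rows(parts$indoor, parts$outdoor) |>
    dplyr::arrange(timestamp)
  expect_equal(both$value, mixed$value)
  expect_true(all(both$quality %in% c("ok", "trimmed")))
})

test_that("demux separates a simulated indoor/outdoor step signal", {
  # instrument alternates between a 100 #/cc room and a 1000 #/cc exterior
  t <- T0 + seq(0, by = 10, length.out = 720)
  pos <- (as.numeric(t) - as.numeric(T0)) %% 600
  val <- ifelse(pos < 300, 100, 1000)
  mixed <- concentration_series(t, val, "total_ufp", "mixed")
  parts <- demux_valve(mixed, valve_schedule(T0))
  expect_equal(mean(parts$indoor$value[parts$indoor$quality == "ok"]), 100)
  expect_equal(mean(parts$outdoor$value[parts$outdoor$quality == "ok"]), 1000)
})

test_that("substitute_cpc fills error gaps only where CPC covers them", {
  n <- 600
  t <- T0 + seq(0, by = 10, length.out = n)
  nano_q <- rep("ok", n)
  nano_q[200:456] <- "error" # 43% gap, as seen in real deployments
  nano <- concentration_series(t, rep(5000, n), "total_ufp", "indoor",
                               quality = nano_q)
  cpc <- concentration_series(t, rep(4800, n), "cpc_total", "indoor")
  filled <- substitute_cpc(nano, cpc)
  expect_equal(sum(filled$quality == "error"), 0)
  expect_equal(mean(filled$quality == "substituted"), 0.4283, tolerance = 0.001)
  expect_equal(unique(filled$value[filled$quality == "substituted"]), 4800)

  # all-ok input is a no-op
  nano_ok <- concentration_series(t, rep(5000, n), "total_ufp", "indoor")
  expect_identical(substitute_cpc(nano_ok, cpc), nano_ok)

  # error retained where the CPC has no sample within tolerance
  cpc_gappy <- concentration_series(t[c(1:100, 500:600)], rep(4800, 201),
                                    "cpc_total", "indoor")
  part <- substitute_cpc(nano, cpc_gappy)
  expect_gt(sum(part$quality == "error"), 0)
  # substitution never shrinks the usable sample count
  usable <- function(s) sum(s$quality %in% c("ok", "substituted"))
  expect_gte(usable(part), usable(nano))
  expect_gte(usable(filled), usable(part))

  # never applied to size-resolved channels
  bin <- concentration_series(t, rep(100, n), "aircraft_ufp", "indoor",
                              quality = nano_q)
  expect_error(substitute_cpc(bin, cpc), "size-resolved")
})

test_that("window_average matches a brute-force re-average and flags low coverage", {
  expect_equal(unique(window_average(const_series(3, 720))$mean), 3)

  # linear ramp over one 30-min window averages to ~0.5
  ramp <- concentration_series(T0 + seq(0, 1790, 10), seq(0, 1, length.out = 180),
                               "total_ufp", "outdoor")
  w <- window_average(ramp)
  expect_equal(w$mean[1], 0.5, tolerance = 1 / 180)

  # brute-force oracle on a simulated series with dropouts
  s <- simulate_outdoor(duration_h = 3, seed = 7)
  set.seed(8)
  s$quality[sample(nrow(s), 200)] <- "error"
  w <- window_average(s)
  for (i in seq_len(nrow(w))) {
    in_win <- s$timestamp >= w$window_start[i] &
      s$timestamp < w$window_start[i] + 1800 & s$quality == "ok"
    expect_equal(w$mean[i], mean(s$value[in_win]))
  }
  # a window with < 50% usable samples is excluded from analysis
  s2 <- s
  first_win <- s2$timestamp < w$window_start[1] + 1800
  s2$quality[first_win][seq_len(floor(sum(first_win) * 0.6))] <- "error"
  w2 <- window_average(s2)
  expect_false(w2$usable[1])
})

test_that("window averaging is linear in the input series", {
  x <- simulate_outdoor(duration_h = 2, seed = 21)
  y <- simulate_outdoor(duration_h = 2, seed = 22)
  combo <- x
  combo$value <- 2 * x$value + 3 * y$value
  expect_equal(window_average(combo)$mean,
               2 * window_average(x)$mean + 3 * window_average(y)$mean)
})

test_that("ingest_session reads, demuxes and substitutes into one long table", {
  dir <- withr::local_tempdir()
  mixed <- const_series(50, 360, location = "mixed")
  write_series(mixed, file.path(dir, "ufp.csv"))
  cpc <- const_series(48, 360, channel = "cpc_total", location = "indoor")
  write_series(cpc, file.path(dir, "cpc.csv"))
  config <- list(
    tz = "UTC",
    valve = list(phase_origin = format(T0, "%Y-%m-%d %H:%M:%S")),
    files = list(
      list(path = file.path(dir, "ufp.csv"), channel = "total_ufp",
           location = "mixed"),
      list(path = file.path(dir, "cpc.csv"), channel = "cpc_total",
           location = "indoor")
    )
  )
  tidy_tbl <- ingest_session(config)
  expect_setequal(names(tidy_tbl),
                  c("timestamp", "channel", "location", "value", "quality"))
  expect_setequal(unique(tidy_tbl$channel), c("total_ufp", "cpc_total"))
  expect_setequal(unique(tidy_tbl$location), c("indoor", "outdoor"))
  expect_equal(nrow(tidy_tbl), 720)
})
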