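#' Check spatial uniformity across room CO2 monitors and merge them
#'
#' A decay experiment uses two analyzers (room centre and outside wall).
#' When their rolling relative difference stays within tolerance the room is
#' considered well mixed and the concurrent readings are averaged into one
#' representative series.
#'
#' @param monitors A list of CO2 concentration series (a single series
#'   passes trivially).
#' @param window Rolling-mean window for the relative difference, seconds
#'   (default 300).
#' @param tol Maximum rolling relative spread for the room to count as
#'   uniform (default 0.10).
#' @return A list with `uniform` (logical) and `merged` (pointwise-mean
#'   concentration series over concurrent ok samples).
#' @export
check_uniformity <- function(monitors, window = 300, tol = 0.10) {
  if (is.data.frame(monitors)) monitors <- list(monitors)
  lapply(monitors, check_series)
  if (length(monitors) == 1) {
    return(list(uniform = TRUE, merged = monitors[[1]]))
  }
  ok_tbls <- lapply(monitors, function(m) {
    m <- m[m$quality == "ok", c("timestamp", "value")]
    m
  })
  wide <- Reduce(function(a, b) inner_join(a, b, by = "timestamp"), ok_tbls)
  if (nrow(wide) == 0) abort("monitors have no temporal overlap")
  vals <- as.matrix(wide[, -1, drop = FALSE])
  spread <- (apply(vals, 1, max) - apply(vals, 1, min)) / rowMeans(vals)
  dt <- median(diff(as.numeric(wide$timestamp)))
  k <- max(1L, round(window / dt))
  roll <- if (nrow(wide) >= k) {
    zoo::rollmean(spread, k, fill = NA, align = "center")
  } else {
    mean(spread)
  }
  merged <- concentration_series(
    wide$timestamp, rowMeans(vals),
    channel = monitors[[1]]$channel[1], location = monitors[[1]]$location[1]
  )
  list(uniform = all(roll <= tol, na.rm = TRUE), merged = merged)
}

# Ambient background ppm from the experiment's outdoor record, preferring
# samples inside the decay window.
decay_background <- function(experiment) {
  out <- experiment$outdoor
  if (is.numeric(out) && length(out) == 1) return(out)
  check_series(out)
  ok <- out[out$quality == "ok", ]
  inwin <- ok[ok$timestamp >= experiment$decay_start &
                ok$timestamp <= experiment$decay_end, ]
  if (nrow(inwin) > 0) mean(inwin$value) else mean(ok$value)
}

#' Fit the CO2 decay model and estimate the air-exchange rate
#'
#' Fits the dynamic mass-balance decay model
#' \deqn{C(t) = C_{bg} + A_0 e^{-k \Delta t}}
#' to the merged room CO2 record over the decay window by nonlinear least
#' squares, with the background fixed to the mean ambient outdoor CO2 (the
#' quantity of interest is the in-room concentration minus ambient). The
#' fitted `k` (1/h) is the outdoor air-exchange rate: CO2 is a conserved gas
#' tracer, so infiltration plus mechanical ventilation are the only decay
#' pathways. A log-linear slope estimate of `ln(C - C_bg)` is reported as a
#' cross-check, and the protocol's adequacy rule (concentration decayed to
#' at most one-third of its initial elevation) is evaluated.
#'
#' @param experiment A `decay_experiment` (from [decay_experiment()] or
#'   [simulate_co2_experiment()]).
#' @param uniformity_tol Tolerance passed to [check_uniformity()].
#' @param min_samples Minimum usable samples in the decay window (default 10).
#' @return An `aer_fit` object; see [tidy()]/[glance()] methods and
#'   [autoplot.aer_fit()].
#' @examples
#' zone <- zone_config(volume = 250, aer = 1.5)
#' exp <- simulate_co2_experiment(zone, noise_sd = 5, seed = 42)
#' fit <- fit_decay(exp)
#' glance(fit)
#' @export
fit_decay <- function(experiment, uniformity_tol = 0.10, min_samples = 10) {
  stopifnot(inherits(experiment, "decay_experiment"))
  unif <- check_uniformity(experiment$room_monitors, tol = uniformity_tol)
  merged <- unif$merged
  bg <- decay_background(experiment)

  win <- merged[merged$quality == "ok" &
                  merged$timestamp >= experiment$decay_start &
                  merged$timestamp <= experiment$decay_end, ]
  elev <- win$value - bg
  usable <- elev > 0
  if (sum(usable) < min_samples) {
    abort(sprintf("only %d usable samples above background in the decay window (need >= %d)",
                  sum(usable), min_samples))
  }
  win <- win[usable, ]
  elev <- elev[usable]
  dt_h <- as.numeric(difftime(win$timestamp, experiment$decay_start, units = "hours"))

  # log-linear cross-check and starting values
  ll <- lm(log(elev) ~ dt_h)
  k0 <- max(-coef(ll)[[2]], 1e-3)
  a0_0 <- exp(coef(ll)[[1]])
  fit <- minpack.lm::nlsLM(
    value ~ bg + a0 * exp(-k * dt_h),
    data = tibble(value = win$value, dt_h = dt_h),
    start = list(a0 = a0_0, k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  rss <- sum(residuals(fit)^2)
  tss <- sum((win$value - mean(win$value))^2)

  # adequacy: decayed to <= 1/3 of the starting elevation (protocol rule);
  # short means over the window ends damp instrument noise
  n_edge <- min(6L, nrow(win))
  elev_first <- mean(head(elev, n_edge))
  elev_last <- mean(tail(elev, n_edge))
  adequate <- elev_last <= elev_first / 3
  if (!adequate) {
    warn(sprintf(
      "decay reached only %.0f%% of initial elevation; protocol requires decay to one-third",
      100 * elev_last / elev_first
    ))
  }
  structure(
    list(
      k = est[["k"]], k_se = se[["k"]],
      a0 = est[["a0"]], a0_se = se[["a0"]],
      background = bg, r_squared = 1 - rss / tss,
      adequate = adequate, uniform = unif$uniform,
      k_loglinear = -coef(ll)[[2]],
      n = nrow(win),
      decay_start = experiment$decay_start, decay_end = experiment$decay_end,
      data = tibble(timestamp = win$timestamp, dt_h = dt_h, value = win$value,
                    fitted = fitted(fit)),
      model = fit
    ),
    class = "aer_fit"
  )
}

#' @export
print.aer_fit <- function(x, ...) {
  cat(sprintf("<aer_fit> k = %.3f /h (SE %.3f), A0 = %.0f ppm, background = %.0f ppm\n",
              x$k, x$k_se, x$a0, x$background))
  cat(sprintf("  R^2 = %.4f over %d samples; adequate decay: %s; uniform room: %s\n",
              x$r_squared, x$n, x$adequate, x$uniform))
  invisible(x)
}

#' Tidy a fitted CO2 decay model
#'
#' @param x An `aer_fit` from [fit_decay()].
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per parameter (`k` in 1/h, `a0` in ppm).
#' @export
tidy.aer_fit <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = c("k", "a0"),
    estimate = c(x$k, x$a0),
    std.error = c(x$k_se, x$a0_se),
    conf.low = c(x$k - z * x$k_se, x$a0 - z * x$a0_se),
    conf.high = c(x$k + z * x$k_se, x$a0 + z * x$a0_se)
  )
}

#' @rdname tidy.aer_fit
#' @return For `glance()`: a one-row tibble of fit diagnostics.
#' @export
glance.aer_fit <- function(x, ...) {
  tibble(
    k = x$k, k_se = x$k_se, k_loglinear = x$k_loglinear,
    background = x$background, r.squared = x$r_squared,
    adequate = x$adequate, uniform = x$uniform, nobs = x$n
  )
}

#' Plot a fitted CO2 decay
#'
#' Observed room CO2 over the decay window with the fitted exponential and
#' the ambient background level.
#'
#' @param object An `aer_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aer_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dt_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$background, linetype = "dashed") +
    ggplot2::labs(
      x = "hours since source removal", y = expression(CO[2] ~ (ppm)),
      title = sprintf("CO2 decay: k = %.2f /h (R² = %.3f)",
                      object$k, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Was the CO2 peak elevated enough for a decay experiment?
#'
#' The field protocol requires the peak to reach at least four times the
#' background before starting the decay.
#'
#' @param experiment A `decay_experiment`.
#' @param threshold Required peak/background multiple (default 4, boundary
#'   inclusive).
#' @return `TRUE` if the peak reaches `threshold` times background.
#' @export
elevation_check <- function(experiment, threshold = 4) {
  stopifnot(inherits(experiment, "decay_experiment"))
  merged <- check_uniformity(experiment$room_monitors)$merged
  ok <- merged[merged$quality == "ok", ]
  if (nrow(ok) == 0) abort("no usable room samples")
  peak <- max(ok$value)
  bg <- decay_background(experiment)
  peak >= threshold * bg
}
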