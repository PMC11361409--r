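#' Estimate infiltration from windowed indoor/outdoor concentrations
#'
#' Infiltration is the ratio of indoor to outdoor concentration computed on
#' aligned 30-min averaging windows, under the assumption that the indoor
#' pollutant is of outdoor origin. Windows with outdoor means at or below a
#' floor are excluded to avoid near-zero denominators. The aggregate is the
#' mean of window ratios (the median is reported alongside), with a
#' nonparametric bootstrap confidence interval over windows.
#'
#' @param indoor,outdoor Windowed series from [window_average()], on the
#'   same window grid.
#' @param hepa_state `"off"` or `"on"` — the filter state this period
#'   represents.
#' @param channel Optional channel label carried into the result.
#' @param floor Minimum outdoor window mean for a window to be usable
#'   (default 50, appropriate for particle counts in #/cc; use ~0.05 for
#'   black carbon in ug/m^3).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `infiltration_estimate` object; `tidy()` returns its one-row
#'   summary.
#' @export
compute_infiltration <- function(indoor, outdoor, hepa_state = c("off", "on"),
                                 channel = NULL, floor = 50, n_boot = 2000,
                                 conf = 0.95, seed = NULL) {
  hepa_state <- arg_match(hepa_state)
  win <- inner_join(
    dplyr::select(indoor, "window_start", indoor = "mean", in_usable = "usable"),
    dplyr::select(outdoor, "window_start", outdoor = "mean", out_usable = "usable"),
    by = "window_start"
  ) |>
    filter(.data$in_usable, .data$out_usable, .data$outdoor > floor) |>
    mutate(ratio = .data$indoor / .data$outdoor) |>
    select("window_start", "indoor", "outdoor", "ratio")
  if (nrow(win) < 4) {
    abort(sprintf("only %d usable aligned windows (need >= 4)", nrow(win)))
  }
  point <- mean(win$ratio)
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(sample(win$ratio, replace = TRUE))
    }, numeric(1))
    quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  structure(
    list(
      channel = channel, hepa_state = hepa_state, windows = win,
      point = point, median = median(win$ratio),
      ci_low = ci[1], ci_high = ci[2],
      n_windows = nrow(win), n_boot = n_boot, conf = conf
    ),
    class = "infiltration_estimate"
  )
}

#' @export
print.infiltration_estimate <- function(x, ...) {
  cat(sprintf(
    "<infiltration_estimate> %sHEPA %s: %.3f [%.3f, %.3f] (median %.3f, %d windows)\n",
    if (is.null(x$channel)) "" else paste0(x$channel, ", "),
    x$hepa_state, x$point, x$ci_low, x$ci_high, x$median, x$n_windows
  ))
  invisible(x)
}

#' @export
tidy.infiltration_estimate <- function(x, ...) {
  tibble(
    channel = x$channel %||% NA_character_, hepa_state = x$hepa_state,
    infiltration = x$point, median = x$median,
    ci_low = x$ci_low, ci_high = x$ci_high, n_windows = x$n_windows
  )
}

#' Plot windowed infiltration ratios
#'
#' @param object An `infiltration_estimate`.
#' @param ... Unused.
#' @return A ggplot object: per-window ratios over time with the aggregate
#'   and its bootstrap interval.
#' @export
autoplot.infiltration_estimate <- function(object, ...) {
  ggplot2::ggplot(object$windows,
                  ggplot2::aes(x = .data$window_start, y = .data$ratio)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = object$point, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$ci_low, object$ci_high),
                        colour = "firebrick", linetype = "dotted") +
    ggplot2::labs(
      x = NULL, y = "indoor / outdoor ratio",
      title = sprintf("Infiltration, HEPA %s: %.2f [%.2f, %.2f]",
                      object$hepa_state, object$point, object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' HEPA removal effectiveness from before/after infiltration
#'
#' Effectiveness is the fractional reduction in infiltration attributable to
#' the filter: `1 - infiltration_on / infiltration_off`. With full
#' `infiltration_estimate` inputs a bootstrap interval is computed by
#' resampling the filter-off and filter-on window sets; with bare numeric
#' infiltration values only the point estimate is returned.
#'
#' @param before Infiltration with the filter off: an
#'   `infiltration_estimate` or a single numeric ratio.
#' @param after Infiltration with the filter on, same type as `before`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A one-row tibble (class `effectiveness_result`): `channel`,
#'   `effectiveness`, `ci_low`, `ci_high`, `method = "ratio"`. Negative
#'   values indicate the filter period had higher infiltration.
#' @examples
#' compute_effectiveness(0.54, 0.09)  # 0.833: 83% removal
#' @export
compute_effectiveness <- function(before, after, n_boot = 2000, conf = 0.95,
                                  seed = NULL) {
  if (is.numeric(before) && is.numeric(after)) {
    stopifnot(length(before) == 1, length(after) == 1)
    if (before == 0) abort("`before` infiltration is zero; effectiveness undefined")
    return(structure(
      tibble(channel = NA_character_, effectiveness = 1 - after / before,
             ci_low = NA_real_, ci_high = NA_real_, method = "ratio"),
      class = c("effectiveness_result", "tbl_df", "tbl", "data.frame")
    ))
  }
  stopifnot(inherits(before, "infiltration_estimate"),
            inherits(after, "infiltration_estimate"))
  if (before$hepa_state != "off" || after$hepa_state != "on") {
    abort("`before` must be the HEPA-off estimate and `after` the HEPA-on estimate")
  }
  if (!identical(before$channel, after$channel)) {
    abort("`before` and `after` are different channels")
  }
  if (before$point == 0) abort("`before` infiltration is zero; effectiveness undefined")
  eff <- 1 - after$point / before$point
  ci <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      b <- mean(sample(before$windows$ratio, replace = TRUE))
      a <- mean(sample(after$windows$ratio, replace = TRUE))
      1 - a / b
    }, numeric(1))
    quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  structure(
    tibble(channel = before$channel %||% NA_character_, effectiveness = eff,
           ci_low = ci[1], ci_high = ci[2], method = "ratio"),
    class = c("effectiveness_result", "tbl_df", "tbl", "data.frame")
  )
}

#' One-sided Wilcoxon rank-sum comparison of infiltration ratios
#'
#' Tests whether infiltration before the filter intervention is
#' stochastically greater than after. The exact null distribution is used
#' for combined sample sizes up to 20 (absent ties); larger samples use the
#' normal approximation with tie correction.
#'
#' @param before,after Numeric vectors of window ratios (each length >= 4).
#' @param alternative Alternative hypothesis (default `"greater"`: before
#'   exceeds after).
#' @return A tibble with `statistic` (rank-sum W), `p_value` and `method`.
#' @export
wilcoxon_compare <- function(before, after, alternative = "greater") {
  if (length(before) < 4 || length(after) < 4) {
    abort("each group needs at least 4 values")
  }
  if (length(unique(c(before, after))) == 1) {
    warn("all values tied across both groups; comparison is uninformative")
    return(tibble(statistic = NA_real_, p_value = 1, method = "degenerate"))
  }
  n_total <- length(before) + length(after)
  has_ties <- anyDuplicated(c(before, after)) > 0
  exact <- n_total <= 20 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(before, after, alternative = alternative,
                exact = exact, correct = TRUE)
  )
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation"
  )
}

#' Pearson correlation of aligned indoor and outdoor windows
#'
#' Quantifies how closely the indoor signal tracks the outdoor driver;
#' strong coupling (high r) indicates infiltration-dominated indoor air,
#' and decoupling under filtration shows as a drop in r.
#'
#' @param indoor,outdoor Windowed series from [window_average()].
#' @return A tibble with `r`, `p_value` and `n`; `r` is `NA` (with a
#'   warning) when either input has zero variance.
#' @export
io_correlation <- function(indoor, outdoor) {
  win <- inner_join(
    dplyr::select(indoor, "window_start", indoor = "mean", in_usable = "usable"),
    dplyr::select(outdoor, "window_start", outdoor = "mean", out_usable = "usable"),
    by = "window_start"
  ) |> filter(.data$in_usable, .data$out_usable)
  if (nrow(win) < 4) abort("fewer than 4 aligned usable windows")
  if (sd(win$indoor) == 0 || sd(win$outdoor) == 0) {
    warn("zero variance in indoor or outdoor windows; correlation undefined")
    return(tibble(r = NA_real_, p_value = NA_real_, n = nrow(win)))
  }
  ct <- cor.test(win$indoor, win$outdoor, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(win))
}

#' Rolling indoor-outdoor correlation after a filter switch-off
#'
#' Tracks how quickly the indoor signal re-couples to the outdoor driver
#' after the HEPA unit is turned off: a rolling-window Pearson correlation
#' of the raw series is computed on a sliding grid starting at the
#' switch-off instant.
#'
#' @param indoor,outdoor Raw concentration series sharing a sampling grid.
#' @param hepa_off_time Instant the filter was switched off.
#' @param horizon Seconds after switch-off to examine (default 7200, 2 h).
#' @param window Correlation window, seconds (default 1800).
#' @param step Grid step, seconds (default 300).
#' @return A tibble (`elapsed_min`, `r`, `n`), one row per window start; if
#'   the series end before the horizon the table is truncated and attribute
#'   `truncated` is `TRUE`.
#' @export
lag_persistence <- function(indoor, outdoor, hepa_off_time, horizon = 7200,
                            window = 1800, step = 300) {
  check_series(indoor)
  check_series(outdoor)
  hepa_off_time <- as.POSIXct(hepa_off_time)
  joined <- inner_join(
    indoor[indoor$quality %in% c("ok", "substituted"), c("timestamp", "value")],
    outdoor[outdoor$quality %in% c("ok", "substituted"), c("timestamp", "value")],
    by = "timestamp", suffix = c("_in", "_out")
  )
  t_num <- as.numeric(joined$timestamp)
  t0 <- as.numeric(hepa_off_time)
  avail <- max(t_num) - t0
  truncated <- avail < horizon
  if (truncated) {
    warn("series end before the requested horizon; table truncated")
  }
  starts <- seq(0, max(0, min(horizon, avail) - window), by = step)
  rows <- purrr::map_dfr(starts, function(s) {
    sel <- t_num >= t0 + s & t_num < t0 + s + window
    x <- joined$value_in[sel]
    y <- joined$value_out[sel]
    r <- if (sum(sel) >= 4 && sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
    tibble(elapsed_min = s / 60, r = r, n = sum(sel))
  })
  attr(rows, "truncated") <- truncated
  rows
}
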