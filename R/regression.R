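#' Build the lagged log-log regression design
#'
#' Pairs each indoor 30-min window with the outdoor window one lag earlier
#' (outdoor peaks precede the indoor response), attaches a HEPA on/off
#' indicator and a school label, and takes natural logs. Windows with
#' non-positive indoor or outdoor means cannot enter a log model; they are
#' dropped and counted, and the design is flagged when more than 20% of its
#' rows drop (sessions dominated by indoor zeros may warrant exclusion).
#'
#' @param indoor,outdoor Windowed series from [window_average()] on the same
#'   grid.
#' @param hepa_intervals List of `(start, end)` pairs during which the
#'   filter ran, or `NULL` for never.
#' @param school School label for these windows.
#' @param lag Outdoor lag in seconds (default 1800 = one 30-min window).
#' @return A tibble (`window_start`, `log_indoor`, `log_outdoor_lagged`,
#'   `hepa`, `school`) with attributes `dropped_zero_rows` and `flagged`.
#'   Designs from several sessions can be combined with
#'   [dplyr::bind_rows()] before fitting.
#' @export
build_design <- function(indoor, outdoor, hepa_intervals, school,
                         lag = 1800) {
  rows <- inner_join(
    dplyr::select(indoor, "window_start", indoor = "mean", in_usable = "usable"),
    dplyr::select(outdoor, "window_start", outdoor = "mean", out_usable = "usable") |>
      mutate(window_start = .data$window_start + lag),
    by = "window_start"
  ) |> filter(.data$in_usable, .data$out_usable)
  if (nrow(rows) == 0) abort("no alignable indoor/outdoor window pairs at this lag")
  hepa_on <- rep(FALSE, nrow(rows))
  if (!is.null(hepa_intervals)) {
    mid <- as.numeric(rows$window_start) + 900
    for (iv in hepa_intervals) {
      hepa_on <- hepa_on | (mid >= as.numeric(as.POSIXct(iv[[1]])) &
                              mid < as.numeric(as.POSIXct(iv[[2]])))
    }
  }
  pos <- rows$indoor > 0 & rows$outdoor > 0
  dropped <- sum(!pos)
  if (!any(pos)) {
    abort(sprintf(
      "all %d rows dropped: non-positive indoor or outdoor window means cannot enter a log-log model",
      dropped
    ))
  }
  out <- tibble(
    window_start = rows$window_start[pos],
    log_indoor = log(rows$indoor[pos]),
    log_outdoor_lagged = log(rows$outdoor[pos]),
    hepa = as.integer(hepa_on[pos]),
    school = as.character(school)
  )
  attr(out, "dropped_zero_rows") <- dropped
  attr(out, "flagged") <- dropped > 0.2 * nrow(rows)
  if (attr(out, "flagged")) {
    warn(sprintf("%d of %d window pairs dropped for non-positive means; session flagged",
                 dropped, nrow(rows)))
  }
  out
}

#' Fit the lagged log-log indoor-on-outdoor model
#'
#' Ordinary least squares for
#' \deqn{\log C_{in} = \beta_0 + \beta_1 \log C_{out,lagged} + \beta_H \cdot HEPA + School}
#' with school as categorical fixed effects (reference level: first school
#' alphabetically) and natural logs throughout. The HEPA coefficient
#' measures the log-scale multiplicative effect of the filter on indoor
#' concentration at fixed outdoor concentration.
#'
#' @param design A design tibble from [build_design()] (possibly several
#'   sessions bound together).
#' @return A `hepa_loglog` fit object; see [tidy()], [glance()],
#'   [predict_indoor()] and [regression_effectiveness()].
#' @export
fit_loglog <- function(design) {
  need <- c("log_indoor", "log_outdoor_lagged", "hepa", "school")
  if (!all(need %in% names(design))) {
    abort(sprintf("design must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(design$log_indoor)) ||
      any(!is.finite(design$log_outdoor_lagged))) {
    abort("design contains non-finite log values")
  }
  schools <- sort(unique(design$school))
  d <- design |>
    mutate(school = factor(.data$school, levels = schools))
  n_par <- 2 + 1 + (length(schools) - 1) # intercept, slope, hepa, school contrasts
  if (nrow(d) < n_par + 5) {
    abort(sprintf("need at least %d rows to fit %d parameters", n_par + 5, n_par))
  }
  if (var(d$hepa) == 0) {
    abort("HEPA indicator is constant; beta_hepa is inestimable (rank-deficient design)")
  }
  form <- if (length(schools) > 1) {
    log_indoor ~ log_outdoor_lagged + hepa + school
  } else {
    log_indoor ~ log_outdoor_lagged + hepa
  }
  fit <- lm(form, data = d)
  if (anyNA(coef(fit))) {
    abort(sprintf("rank-deficient design; inestimable terms: %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  structure(
    list(model = fit, schools = schools, n = nrow(d),
         dropped_zero_rows = attr(design, "dropped_zero_rows") %||% 0L),
    class = "hepa_loglog"
  )
}

#' @export
print.hepa_loglog <- function(x, ...) {
  cf <- coef(x$model)
  cat(sprintf(
    "<hepa_loglog> n = %d, slope = %.3f, beta_hepa = %.3f (effectiveness %.1f%%), %d school(s)\n",
    x$n, cf[["log_outdoor_lagged"]], cf[["hepa"]],
    100 * (1 - exp(cf[["hepa"]])), length(x$schools)
  ))
  invisible(x)
}

#' Tidy the lagged log-log fit
#'
#' @param x A `hepa_loglog` fit.
#' @param ... Unused.
#' @return Coefficient tibble (`term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`); for `glance()`, a one-row model summary.
#' @export
tidy.hepa_loglog <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidy.hepa_loglog
#' @export
glance.hepa_loglog <- function(x, ...) {
  sm <- summary(x$model)
  tibble(
    r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma, nobs = x$n, dropped_zero_rows = x$dropped_zero_rows,
    n_schools = length(x$schools)
  )
}

#' Predict indoor concentration at a fixed outdoor level
#'
#' Evaluates the fitted log-log model at a fixed outdoor concentration
#' (default 5000 #/cc, a typical dataset median) for given school(s) and
#' filter states, exponentiating the linear predictor. The confidence
#' interval propagates the coefficient covariance through the linear
#' predictor before exponentiating.
#'
#' @param fit A `hepa_loglog` fit.
#' @param outdoor_level Fixed outdoor concentration, #/cc (default 5000).
#' @param school School label(s); default all schools in the fit.
#' @param hepa Filter states to predict (default both 0 and 1).
#' @param conf Confidence level (default 0.95).
#' @return A tibble (`school`, `hepa`, `outdoor_level`, `point`, `ci_low`,
#'   `ci_high`) in concentration units.
#' @export
predict_indoor <- function(fit, outdoor_level = 5000, school = NULL,
                           hepa = c(0L, 1L), conf = 0.95) {
  stopifnot(inherits(fit, "hepa_loglog"), outdoor_level > 0)
  school <- school %||% fit$schools
  unknown <- setdiff(school, fit$schools)
  if (length(unknown) > 0) {
    abort(sprintf("school(s) not in fit: %s", paste(unknown, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(school = school, hepa = as.integer(hepa))
  newdata <- tibble(
    log_outdoor_lagged = log(outdoor_level),
    hepa = grid$hepa,
    school = factor(grid$school, levels = fit$schools)
  )
  pr <- predict(fit$model, newdata = newdata, se.fit = TRUE)
  z <- qnorm(1 - (1 - conf) / 2)
  tibble(
    school = grid$school, hepa = grid$hepa, outdoor_level = outdoor_level,
    point = unname(exp(pr$fit)),
    ci_low = unname(exp(pr$fit - z * pr$se.fit)),
    ci_high = unname(exp(pr$fit + z * pr$se.fit))
  )
}

#' Regression-based HEPA removal effectiveness
#'
#' In the log-log model the filter multiplies indoor concentration by
#' `exp(beta_hepa)` at fixed outdoor concentration, so removal
#' effectiveness is `1 - exp(beta_hepa)`. The interval transforms the Wald
#' interval of `beta_hepa` (delta method on the coefficient scale).
#'
#' @param fit A `hepa_loglog` fit.
#' @param conf Confidence level (default 0.95).
#' @return A one-row `effectiveness_result` tibble with
#'   `method = "regression"`.
#' @export
regression_effectiveness <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "hepa_loglog"))
  sm <- summary(fit$model)$coefficients
  b <- sm["hepa", 1]
  se <- sm["hepa", 2]
  z <- qnorm(1 - (1 - conf) / 2)
  structure(
    tibble(
      channel = NA_character_,
      effectiveness = 1 - exp(b),
      ci_low = 1 - exp(b + z * se),
      ci_high = 1 - exp(b - z * se),
      method = "regression"
    ),
    class = c("effectiveness_result", "tbl_df", "tbl", "data.frame")
  )
}
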