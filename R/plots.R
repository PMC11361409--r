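#' Plot one or more concentration series
#'
#' Line plot of concentration against time, coloured by location, with
#' non-ok samples marked. Several series can be passed and are row-bound;
#' channels are faceted.
#'
#' @param ... Concentration-series tibbles.
#' @param mark_quality Mark samples whose quality is not `"ok"`? Default
#'   `TRUE`.
#' @return A ggplot object.
#' @export
plot_series <- function(..., mark_quality = TRUE) {
  all <- bind_rows(lapply(list(...), function(s) {
    check_series(s)
    s
  }))
  p <- ggplot2::ggplot(
    all[all$quality %in% c("ok", "substituted"), ],
    ggplot2::aes(x = .data$timestamp, y = .data$value, colour = .data$location)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = "concentration", colour = NULL) +
    ggplot2::theme_minimal()
  flagged <- all[!all$quality %in% c("ok", "trimmed"), ]
  if (mark_quality && nrow(flagged) > 0 && any(flagged$quality == "substituted")) {
    p <- p + ggplot2::geom_point(
      data = flagged[flagged$quality == "substituted", ],
      shape = 1, size = 0.6
    )
  }
  p
}
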