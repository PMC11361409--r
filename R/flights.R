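#' Does a flight track enter the exposure geofence of a site?
#'
#' A flight counts as a near-site operation if any track point is below the
#' altitude ceiling and within the great-circle radius of the site — both
#' thresholds strict. Distances use the haversine formula on a sphere of
#' mean Earth radius 6371.0088 km.
#'
#' @param track Tibble of track points with `latitude`, `longitude`
#'   (degrees) and `altitude_m` columns.
#' @param site List or one-row data frame with `latitude` and `longitude`.
#' @param alt_ceiling Altitude ceiling in metres (default 750).
#' @param radius_m Radius in metres (default one statute mile, 1609.344 m).
#' @return `TRUE` if any point satisfies both thresholds. All-missing
#'   altitudes give `FALSE` with a warning.
#' @export
flight_near_site <- function(track, site, alt_ceiling = 750,
                             radius_m = MILE_M) {
  stopifnot(nrow(track) >= 1)
  if (all(is.na(track$altitude_m))) {
    warn("all altitudes missing; flight cannot be assessed and is not counted")
    return(FALSE)
  }
  d <- geosphere::distHaversine(
    cbind(track$longitude, track$latitude),
    c(site$longitude, site$latitude),
    r = EARTH_RADIUS_M
  )
  any(track$altitude_m < alt_ceiling & d < radius_m, na.rm = TRUE)
}

#' Count flight operations near school sites
#'
#' Applies the altitude/radius geofence to every flight at every site and
#' tabulates counts by site, airport and operation. Each `flight_id` is
#' counted at most once per site; a flight near two sites contributes to
#' both. Totals over operations (`operation = "total"`) and over airports
#' (`airport = "all"`) are included.
#'
#' @param tracks Tibble of track points: `flight_id`, `airport`,
#'   `operation` (`"arrival"`/`"departure"`), `latitude`, `longitude`,
#'   `altitude_m` (a `time` column is allowed and ignored).
#' @param sites Tibble of sites: `school_id`, `latitude`, `longitude`.
#' @param alt_ceiling,radius_m Geofence thresholds (defaults 750 m and one
#'   mile).
#' @return A tibble (`school_id`, `airport`, `operation`, `n`) over the full
#'   site x airport x operation grid, including the `"total"`/`"all"`
#'   margins.
#' @export
count_flights <- function(tracks, sites, alt_ceiling = 750,
                          radius_m = MILE_M) {
  stopifnot(all(c("school_id", "latitude", "longitude") %in% names(sites)))
  airports <- sort(unique(tracks$airport))
  if (length(airports) == 0) airports <- character()
  ops <- c("arrival", "departure")

  meta <- distinct(tracks, .data$flight_id, .data$airport, .data$operation)
  if (anyDuplicated(meta$flight_id) > 0) {
    warn("flight_id(s) with conflicting airport/operation labels; first occurrence used")
    meta <- meta[!duplicated(meta$flight_id), ]
  }

  hits <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    if (nrow(tracks) == 0) {
      return(tibble(school_id = character(), flight_id = character()))
    }
    d <- geosphere::distHaversine(
      cbind(tracks$longitude, tracks$latitude),
      c(site$longitude, site$latitude),
      r = EARTH_RADIUS_M
    )
    in_fence <- !is.na(tracks$altitude_m) &
      tracks$altitude_m < alt_ceiling & d < radius_m
    tibble(school_id = site$school_id,
           flight_id = unique(tracks$flight_id[in_fence]))
  })

  cells <- hits |>
    inner_join(meta, by = "flight_id") |>
    dplyr::count(.data$school_id, .data$airport, .data$operation, name = "n")

  grid <- tidyr::expand_grid(
    school_id = sites$school_id, airport = airports, operation = ops
  )
  base <- left_join(grid, cells, by = c("school_id", "airport", "operation")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))

  op_tot <- base |>
    group_by(.data$school_id, .data$airport) |>
    summarise(operation = "total", n = sum(.data$n), .groups = "drop")
  apt_tot <- bind_rows(base, op_tot) |>
    group_by(.data$school_id, .data$operation) |>
    summarise(airport = "all", n = sum(.data$n), .groups = "drop")

  bind_rows(base, op_tot, apt_tot) |>
    select("school_id", "airport", "operation", "n") |>
    arrange(.data$school_id, .data$airport, .data$operation)
}

#' Summarise per-site flight counts across a group of schools
#'
#' Median and 25th–75th percentiles (linear interpolation, quantile type 7)
#' of per-site counts for each airport/operation cell.
#'
#' @param counts Output of [count_flights()].
#' @param sites Optional character vector of `school_id`s defining the group
#'   (default: all sites present).
#' @return A tibble (`airport`, `operation`, `median`, `q25`, `q75`,
#'   `n_sites`).
#' @export
summarize_counts <- function(counts, sites = NULL) {
  if (!is.null(sites)) {
    if (length(sites) == 0) abort("site group is empty")
    counts <- filter(counts, .data$school_id %in% sites)
    if (nrow(counts) == 0) abort("no counts for the requested sites")
  }
  counts |>
    group_by(.data$airport, .data$operation) |>
    summarise(
      median = median(.data$n),
      q25 = quantile(.data$n, 0.25, names = FALSE, type = 7),
      q75 = quantile(.data$n, 0.75, names = FALSE, type = 7),
      n_sites = dplyr::n(),
      .groups = "drop"
    )
}
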