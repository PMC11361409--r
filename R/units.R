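#' Unit conversions used in room and air-cleaner metadata
#'
#' Field metadata for US school buildings typically reports room volumes in
#' cubic feet and clean-air delivery rates (CADR) in cubic feet per minute
#' (CFM); the mass-balance model works in SI units.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' ft3_to_m3(8725.3)   # a typical classroom, ~247 m^3
#' cfm_to_m3h(500)     # a portable HEPA unit on high, ~849.5 m^3/h
#' @name units
NULL

#' @rdname units
#' @export
ft3_to_m3 <- function(x) x * 0.3048^3

#' @rdname units
#' @export
cfm_to_m3h <- function(x) x * 1.699011

# 1 statute mile in metres (geofence radius unit)
MILE_M <- 1609.344

# Mean Earth radius (m) for great-circle distances
EARTH_RADIUS_M <- 6371008.8
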