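# Geometric and kinematic primitives. All public interfaces take and return
# angles in degrees (compass convention, clockwise from true north); radians
# are used only inside function bodies.

EARTH_RADIUS_M <- 6371000

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# wrap an angle into [0, 360)
.wrap360 <- function(x) ((x %% 360) + 360) %% 360

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("non-finite or non-numeric value in '", name, "'", call. = FALSE)
  }
  invisible(x)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorised over all
#' arguments (usual recycling rules).
#'
#' @param lat1,lon1 Coordinates of the first point, decimal degrees WGS84.
#' @param lat2,lon2 Coordinates of the second point, decimal degrees.
#' @return Distance in meters (non-negative; zero iff the points coincide).
#' @examples
#' great_circle_distance(36.0, -5.6, 36.0, -5.59)
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  .check_finite(lat1, "lat1"); .check_finite(lon1, "lon1")
  .check_finite(lat2, "lat2"); .check_finite(lon2, "lon2")
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial great-circle bearing from one point to another
#'
#' @inheritParams great_circle_distance
#' @return Bearing in degrees clockwise from true north, in `[0, 360)`.
#'   Identical points have no bearing and raise an error.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_finite(lat1, "lat1"); .check_finite(lon1, "lon1")
  .check_finite(lat2, "lat2"); .check_finite(lon2, "lon2")
  if (any(lat1 == lat2 & lon1 == lon2)) {
    stop("bearing undefined for identical points", call. = FALSE)
  }
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  .wrap360(.rad2deg(atan2(y, x)))
}

#' Minimal circular difference between a heading and a bearing
#'
#' Invariant to adding any multiple of 360 degrees to either argument and
#' symmetric in its arguments.
#'
#' @param heading Flight heading, degrees.
#' @param bearing Bearing to the target, degrees.
#' @return Angular deviation in degrees, in `[0, 180]`.
#' @export
angular_deviation <- function(heading, bearing) {
  .check_finite(heading, "heading")
  .check_finite(bearing, "bearing")
  d <- abs(.wrap360(heading) - .wrap360(bearing))
  pmin(d, 360 - d)
}

#' Facing-the-turbine indicator
#'
#' The binomial response of the avoidance models: 1 when the flight heading
#' deviates strictly less than `threshold` degrees from the bearing to the
#' nearest turbine, 0 otherwise. With headings uniform on the circle the
#' expected value is `threshold / 180` (1/3 at the default 60 degrees).
#'
#' @param deviation Angular deviation in degrees, in `[0, 180]`.
#' @param threshold Facing half-angle in degrees; default 60.
#' @return Integer vector of 0/1.
#' @export
facing_indicator <- function(deviation, threshold = 60) {
  .check_finite(deviation, "deviation")
  if (any(deviation < 0 | deviation > 180)) {
    stop("'deviation' outside [0, 180]", call. = FALSE)
  }
  as.integer(deviation < threshold)
}

#' Wind component along the bearing to a target
#'
#' Scalar projection of the wind vector onto the bearing from the bird to the
#' nearest turbine. Wind direction uses the meteorological convention (the
#' direction the wind blows FROM); internally 180 degrees is added to obtain
#' the blowing-to direction. Positive values mean the wind pushes the bird
#' toward the target (tailwind toward the turbine).
#'
#' @param speed Wind speed, m/s, non-negative.
#' @param direction_from Meteorological wind direction, degrees.
#' @param bearing Bearing from bird to target, degrees.
#' @return Signed component in m/s, with absolute value at most `speed`.
#' @export
wind_component_towards <- function(speed, direction_from, bearing) {
  .check_finite(speed, "speed")
  .check_finite(direction_from, "direction_from")
  .check_finite(bearing, "bearing")
  if (any(speed < 0)) stop("'speed' must be non-negative", call. = FALSE)
  blowing_to <- direction_from + 180
  speed * cos(.deg2rad(blowing_to - bearing))
}

#' Maximum turbine height (top of the rotor-swept zone)
#'
#' Hub height plus rotor radius when the hub height is known; otherwise the
#' 1.5 x rotor-diameter rule (hub height approximately equal to rotor
#' diameter, as holds for the turbine models in the study region).
#'
#' @param rotor_diameter Rotor diameter in meters, positive.
#' @param hub_height Hub height in meters, or `NA` when unknown.
#' @return Maximum height in meters.
#' @examples
#' max_turbine_height(80)            # 120
#' max_turbine_height(80, hub_height = 80)  # 120
#' @export
max_turbine_height <- function(rotor_diameter, hub_height = NA_real_) {
  .check_finite(rotor_diameter, "rotor_diameter")
  if (any(rotor_diameter <= 0)) {
    stop("'rotor_diameter' must be positive", call. = FALSE)
  }
  n <- max(length(rotor_diameter), length(hub_height))
  rotor_diameter <- rep_len(rotor_diameter, n)
  hub_height <- rep_len(as.numeric(hub_height), n)
  ifelse(is.na(hub_height), 1.5 * rotor_diameter,
         hub_height + rotor_diameter / 2)
}

#' Flight-height classes
#'
#' Factor levels used throughout: `low` (up to the maximum turbine height,
#' the rotor-swept zone and below), `medium` (up to twice the maximum turbine
#' height) and `high` (above that).
#'
#' @export
height_class_levels <- function() c("low", "medium", "high")

#' Classify flight height relative to a turbine
#'
#' `low` iff `height_agl <= max_height`, `medium` iff
#' `max_height < height_agl <= 2 * max_height`, `high` above. Negative
#' heights above ground (GPS error) are clamped into `low`; the number of
#' clamped values is attached as attribute `n_negative_clamped`.
#'
#' @param height_agl Flight height above ground, meters.
#' @param max_height Maximum turbine height, meters, positive.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
height_class <- function(height_agl, max_height) {
  .check_finite(height_agl, "height_agl")
  .check_finite(max_height, "max_height")
  if (any(max_height <= 0)) stop("'max_height' must be positive", call. = FALSE)
  n_neg <- sum(height_agl < 0)
  if (n_neg > 0) {
    warning(n_neg, " negative height(s) above ground clamped to the low class")
    height_agl <- pmax(height_agl, 0)
  }
  cls <- ifelse(height_agl <= max_height, "low",
                ifelse(height_agl <= 2 * max_height, "medium", "high"))
  out <- factor(cls, levels = height_class_levels())
  attr(out, "n_negative_clamped") <- n_neg
  out
}
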