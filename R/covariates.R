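# Physical covariate layers: orographic and thermal uplift, terrain
# derivatives, 500 m grid aggregation, and time-matching of wind records.

#' Orographic uplift from terrain and wind
#'
#' Vertical air velocity generated by wind deflected up a slope:
#' `w = wind_speed * sin(slope) * max(0, cos(aspect - wind_direction_from))`,
#' where `aspect` is the downslope-facing compass direction of the terrain
#' cell. Zero on flat ground and on the lee side; never exceeds the wind
#' speed.
#'
#' @param wind_speed Wind speed, m/s, non-negative.
#' @param wind_direction_from Meteorological wind direction, degrees.
#' @param aspect Terrain aspect (downslope-facing direction), degrees.
#' @param slope Terrain slope, degrees in `[0, 90)`.
#' @return Uplift velocity, m/s, non-negative.
#' @export
orographic_uplift <- function(wind_speed, wind_direction_from, aspect, slope) {
  .check_finite(wind_speed, "wind_speed")
  .check_finite(wind_direction_from, "wind_direction_from")
  .check_finite(aspect, "aspect")
  .check_finite(slope, "slope")
  if (any(wind_speed < 0)) stop("'wind_speed' must be non-negative", call. = FALSE)
  if (any(slope < 0 | slope >= 90)) stop("'slope' outside [0, 90)", call. = FALSE)
  wind_speed * sin(.deg2rad(slope)) *
    pmax(0, cos(.deg2rad(aspect - wind_direction_from)))
}

#' Thermal uplift from surface temperature
#'
#' Convective velocity scale
#' `w* = (g * z_i * max(0, T_s - T_ref) / T_ref)^(1/3)` with
#' `g = 9.81 m/s^2`. Zero when the surface is no warmer than the reference;
#' strictly increasing in the surface temperature above it.
#'
#' @param surface_temp Land-surface temperature, Kelvin.
#' @param reference_temp Reference (e.g. domain-mean) temperature, Kelvin.
#' @param boundary_layer_height Convective boundary-layer depth `z_i`,
#'   meters; default 1000.
#' @return Uplift velocity, m/s, non-negative.
#' @export
thermal_uplift <- function(surface_temp, reference_temp,
                           boundary_layer_height = 1000) {
  .check_finite(surface_temp, "surface_temp")
  .check_finite(reference_temp, "reference_temp")
  if (any(surface_temp <= 0) || any(reference_temp <= 0)) {
    stop("temperatures must be positive (Kelvin)", call. = FALSE)
  }
  if (any(boundary_layer_height <= 0)) {
    stop("'boundary_layer_height' must be positive", call. = FALSE)
  }
  g <- 9.81
  (g * boundary_layer_height *
     pmax(0, surface_temp - reference_temp) / reference_temp)^(1 / 3)
}

#' Terrain aspect and slope from an elevation grid
#'
#' Horn's eight-neighbour finite differences on a regular grid. The matrix is
#' oriented with row 1 the northernmost row and column 1 the westernmost
#' column; `cell_size` is the grid spacing in meters. Border cells cannot be
#' evaluated and are returned as `NA`. Aspect is the downslope-facing compass
#' direction and is `NA` where the slope is zero.
#'
#' @param elevation Numeric matrix of elevations in meters, at least 3 x 3.
#' @param cell_size Grid spacing, meters.
#' @return List with matrices `slope` (degrees) and `aspect` (degrees,
#'   compass convention).
#' @export
aspect_slope_from_grid <- function(elevation, cell_size) {
  if (!is.matrix(elevation) || nrow(elevation) < 3 || ncol(elevation) < 3) {
    stop("'elevation' must be a matrix of at least 3 x 3", call. = FALSE)
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    stop("'cell_size' must be a positive number of meters", call. = FALSE)
  }
  nr <- nrow(elevation); nc <- ncol(elevation)
  slope <- matrix(NA_real_, nr, nc)
  aspect <- matrix(NA_real_, nr, nc)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  # Horn kernel; rows run north -> south, so +y (north) is decreasing row
  a <- elevation[i - 1, j - 1, drop = FALSE]; b <- elevation[i - 1, j, drop = FALSE]
  cc <- elevation[i - 1, j + 1, drop = FALSE]
  d <- elevation[i, j - 1, drop = FALSE];     f <- elevation[i, j + 1, drop = FALSE]
  g <- elevation[i + 1, j - 1, drop = FALSE]; h <- elevation[i + 1, j, drop = FALSE]
  k <- elevation[i + 1, j + 1, drop = FALSE]
  dzdx <- ((cc + 2 * f + k) - (a + 2 * d + g)) / (8 * cell_size)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + k)) / (8 * cell_size)
  sl <- atan(sqrt(dzdx^2 + dzdy^2))
  # downslope direction: opposite of the gradient; compass angle
  asp <- .wrap360(.rad2deg(atan2(-dzdx, -dzdy)))
  asp[sl == 0] <- NA_real_
  slope[i, j] <- .rad2deg(sl)
  aspect[i, j] <- asp
  list(slope = slope, aspect = aspect)
}

#' Aggregate point values to a square grid
#'
#' Arithmetic mean of values per cell; points are assigned to cells by floor
#' division of their metric coordinates by the cell size (the convention used
#' for the 500 x 500 m uplift grids).
#'
#' @param x,y Metric coordinates of the points, meters.
#' @param values Values to average.
#' @param cell_size Cell edge length, meters; default 500.
#' @return Data frame with `cell_x`, `cell_y` (cell indices), `x`, `y` (cell
#'   center coordinates), `mean` and `n`. Empty input gives an empty frame.
#' @export
aggregate_to_grid <- function(x, y, values, cell_size = 500) {
  if (length(x) == 0) {
    return(data.frame(cell_x = integer(), cell_y = integer(),
                      x = numeric(), y = numeric(),
                      mean = numeric(), n = integer()))
  }
  .check_finite(x, "x"); .check_finite(y, "y"); .check_finite(values, "values")
  cx <- floor(x / cell_size); cy <- floor(y / cell_size)
  key <- paste(cx, cy, sep = ":")
  agg <- tapply(values, key, mean)
  cnt <- tapply(values, key, length)
  parts <- do.call(rbind, strsplit(names(agg), ":", fixed = TRUE))
  out <- data.frame(
    cell_x = as.integer(parts[, 1]),
    cell_y = as.integer(parts[, 2]),
    mean = as.numeric(agg),
    n = as.integer(cnt)
  )
  out$x <- (out$cell_x + 0.5) * cell_size
  out$y <- (out$cell_y + 0.5) * cell_size
  out <- out[order(out$cell_x, out$cell_y), c("cell_x", "cell_y", "x", "y", "mean", "n")]
  rownames(out) <- NULL
  out
}

#' Match timestamps to the nearest wind record
#'
#' Wind is recorded on a fixed schedule (every 10 min at the study's weather
#' stations); each query timestamp is matched to the record nearest in time,
#' ties broken toward the earlier record. Matches farther than `max_gap`
#' seconds are flagged as missing covariates (index `NA`).
#'
#' @param timestamps `POSIXct` vector of query times.
#' @param wind Data frame with columns `timestamp` (`POSIXct`, sorted),
#'   `direction_from` and `speed`.
#' @param max_gap Staleness limit in seconds; default 3600 (60 min).
#' @return Data frame with one row per query: `direction_from`, `speed`,
#'   `gap_s` and logical `missing`.
#' @export
match_wind <- function(timestamps, wind, max_gap = 3600) {
  if (is.null(wind) || nrow(wind) == 0) {
    stop("wind series is empty", call. = FALSE)
  }
  wt <- as.numeric(wind$timestamp)
  if (is.unsorted(wt)) stop("wind series must be sorted by time", call. = FALSE)
  qt <- as.numeric(timestamps)
  # index of last record <= query
  lo <- findInterval(qt, wt)
  hi <- pmin(lo + 1, length(wt))
  lo <- pmax(lo, 1)
  gap_lo <- abs(qt - wt[lo])
  gap_hi <- abs(wt[hi] - qt)
  use_lo <- gap_lo <= gap_hi  # tie -> earlier record
  idx <- ifelse(use_lo, lo, hi)
  gap <- pmin(gap_lo, gap_hi)
  missing <- gap > max_gap
  idx[missing] <- NA_integer_
  data.frame(
    direction_from = wind$direction_from[idx],
    speed = wind$speed[idx],
    gap_s = gap,
    missing = missing
  )
}
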