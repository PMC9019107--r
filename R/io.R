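# CSV dialects: Movebank-style tracks, turbine and wind tables, terrain
# grids. All timestamps ISO 8601 UTC.

.parse_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  if (any(is.na(out) & !is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))[1]
    stop("unparseable timestamp at row ", bad, ": '", x[bad], "'", call. = FALSE)
  }
  out
}

.format_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

# Movebank column name -> internal name
.track_col_map <- c(
  "individual-local-identifier" = "bird_id",
  "timestamp" = "timestamp",
  "location-long" = "lon",
  "location-lat" = "lat",
  "height-above-ground" = "height_agl",
  "ground-speed" = "ground_speed",
  "heading" = "heading",
  "sex" = "sex",
  "age" = "age"
)

#' Validate a track table
#'
#' Checks column presence, coordinate, heading and speed ranges. On failure
#' the error names the first offending row and column.
#'
#' @param tracks Data frame with internal track columns (`bird_id`,
#'   `timestamp`, `lon`, `lat`, `height_agl`, `ground_speed`, `heading`).
#' @return The input, invisibly, on success.
#' @export
validate_tracks <- function(tracks) {
  .require_columns(tracks, c("bird_id", "timestamp", "lon", "lat",
                             "height_agl", "ground_speed", "heading"),
                   "track table")
  checks <- list(
    lat = function(x) !is.na(x) & abs(x) <= 90,
    lon = function(x) !is.na(x) & abs(x) <= 180,
    heading = function(x) is.na(x) | (x >= 0 & x < 360),
    ground_speed = function(x) is.na(x) | x >= 0
  )
  for (col in names(checks)) {
    ok <- checks[[col]](tracks[[col]])
    if (!all(ok)) {
      stop("invalid value in column '", col, "' at row ", which(!ok)[1],
           ": ", tracks[[col]][which(!ok)[1]], call. = FALSE)
    }
  }
  invisible(tracks)
}

#' Read a Movebank-dialect track CSV
#'
#' Expects the Movebank column names `individual-local-identifier`,
#' `timestamp`, `location-long`, `location-lat`, `height-above-ground`,
#' `ground-speed`, `heading`, plus optional `sex` and `age`. Internal column
#' names are returned; rows are ordered by bird and time.
#'
#' @param path Path to the CSV file.
#' @return Data frame of track points.
#' @export
read_tracks <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .require_columns(raw, setdiff(names(.track_col_map), c("sex", "age")),
                   "track CSV")
  present <- intersect(names(.track_col_map), names(raw))
  df <- raw[present]
  names(df) <- .track_col_map[present]
  if (nrow(df) > 0) {
    df$timestamp <- .parse_time(df$timestamp)
    df$bird_id <- as.character(df$bird_id)
    validate_tracks(df)
    df <- df[order(df$bird_id, df$timestamp), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df$timestamp <- as.POSIXct(character(), tz = "UTC")
  }
  df
}

#' Write a track table in the Movebank dialect
#'
#' @param tracks Track data frame (internal column names).
#' @param path Output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  inv <- names(.track_col_map); names(inv) <- unname(.track_col_map)
  out <- tracks[intersect(names(inv), names(tracks))]
  out$timestamp <- .format_time(out$timestamp)
  names(out) <- inv[names(out)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a turbine table
#'
#' Columns `turbine_id`, `lon`, `lat`, `rotor_diameter_m` and optional
#' `hub_height_m` (blank when unknown). The derived maximum turbine height
#' (hub + rotor radius, or 1.5 x rotor diameter when the hub height is
#' absent) is appended as `max_height`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of turbines with a `max_height` column.
#' @export
read_turbines <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(raw, c("turbine_id", "lon", "lat", "rotor_diameter_m"),
                   "turbine CSV")
  df <- data.frame(
    turbine_id = as.character(raw$turbine_id),
    lon = raw$lon, lat = raw$lat,
    rotor_diameter = raw$rotor_diameter_m,
    hub_height = if ("hub_height_m" %in% names(raw))
      as.numeric(raw$hub_height_m) else NA_real_
  )
  df$max_height <- max_turbine_height(df$rotor_diameter, df$hub_height)
  df
}

#' Write a turbine table
#' @param turbines Turbine data frame.
#' @param path Output CSV path.
#' @export
write_turbines <- function(turbines, path) {
  out <- data.frame(
    turbine_id = turbines$turbine_id,
    lon = turbines$lon, lat = turbines$lat,
    rotor_diameter_m = turbines$rotor_diameter,
    hub_height_m = turbines$hub_height
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a wind series
#'
#' Columns `timestamp`, `wind_direction_deg` (meteorological, FROM) and
#' `wind_speed_ms`. Returned sorted by time with internal names
#' `timestamp`, `direction_from`, `speed`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of wind records.
#' @export
read_wind <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(raw, c("timestamp", "wind_direction_deg", "wind_speed_ms"),
                   "wind CSV")
  df <- data.frame(
    timestamp = .parse_time(raw$timestamp),
    direction_from = raw$wind_direction_deg,
    speed = raw$wind_speed_ms
  )
  if (any(df$speed < 0, na.rm = TRUE)) stop("negative wind speed", call. = FALSE)
  df[order(df$timestamp), , drop = FALSE]
}

#' Write a wind series
#' @param wind Wind data frame (internal names).
#' @param path Output CSV path.
#' @export
write_wind <- function(wind, path) {
  out <- data.frame(
    timestamp = .format_time(wind$timestamp),
    wind_direction_deg = wind$direction_from,
    wind_speed_ms = wind$speed
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a terrain grid
#'
#' Headered CSV with one row per cell: `cell_id`, `lon`, `lat`, `aspect_deg`,
#' `slope_deg`, `surface_temp_k` (blank allowed).
#'
#' @param path Path to the CSV file.
#' @return Data frame of terrain cells with internal names.
#' @export
read_terrain <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(raw, c("cell_id", "lon", "lat", "aspect_deg", "slope_deg"),
                   "terrain CSV")
  data.frame(
    cell_id = as.character(raw$cell_id),
    lon = raw$lon, lat = raw$lat,
    aspect = as.numeric(raw$aspect_deg),
    slope = as.numeric(raw$slope_deg),
    surface_temp = if ("surface_temp_k" %in% names(raw))
      as.numeric(raw$surface_temp_k) else NA_real_
  )
}

#' Write a terrain grid
#' @param terrain Terrain data frame (internal names).
#' @param path Output CSV path.
#' @export
write_terrain <- function(terrain, path) {
  out <- data.frame(
    cell_id = terrain$cell_id,
    lon = terrain$lon, lat = terrain$lat,
    aspect_deg = terrain$aspect,
    slope_deg = terrain$slope,
    surface_temp_k = terrain$surface_temp
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Local equirectangular projection around a reference point; adequate for the
# few-km extents the pipeline works at.
.lonlat_to_xy <- function(lon, lat, lon0, lat0) {
  kx <- EARTH_RADIUS_M * pi / 180 * cos(.deg2rad(lat0))
  ky <- EARTH_RADIUS_M * pi / 180
  list(x = (lon - lon0) * kx, y = (lat - lat0) * ky)
}

.xy_to_lonlat <- function(x, y, lon0, lat0) {
  kx <- EARTH_RADIUS_M * pi / 180 * cos(.deg2rad(lat0))
  ky <- EARTH_RADIUS_M * pi / 180
  list(lon = lon0 + x / kx, lat = lat0 + y / ky)
}
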