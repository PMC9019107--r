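# Data-preparation chain: flight filtering, high-frequency thinning,
# nearest-turbine search, covariate joining, response construction and
# analysis-subset extraction.

.new_filter_report <- function(input, dropped = list(), retained) {
  stopifnot(sum(unlist(dropped)) + retained == input)
  structure(list(input = input, dropped = dropped, retained = retained),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:", x$input, "records in,", x$retained, "retained\n")
  for (nm in names(x$dropped)) {
    cat("  dropped (", nm, "): ", x$dropped[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Combine filter reports sequentially
#' @param ... `filter_report` objects in pipeline order.
#' @return A single `filter_report` covering the whole chain.
#' @export
combine_filter_reports <- function(...) {
  reps <- list(...)
  dropped <- do.call(c, lapply(reps, function(r) r$dropped))
  .new_filter_report(reps[[1]]$input, dropped, reps[[length(reps)]]$retained)
}

#' Keep only locations of flying birds
#'
#' Records with ground speed below 1 m/s (birds perched or soaring in place)
#' are excluded; records with missing speed are dropped and counted
#' separately.
#'
#' @param tracks Track data frame.
#' @param min_speed Flight-speed threshold in m/s; default 1.
#' @return List with `tracks` (kept rows) and `report` (a `filter_report`).
#' @export
filter_flying <- function(tracks, min_speed = 1) {
  n <- nrow(tracks)
  if (n == 0) {
    return(list(tracks = tracks,
                report = .new_filter_report(0, list(not_flying = 0,
                                                    missing_speed = 0), 0)))
  }
  miss <- is.na(tracks$ground_speed)
  slow <- !miss & tracks$ground_speed < min_speed
  keep <- !miss & !slow
  list(
    tracks = tracks[keep, , drop = FALSE],
    report = .new_filter_report(
      n, list(not_flying = sum(slow), missing_speed = sum(miss)), sum(keep))
  )
}

#' Thin high-frequency (1 Hz burst) records
#'
#' Greedy per-bird thinning: walking each bird's track in time order, a
#' record is dropped when its gap to the previously retained record of the
#' same bird is shorter than `min_interval` seconds. This removes 1 Hz burst
#' data while leaving 10 s and slower regimes untouched.
#'
#' @param tracks Track data frame, chronologically ordered within bird.
#' @param min_interval Minimum inter-fix interval in seconds; default 5.
#' @return List with `tracks` and `report`.
#' @export
exclude_high_frequency <- function(tracks, min_interval = 5) {
  n <- nrow(tracks)
  if (n == 0) {
    return(list(tracks = tracks,
                report = .new_filter_report(0, list(high_frequency = 0), 0)))
  }
  ord <- order(tracks$bird_id, tracks$timestamp)
  tracks <- tracks[ord, , drop = FALSE]
  keep <- logical(n)
  for (b in unique(tracks$bird_id)) {
    idx <- which(tracks$bird_id == b)
    t <- as.numeric(tracks$timestamp[idx])
    last_kept <- -Inf
    for (k in seq_along(idx)) {
      if (t[k] - last_kept >= min_interval) {
        keep[idx[k]] <- TRUE
        last_kept <- t[k]
      }
    }
  }
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(tracks = out,
       report = .new_filter_report(n, list(high_frequency = sum(!keep)),
                                   sum(keep)))
}

#' Nearest turbine to each point
#'
#' Minimal great-circle distance over the turbine set; ties (within 1e-9 m)
#' broken by lexicographically smallest turbine id.
#'
#' @param lat,lon Point coordinates, degrees (vectorised).
#' @param turbines Turbine data frame (`turbine_id`, `lon`, `lat`, ...).
#' @return Data frame with `turbine_id`, `distance` (m) and `bearing`
#'   (degrees) per point.
#' @export
nearest_turbine <- function(lat, lon, turbines) {
  if (is.null(turbines) || nrow(turbines) == 0) {
    stop("turbine set is empty", call. = FALSE)
  }
  ord <- order(turbines$turbine_id)  # so which.min picks the smallest id on ties
  turbines <- turbines[ord, , drop = FALSE]
  np <- length(lat); nt <- nrow(turbines)
  dmat <- matrix(NA_real_, np, nt)
  for (j in seq_len(nt)) {
    dmat[, j] <- great_circle_distance(lat, lon, turbines$lat[j], turbines$lon[j])
  }
  # tie tolerance: snap distances within 1e-9 m of the row minimum
  dmin <- apply(dmat, 1, min)
  jmin <- apply(dmat <= dmin + 1e-9, 1, which.max)
  bearing <- initial_bearing(lat, lon, turbines$lat[jmin], turbines$lon[jmin])
  data.frame(
    turbine_id = turbines$turbine_id[jmin],
    distance = dmat[cbind(seq_len(np), jmin)],
    bearing = bearing
  )
}

# nearest terrain cell (by center) for each query point
.nearest_terrain_cell <- function(lat, lon, terrain) {
  np <- length(lat); nc <- nrow(terrain)
  idx <- integer(np)
  for (i in seq_len(np)) {
    d <- great_circle_distance(lat[i], lon[i], terrain$lat, terrain$lon)
    idx[i] <- which.min(d)
  }
  idx
}

#' Annotate track points with turbine, wind and uplift covariates
#'
#' For every retained point: nearest turbine (id, distance, bearing), angular
#' deviation of the heading from that bearing, the binomial facing response,
#' flight-height class relative to the nearest turbine's maximum height, the
#' wind record matched by time, the signed wind component toward the turbine,
#' and orographic/thermal uplift evaluated at the terrain cell of the nearest
#' turbine (uplift is a property of the turbine location, not of the bird's
#' position). Points whose wind match exceeds the staleness limit are flagged
#' `covariate_missing` and are excluded by the model-subset helpers.
#'
#' Annotation is idempotent: all derived columns are recomputed from the raw
#' track fields, so annotating an annotated table changes nothing.
#'
#' @param tracks Track data frame (validated, filtered).
#' @param turbines Turbine data frame with `max_height` (see
#'   [read_turbines()]).
#' @param wind Wind data frame (`timestamp`, `direction_from`, `speed`).
#' @param terrain Optional terrain data frame (`cell_id`, `lon`, `lat`,
#'   `aspect`, `slope`, `surface_temp`); without it the uplift covariates are
#'   `NA` but not counted as missing.
#' @param max_wind_gap Wind staleness limit, seconds; default 3600.
#' @return The input with annotation columns appended (`nearest_turbine_id`,
#'   `distance_to_turbine`, `bearing_to_turbine`, `heading_deviation`,
#'   `facing`, `turbine_max_height`, `height_class`, `wind_component`,
#'   `orographic_uplift`, `thermal_uplift`, `covariate_missing`).
#' @export
annotate_tracks <- function(tracks, turbines, wind, terrain = NULL,
                            max_wind_gap = 3600) {
  validate_tracks(tracks)
  if (nrow(tracks) == 0) {
    for (col in c("nearest_turbine_id", "distance_to_turbine",
                  "bearing_to_turbine", "heading_deviation", "facing",
                  "turbine_max_height", "height_class", "wind_component",
                  "orographic_uplift", "thermal_uplift", "covariate_missing")) {
      tracks[[col]] <- vector(if (col == "covariate_missing") "logical"
                              else "numeric", 0)
    }
    return(tracks)
  }
  if (!"max_height" %in% names(turbines)) {
    turbines$max_height <- max_turbine_height(turbines$rotor_diameter,
                                              turbines$hub_height)
  }
  nt <- nearest_turbine(tracks$lat, tracks$lon, turbines)
  tracks$nearest_turbine_id <- nt$turbine_id
  tracks$distance_to_turbine <- nt$distance
  tracks$bearing_to_turbine <- nt$bearing
  tracks$heading_deviation <- angular_deviation(tracks$heading, nt$bearing)
  tracks$facing <- facing_indicator(tracks$heading_deviation)
  tmap <- match(nt$turbine_id, turbines$turbine_id)
  tracks$turbine_max_height <- turbines$max_height[tmap]
  hc <- suppressWarnings(height_class(tracks$height_agl,
                                      tracks$turbine_max_height))
  tracks$height_class <- hc

  wm <- match_wind(tracks$timestamp, wind, max_gap = max_wind_gap)
  wc <- rep(NA_real_, nrow(tracks))
  okw <- !wm$missing
  wc[okw] <- wind_component_towards(wm$speed[okw], wm$direction_from[okw],
                                    nt$bearing[okw])
  tracks$wind_component <- wc

  if (!is.null(terrain) && nrow(terrain) > 0) {
    # covariates evaluated at the nearest turbine's grid cell
    tcell <- .nearest_terrain_cell(turbines$lat, turbines$lon, terrain)
    cell_of_point <- tcell[tmap]
    aspect <- terrain$aspect[cell_of_point]
    slope <- terrain$slope[cell_of_point]
    oro <- rep(NA_real_, nrow(tracks))
    ok <- !wm$missing & !is.na(aspect) & !is.na(slope)
    oro[ok] <- orographic_uplift(wm$speed[ok], wm$direction_from[ok],
                                 aspect[ok], slope[ok])
    # flat cells carry an undefined aspect but zero uplift by construction
    flat <- !wm$missing & !is.na(slope) & slope == 0 & is.na(aspect)
    oro[flat] <- 0
    tracks$orographic_uplift <- oro
    st <- terrain$surface_temp[cell_of_point]
    tref <- mean(terrain$surface_temp, na.rm = TRUE)
    th <- rep(NA_real_, nrow(tracks))
    okt <- !is.na(st) & is.finite(tref)
    if (any(okt)) th[okt] <- thermal_uplift(st[okt], tref)
    tracks$thermal_uplift <- th
  } else {
    tracks$orographic_uplift <- NA_real_
    tracks$thermal_uplift <- NA_real_
  }
  tracks$covariate_missing <- wm$missing
  rownames(tracks) <- NULL
  tracks
}

#' Large-scale (GAMM) analysis subset
#'
#' Locations within 1500 m (inclusive) of the closest turbine with complete
#' response and wind covariates.
#'
#' @param annotated Annotated track data frame.
#' @param max_distance Cut-off in meters; default 1500.
#' @return Subset data frame.
#' @export
subset_gamm <- function(annotated, max_distance = 1500) {
  keep <- annotated$distance_to_turbine <= max_distance &
    !annotated$covariate_missing & !is.na(annotated$facing)
  out <- annotated[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Near-turbine (GLMM) analysis subset
#'
#' Locations within 750 m (inclusive) of the closest turbine AND at low
#' flight height (up to the maximum turbine height), where the strongest
#' avoidance is expected. Always a subset of [subset_gamm()].
#'
#' @param annotated Annotated track data frame.
#' @param max_distance Cut-off in meters; default 750.
#' @return Subset data frame.
#' @export
subset_glmm <- function(annotated, max_distance = 750) {
  base <- subset_gamm(annotated, max_distance = max_distance)
  out <- base[base$height_class == "low", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation of model predictors
#'
#' Flags pairs whose absolute correlation exceeds the collinearity threshold
#' so that model configurations can exclude one member of each (the study
#' found r = 0.77 between turbine height and thermal uplift and split the
#' near-turbine model into two configurations for that reason).
#'
#' @param data Data frame holding the predictors.
#' @param vars Character vector of predictor column names; default the
#'   near-turbine model's numeric predictors.
#' @param threshold Absolute-correlation flag level; default 0.7.
#' @return Data frame with `var1`, `var2`, `r` and logical `flagged`.
#' @export
predictor_correlation <- function(data,
                                  vars = c("wind_component",
                                           "orographic_uplift",
                                           "thermal_uplift",
                                           "turbine_max_height"),
                                  threshold = 0.7) {
  vars <- intersect(vars, names(data))
  pairs <- utils::combn(vars, 2)
  r <- apply(pairs, 2, function(p) {
    stats::cor(data[[p[1]]], data[[p[2]]], use = "complete.obs")
  })
  data.frame(var1 = pairs[1, ], var2 = pairs[2, ], r = r,
             flagged = abs(r) > threshold)
}
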