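# Synthetic turbine landscapes, wind series, terrain fields and bird tracks
# with known avoidance parameters. The generative model mirrors the
# statistical model under test: the facing indicator is Bernoulli with logit
#   eta = eta0 + b_i - depth * invlogit((d0 - d)/shape) * 1[low]
#              + beta_w * w_c * 1[low & d <= d0]
# so the near-turbine GLMM is a correctly specified estimator on the
# low-height subset within d0, and parameter recovery is a meaningful test.

#' Scenario configuration for the synthetic generator
#'
#' Ground-truth parameters of a synthetic tracking experiment. Defaults
#' emulate the study system scaled to desk size: turbines in ridge rows,
#' strong easterly wind regime, facing baseline at the random-orientation
#' null logit(1/3), avoidance confined to low flight heights with a logistic
#' onset around 750 m, and a wind-component effect of -0.06 per m/s on the
#' logit scale.
#'
#' @param n_birds Number of birds.
#' @param steps_per_bird GPS fixes per bird.
#' @param step_interval Seconds between fixes.
#' @param n_rows Turbine rows.
#' @param turbines_per_row Turbines per row.
#' @param turbine_spacing Spacing within a row, meters.
#' @param rotor_diameter_range Min/max rotor diameter, meters.
#' @param wind_mean_speed Mean wind speed, m/s (Gamma distributed).
#' @param wind_direction_mean Mean meteorological wind direction, degrees.
#' @param wind_concentration Von Mises concentration of wind directions
#'   (0 = circular uniform).
#' @param baseline_facing_logit Facing logit far from turbines; default
#'   `qlogis(1/3)`, the random-orientation null.
#' @param avoidance_depth Maximum logit depression near turbines (low class).
#' @param avoidance_range Distance scale `d0` of the avoidance onset, meters.
#' @param range_shape Logistic steepness of the onset, meters.
#' @param wind_slope Logit change per m/s of wind component toward the
#'   turbine (low class, within `avoidance_range`).
#' @param bird_intercept_sd SD of per-bird random intercepts (logit scale).
#' @param height_mixture Probabilities of the low/medium/high flight-height
#'   classes.
#' @param box_margin Margin of the roaming box around the turbine rows,
#'   meters; controls the distance range visited.
#' @param wind_drift Fraction of the wind vector added to the displacement.
#' @param bird_start_stagger Offset between consecutive birds' first fixes,
#'   seconds; default 3600 (birds are tracked over different parts of the
#'   wind record, as in a real campaign).
#' @param ridge_slope Terrain slope under the turbine rows, degrees.
#' @param terrain_cell_size Terrain grid spacing, meters.
#' @param origin_lon,origin_lat Geographic anchor of the landscape.
#' @param seed Random seed (mandatory).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_birds = 80,
                            steps_per_bird = 220,
                            step_interval = 10,
                            n_rows = 2,
                            turbines_per_row = 8,
                            turbine_spacing = 400,
                            rotor_diameter_range = c(50, 90),
                            wind_mean_speed = 8,
                            wind_direction_mean = 90,
                            wind_concentration = 4,
                            baseline_facing_logit = stats::qlogis(1 / 3),
                            avoidance_depth = 2,
                            avoidance_range = 750,
                            range_shape = 150,
                            wind_slope = -0.06,
                            bird_intercept_sd = 0.2,
                            height_mixture = c(low = 0.5, medium = 0.25,
                                               high = 0.25),
                            box_margin = 1400,
                            wind_drift = 0.5,
                            bird_start_stagger = 3600,
                            ridge_slope = 12,
                            terrain_cell_size = 500,
                            origin_lon = -5.7,
                            origin_lat = 36.05,
                            seed = NULL) {
  if (is.null(seed)) stop("'seed' is mandatory in a scenario_config",
                          call. = FALSE)
  cfg <- list(
    n_birds = n_birds, steps_per_bird = steps_per_bird,
    step_interval = step_interval,
    n_rows = n_rows, turbines_per_row = turbines_per_row,
    turbine_spacing = turbine_spacing,
    rotor_diameter_range = rotor_diameter_range,
    wind_mean_speed = wind_mean_speed,
    wind_direction_mean = wind_direction_mean,
    wind_concentration = wind_concentration,
    baseline_facing_logit = baseline_facing_logit,
    avoidance_depth = avoidance_depth,
    avoidance_range = avoidance_range,
    range_shape = range_shape,
    wind_slope = wind_slope,
    bird_intercept_sd = bird_intercept_sd,
    height_mixture = height_mixture,
    box_margin = box_margin,
    wind_drift = wind_drift,
    bird_start_stagger = bird_start_stagger,
    ridge_slope = ridge_slope,
    terrain_cell_size = terrain_cell_size,
    origin_lon = origin_lon, origin_lat = origin_lat,
    seed = as.integer(seed)
  )
  stopifnot(n_birds >= 1, steps_per_bird >= 1, step_interval > 0,
            turbine_spacing > 0, all(height_mixture >= 0),
            abs(sum(height_mixture) - 1) < 1e-8,
            avoidance_range > 0, range_shape > 0, bird_intercept_sd >= 0)
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic avoidance scenario:\n")
  cat("  ", x$n_birds, "birds x", x$steps_per_bird, "fixes every",
      x$step_interval, "s\n")
  cat("  ", x$n_rows * x$turbines_per_row, "turbines in", x$n_rows,
      "row(s); avoidance depth", x$avoidance_depth, "over",
      x$avoidance_range, "m; wind slope", x$wind_slope, "per m/s\n")
  cat("   seed", x$seed, "\n")
  invisible(x)
}

# von Mises sampler (Best & Fisher rejection); mu, return value in radians
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    ccc <- kappa * (r - f)
    if (ccc * (2 - ccc) - u[2] > 0 || log(ccc / u[2]) + 1 - ccc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1
    }
  }
  out %% (2 * pi)
}

#' Simulate the turbine landscape and terrain grid
#'
#' Places turbines in linear east-west rows along a synthetic ridge and
#' builds a 500 m terrain grid: cells under the rows carry the ridge slope
#' with a west-facing aspect (into the prevailing wind), cells elsewhere are
#' flat. Surface temperature varies smoothly across the grid so that thermal
#' uplift has spatial structure.
#'
#' @param config A [scenario_config()].
#' @return List with `turbines` and `terrain` data frames.
#' @export
simulate_landscape <- function(config) {
  set.seed(config$seed)
  nt <- config$n_rows * config$turbines_per_row
  row_idx <- rep(seq_len(config$n_rows), each = config$turbines_per_row)
  col_idx <- rep(seq_len(config$turbines_per_row), config$n_rows)
  x <- (col_idx - 1) * config$turbine_spacing
  y <- (row_idx - 1) * 900  # rows 900 m apart on parallel ridge lines
  if (nt > 1) {
    dx <- stats::dist(cbind(x, y))
    if (min(dx) < 50) stop("turbines closer than 50 m", call. = FALSE)
  }
  ll <- .xy_to_lonlat(x, y, config$origin_lon, config$origin_lat)
  rd <- stats::runif(nt, config$rotor_diameter_range[1],
                     config$rotor_diameter_range[2])
  hub_known <- stats::runif(nt) < 0.5
  turbines <- data.frame(
    turbine_id = sprintf("T%03d", seq_len(nt)),
    lon = ll$lon, lat = ll$lat,
    rotor_diameter = rd,
    hub_height = ifelse(hub_known, rd, NA_real_)
  )
  turbines$max_height <- max_turbine_height(turbines$rotor_diameter,
                                            turbines$hub_height)

  cs <- config$terrain_cell_size
  m <- config$box_margin + cs
  gx <- seq(min(x) - m, max(x) + m, by = cs)
  gy <- seq(min(y) - m, max(y) + m, by = cs)
  grid <- expand.grid(x = gx, y = gy)
  # ridge: within 300 m (north-south) of a row line
  near_row <- sapply(grid$y, function(yy) min(abs(yy - unique(y))) < 300)
  grid$slope <- ifelse(near_row, config$ridge_slope, 0)
  # ridge face oriented into the prevailing wind so orographic uplift is live
  grid$aspect <- ifelse(near_row, config$wind_direction_mean, NA_real_)
  grid$surface_temp <- 300 +
    6 * sin(grid$x / max(abs(gx) + 1) * pi) +
    4 * cos(grid$y / max(abs(gy) + 1) * pi) +
    stats::rnorm(nrow(grid), 0, 1)
  llg <- .xy_to_lonlat(grid$x, grid$y, config$origin_lon, config$origin_lat)
  terrain <- data.frame(
    cell_id = sprintf("C%05d", seq_len(nrow(grid))),
    lon = llg$lon, lat = llg$lat,
    aspect = grid$aspect, slope = grid$slope,
    surface_temp = grid$surface_temp
  )
  list(turbines = turbines, terrain = terrain)
}

#' Simulate a 10-minute wind series
#'
#' Directions von Mises around the regime mean, speeds Gamma with the regime
#' mean (shape 4). The series covers the whole tracking period.
#'
#' @param config A [scenario_config()].
#' @param start Start time (`POSIXct`); default 2013-08-01 08:00 UTC.
#' @return Wind data frame (`timestamp`, `direction_from`, `speed`).
#' @export
simulate_wind <- function(config,
                          start = as.POSIXct("2013-08-01 08:00:00",
                                             tz = "UTC")) {
  set.seed(config$seed + 1L)
  dur <- config$steps_per_bird * config$step_interval +
    config$n_birds * config$bird_start_stagger
  times <- seq(start, start + dur + 600, by = 600)
  dirs <- .rad2deg(.rvonmises(length(times),
                              .deg2rad(config$wind_direction_mean),
                              config$wind_concentration))
  shape <- 4
  speeds <- stats::rgamma(length(times), shape = shape,
                          rate = shape / config$wind_mean_speed)
  data.frame(timestamp = times, direction_from = .wrap360(dirs),
             speed = speeds)
}

# logistic avoidance ramp in [0, 1]; ~1 close to the turbine, ~0 beyond d0
.avoidance_ramp <- function(distance, d0, shape) {
  stats::plogis((d0 - distance) / shape)
}

#' Simulate bird tracks with known avoidance behaviour
#'
#' Birds roam a box around the turbine rows. At each step the nearest
#' turbine's distance, bearing and wind component are computed with the same
#' primitives the annotation pipeline uses; the facing indicator is drawn
#' from the generative logit (see the package vignette), the heading is then
#' drawn uniformly inside the facing cone (bearing +/- 60 degrees) or
#' uniformly over its complement, and the bird advances along its heading at
#' its airspeed plus a fraction of the wind vector. Positions leaving the box
#' are reflected. Flight heights are drawn per fix from the height-class
#' mixture relative to the nearest turbine's maximum height, so every class
#' spans its full bracket.
#'
#' @param config A [scenario_config()].
#' @param landscape Output of [simulate_landscape()].
#' @param wind Output of [simulate_wind()].
#' @param start Start time of the first fix.
#' @return List with `tracks` (Movebank-style data frame) and `truth` (per
#'   point: true logit, true probability, the generator's internal distance,
#'   bearing, wind component and height class; attributes carry the per-bird
#'   intercepts and the realized config).
#' @export
simulate_tracks <- function(config, landscape, wind,
                            start = as.POSIXct("2013-08-01 08:00:00",
                                               tz = "UTC")) {
  set.seed(config$seed + 2L)
  turbines <- landscape$turbines
  tx <- .lonlat_to_xy(turbines$lon, turbines$lat,
                      config$origin_lon, config$origin_lat)
  xmin <- min(tx$x) - config$box_margin
  xmax <- max(tx$x) + config$box_margin
  ymin <- min(tx$y) - config$box_margin
  ymax <- max(tx$y) + config$box_margin

  n_steps <- config$steps_per_bird

  b_i <- stats::rnorm(config$n_birds, 0, config$bird_intercept_sd)
  sexes <- sample(c("f", "m"), config$n_birds, replace = TRUE)
  ages <- sample(c("ad", "juv"), config$n_birds, replace = TRUE)

  n_total <- config$n_birds * n_steps
  out <- vector("list", config$n_birds)
  truth_list <- vector("list", config$n_birds)
  n_reflected <- 0L
  mix <- config$height_mixture / sum(config$height_mixture)

  for (bi in seq_len(config$n_birds)) {
    step_times <- start + (bi - 1) * config$bird_start_stagger +
      (seq_len(n_steps) - 1) * config$step_interval
    wmatch <- match_wind(step_times, wind)
    x <- stats::runif(1, xmin, xmax)
    y <- stats::runif(1, ymin, ymax)
    v_lon <- v_lat <- v_h <- v_spd <- v_head <- numeric(n_steps)
    v_eta <- v_p <- v_d <- v_b <- v_wc <- numeric(n_steps)
    v_cls <- character(n_steps)
    v_fac <- integer(n_steps)
    for (s in seq_len(n_steps)) {
      ll <- .xy_to_lonlat(x, y, config$origin_lon, config$origin_lat)
      d_all <- great_circle_distance(ll$lat, ll$lon, turbines$lat,
                                     turbines$lon)
      j <- which.min(d_all)
      d <- d_all[j]
      b <- initial_bearing(ll$lat, ll$lon, turbines$lat[j], turbines$lon[j])
      H <- turbines$max_height[j]
      cls <- sample(height_class_levels(), 1, prob = mix)
      h <- switch(cls,
                  low = stats::runif(1, 1, H),
                  medium = stats::runif(1, H + 0.1, 2 * H),
                  high = stats::runif(1, 2 * H + 0.1, 3 * H))
      wspd <- wmatch$speed[s]; wdir <- wmatch$direction_from[s]
      wc <- wind_component_towards(wspd, wdir, b)
      is_low <- cls == "low"
      eta <- config$baseline_facing_logit + b_i[bi] -
        config$avoidance_depth *
          .avoidance_ramp(d, config$avoidance_range, config$range_shape) *
          is_low +
        config$wind_slope * wc * is_low * (d <= config$avoidance_range)
      p <- stats::plogis(eta)
      facing <- stats::rbinom(1, 1, p)
      if (facing == 1) {
        heading <- .wrap360(b + stats::runif(1, -60, 60))
      } else {
        heading <- .wrap360(b + stats::runif(1, 60, 300))
      }
      speed <- stats::runif(1, 6, 14)
      v_lon[s] <- ll$lon; v_lat[s] <- ll$lat
      v_h[s] <- h; v_spd[s] <- speed; v_head[s] <- heading
      v_eta[s] <- eta; v_p[s] <- p; v_d[s] <- d; v_b[s] <- b; v_wc[s] <- wc
      v_cls[s] <- cls; v_fac[s] <- facing
      # advance: airspeed along heading plus wind drift
      dt <- config$step_interval
      hx <- sin(.deg2rad(heading)); hy <- cos(.deg2rad(heading))
      to_dir <- .deg2rad(wdir + 180)
      x <- x + speed * dt * hx + config$wind_drift * wspd * dt * sin(to_dir)
      y <- y + speed * dt * hy + config$wind_drift * wspd * dt * cos(to_dir)
      if (x < xmin || x > xmax) {
        x <- min(max(2 * (if (x < xmin) xmin else xmax) - x, xmin), xmax)
        n_reflected <- n_reflected + 1L
      }
      if (y < ymin || y > ymax) {
        y <- min(max(2 * (if (y < ymin) ymin else ymax) - y, ymin), ymax)
        n_reflected <- n_reflected + 1L
      }
    }
    out[[bi]] <- data.frame(
      bird_id = sprintf("B%03d", bi), timestamp = step_times,
      lon = v_lon, lat = v_lat, height_agl = v_h,
      ground_speed = v_spd, heading = v_head,
      sex = sexes[bi], age = ages[bi]
    )
    truth_list[[bi]] <- data.frame(
      true_logit = v_eta, true_prob = v_p,
      distance = v_d, bearing = v_b, wind_component = v_wc,
      height_class = factor(v_cls, levels = height_class_levels()),
      facing = v_fac
    )
  }
  tracks <- do.call(rbind, out)
  truth <- do.call(rbind, truth_list)
  truth$bird_id <- tracks$bird_id
  rownames(tracks) <- rownames(truth) <- NULL
  attr(truth, "bird_intercepts") <- stats::setNames(b_i,
                                                    sprintf("B%03d",
                                                            seq_len(config$n_birds)))
  attr(truth, "config") <- config
  attr(truth, "n_reflected") <- n_reflected
  stopifnot(nrow(tracks) == n_total)
  list(tracks = tracks, truth = truth)
}

#' Simulate a complete scenario
#'
#' Convenience wrapper running [simulate_landscape()], [simulate_wind()] and
#' [simulate_tracks()] from one config.
#'
#' @param config A [scenario_config()].
#' @return List with `tracks`, `truth`, `turbines`, `terrain`, `wind`,
#'   `config`.
#' @export
simulate_scenario <- function(config) {
  landscape <- simulate_landscape(config)
  wind <- simulate_wind(config)
  tr <- simulate_tracks(config, landscape, wind)
  list(tracks = tr$tracks, truth = tr$truth,
       turbines = landscape$turbines, terrain = landscape$terrain,
       wind = wind, config = config)
}

#' Export a scenario to the pipeline's CSV/JSON dialects
#'
#' Writes `tracks.csv` (Movebank dialect), `turbines.csv`, `wind.csv`,
#' `terrain.csv`, `truth.json` and `config.yaml` into a directory; the files
#' are the exact formats the annotation pipeline consumes.
#'
#' @param scenario Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
export_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tracks = file.path(dir, "tracks.csv"),
    turbines = file.path(dir, "turbines.csv"),
    wind = file.path(dir, "wind.csv"),
    terrain = file.path(dir, "terrain.csv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_tracks(scenario$tracks, paths["tracks"])
  write_turbines(scenario$turbines, paths["turbines"])
  write_wind(scenario$wind, paths["wind"])
  write_terrain(scenario$terrain, paths["terrain"])
  truth <- scenario$truth
  truth_out <- list(
    config = unclass(attr(truth, "config")),
    bird_intercepts = as.list(attr(truth, "bird_intercepts")),
    n_reflected = attr(truth, "n_reflected"),
    points = as.data.frame(lapply(truth, function(col) {
      if (is.factor(col)) as.character(col) else col
    }))
  )
  jsonlite::write_json(truth_out, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(unclass(scenario$config), paths["config"])
  invisible(paths)
}
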