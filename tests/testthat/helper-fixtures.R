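# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# a tiny track table in internal column layout
make_tracks <- function(n = 5, bird_id = "B001",
                        t0 = as.POSIXct("2013-08-01 10:00:00", tz = "UTC"),
                        interval = 60, lon = -5.7, lat = 36.05,
                        speed = 8, heading = 90, height = 50) {
  data.frame(
    bird_id = rep_len(bird_id, n),
    timestamp = t0 + (seq_len(n) - 1) * interval,
    lon = rep_len(lon, n), lat = rep_len(lat, n),
    height_agl = rep_len(height, n),
    ground_speed = rep_len(speed, n),
    heading = rep_len(heading, n),
    sex = rep_len("f", n), age = rep_len("ad", n)
  )
}

make_turbines <- function(lon = -5.69, lat = 36.05, rotor = 80,
                          hub = NA_real_, id = "T001") {
  df <- data.frame(turbine_id = id, lon = lon, lat = lat,
                   rotor_diameter = rotor, hub_height = hub)
  df$max_height <- max_turbine_height(df$rotor_diameter, df$hub_height)
  df
}

make_wind <- function(n = 12, t0 = as.POSIXct("2013-08-01 08:00:00",
                                              tz = "UTC"),
                      direction = 270, speed = 10) {
  data.frame(
    timestamp = t0 + (seq_len(n) - 1) * 600,
    direction_from = rep_len(direction, n),
    speed = rep_len(speed, n)
  )
}

make_terrain <- function(lon = -5.69, lat = 36.05, aspect = 90, slope = 10,
                         temp = 305) {
  data.frame(cell_id = "C001", lon = lon, lat = lat,
             aspect = aspect, slope = slope, surface_temp = temp)
}

# small scenario for pipeline tests; fast to simulate
small_config <- function(seed, ...) {
  args <- list(n_birds = 8, steps_per_bird = 80, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scenario_config, args)
}

run_pipeline <- function(scn) {
  f1 <- filter_flying(scn$tracks)
  f2 <- exclude_high_frequency(f1$tracks)
  annotate_tracks(f2$tracks, scn$turbines, scn$wind, scn$terrain)
}
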