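# The synthetic generator: landscape geometry, wind regime, generative
# facing behaviour, export round-trips and generator->annotator consistency.

test_that("landscape places turbine rows at the configured spacing", {
  cfg <- small_config(201, n_rows = 1, turbines_per_row = 10,
                      turbine_spacing = 500)
  ls <- simulate_landscape(cfg)
  expect_equal(nrow(ls$turbines), 10)
  d <- great_circle_distance(ls$turbines$lat[-10], ls$turbines$lon[-10],
                             ls$turbines$lat[-1], ls$turbines$lon[-1])
  expect_true(all(abs(d - 500) < 1))
  # flat-terrain option
  flat <- simulate_landscape(small_config(201, ridge_slope = 0))
  expect_true(all(flat$terrain$slope == 0))
  # reproducibility
  ls2 <- simulate_landscape(cfg)
  expect_identical(ls, ls2)
  expect_error(simulate_landscape(small_config(201, turbine_spacing = 10)),
               "50 m")
})

test_that("wind series has the configured regime", {
  cfg <- small_config(202, steps_per_bird = 6000, step_interval = 1,
                      wind_mean_speed = 8)
  w <- simulate_wind(cfg)
  expect_equal(as.numeric(diff(w$timestamp)[1], units = "secs"), 600)
  expect_true(all(w$speed >= 0))
  expect_true(all(w$direction_from >= 0 & w$direction_from < 360))
  expect_identical(w, simulate_wind(cfg))

  # mean speed within 5% at large n; zero concentration -> circular uniform
  cfg2 <- small_config(203, steps_per_bird = 60000, step_interval = 100,
                       wind_mean_speed = 8, wind_concentration = 0)
  w2 <- simulate_wind(cfg2)
  n <- nrow(w2)
  expect_gt(n, 9000)
  expect_lt(abs(mean(w2$speed) - 8) / 8, 0.05)
  # Rayleigh test of circular uniformity: R^2 small under uniformity
  th <- w2$direction_from * pi / 180
  Rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * Rbar^2           # Rayleigh statistic, approx Exp(1) under H0
  expect_lt(z, 4.6)         # 1% critical value ~ -log(0.01)
})

test_that("null generator produces the random-orientation facing rate everywhere", {
  cfg <- scenario_config(n_birds = 12, steps_per_bird = 300,
                         avoidance_depth = 0, wind_slope = 0,
                         bird_intercept_sd = 0, seed = 204)
  scn <- simulate_scenario(cfg)
  p <- mean(scn$truth$facing)
  n <- nrow(scn$truth)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(p - 1 / 3), 3 * se)
  expect_true(all(scn$truth$true_prob == 1 / 3))
})

test_that("avoidance depresses facing near turbines only in the low class", {
  cfg <- scenario_config(n_birds = 20, steps_per_bird = 250,
                         avoidance_depth = 4, box_margin = 600,
                         height_mixture = c(low = 0.6, medium = 0.2,
                                            high = 0.2),
                         seed = 205)
  scn <- simulate_scenario(cfg)
  tru <- scn$truth
  near_low <- tru$height_class == "low" & tru$distance < 200
  expect_gt(sum(near_low), 30)
  expect_lt(mean(tru$facing[near_low]), 0.2)
  # high class unaffected by distance
  hi <- tru$height_class == "high"
  n_hi <- sum(hi)
  se <- sqrt((1 / 3) * (2 / 3) / n_hi)
  expect_lt(abs(mean(tru$facing[hi]) - 1 / 3), 3 * se)
  # every emitted point carries a stored truth probability
  expect_false(any(is.na(tru$true_prob)))
  expect_equal(nrow(tru), nrow(scn$tracks))
})

test_that("generator internals match the annotation pipeline exactly", {
  scn <- simulate_scenario(small_config(206))
  ann <- annotate_tracks(scn$tracks, scn$turbines, scn$wind, scn$terrain)
  expect_equal(ann$distance_to_turbine, scn$truth$distance, tolerance = 1e-9)
  expect_equal(ann$bearing_to_turbine, scn$truth$bearing, tolerance = 1e-9)
  expect_equal(ann$wind_component, scn$truth$wind_component,
               tolerance = 1e-9)
  expect_equal(as.character(ann$height_class),
               as.character(scn$truth$height_class))
  expect_equal(ann$facing, scn$truth$facing)
})

test_that("exported scenarios round-trip and re-annotate to the stored truth", {
  scn <- simulate_scenario(small_config(207))
  dir <- withr::local_tempdir()
  paths <- export_scenario(scn, dir)
  expect_true(all(file.exists(paths)))
  tracks <- read_tracks(paths[["tracks"]])
  turbines <- read_turbines(paths[["turbines"]])
  wind <- read_wind(paths[["wind"]])
  terrain <- read_terrain(paths[["terrain"]])
  expect_equal(nrow(tracks), nrow(scn$tracks))
  expect_equal(turbines$max_height, scn$turbines$max_height, tolerance = 1e-9)
  ann <- annotate_tracks(tracks, turbines, wind, terrain)
  ord <- match(paste(scn$tracks$bird_id, scn$tracks$timestamp),
               paste(ann$bird_id, ann$timestamp))
  expect_equal(ann$distance_to_turbine[ord], scn$truth$distance,
               tolerance = 1e-5)
  expect_equal(ann$wind_component[ord], scn$truth$wind_component,
               tolerance = 1e-5)
  truth_json <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth_json$config$wind_slope, scn$config$wind_slope)
  expect_equal(nrow(truth_json$points), nrow(scn$truth))
})

test_that("seeded simulation is fully reproducible", {
  s1 <- simulate_scenario(small_config(208))
  s2 <- simulate_scenario(small_config(208))
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth$true_prob, s2$truth$true_prob)
  s3 <- simulate_scenario(small_config(209))
  expect_false(identical(s1$tracks$lon, s3$tracks$lon))
})
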