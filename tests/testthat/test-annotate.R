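# Filtering, thinning, nearest-turbine search, covariate joining and the
# analysis subsets.

test_that("flying filter drops slow and speed-missing records and conserves counts", {
  tr <- make_tracks(n = 6)
  tr$ground_speed <- c(0.99, 1.0, 0, 5, NA, 12)
  res <- filter_flying(tr)
  expect_equal(res$tracks$ground_speed, c(1.0, 5, 12))
  expect_equal(res$report$dropped$not_flying, 2)
  expect_equal(res$report$dropped$missing_speed, 1)
  expect_equal(res$report$retained, 3)
  expect_equal(sum(unlist(res$report$dropped)) + res$report$retained,
               res$report$input)
  # identity on all-flying input; empty input
  allfly <- filter_flying(make_tracks(n = 4, speed = 9))
  expect_equal(nrow(allfly$tracks), 4)
  emp <- filter_flying(make_tracks(n = 0))
  expect_equal(emp$report$input, 0)
})

test_that("high-frequency thinning matches a greedy oracle on a 1 Hz burst", {
  # burst of 20 fixes at 1 s: greedy thinning keeps every 5th fix
  tr <- make_tracks(n = 20, interval = 1)
  res <- exclude_high_frequency(tr)
  kept_times <- as.numeric(res$tracks$timestamp) -
    as.numeric(tr$timestamp[1])
  # greedy oracle: walk and keep when gap >= 5
  oracle <- local({
    t <- as.numeric(tr$timestamp) - as.numeric(tr$timestamp[1])
    keep <- c(); last <- -Inf
    for (x in t) if (x - last >= 5) { keep <- c(keep, x); last <- x }
    keep
  })
  expect_equal(kept_times, oracle)
  expect_equal(res$report$retained + res$report$dropped$high_frequency, 20)
  # 60 s regime untouched; single fix kept
  slow <- exclude_high_frequency(make_tracks(n = 10, interval = 60))
  expect_equal(nrow(slow$tracks), 10)
  single <- exclude_high_frequency(make_tracks(n = 1))
  expect_equal(nrow(single$tracks), 1)
  # thinning is per bird: interleaved birds do not mask each other
  two <- rbind(make_tracks(n = 6, interval = 10, bird_id = "B001"),
               make_tracks(n = 6, interval = 10, bird_id = "B002"))
  expect_equal(nrow(exclude_high_frequency(two)$tracks), 12)
})

test_that("nearest turbine agrees with an exhaustive scan and breaks ties by id", {
  one <- nearest_turbine(36.05, -5.7, make_turbines())
  expect_equal(one$turbine_id, "T001")
  # equidistant pair -> smaller id
  tt <- rbind(make_turbines(lon = -5.69, id = "T002"),
              make_turbines(lon = -5.71, id = "T001"))
  tie <- nearest_turbine(36.05, -5.70, tt)
  expect_equal(tie$turbine_id, "T001")
  expect_error(nearest_turbine(36, -5.7, tt[0, ]), "empty")

  # brute-force oracle over random configurations
  set.seed(81)
  turbs <- data.frame(
    turbine_id = sprintf("T%03d", 1:50),
    lon = runif(50, -5.8, -5.6), lat = runif(50, 36.0, 36.1),
    rotor_diameter = 80, hub_height = NA_real_
  )
  lat <- runif(1000, 36.0, 36.1); lon <- runif(1000, -5.8, -5.6)
  got <- nearest_turbine(lat, lon, turbs)
  for (i in sample(1000, 200)) {
    d <- sapply(seq_len(50), function(j)
      great_circle_distance(lat[i], lon[i], turbs$lat[j], turbs$lon[j]))
    expect_equal(got$turbine_id[i], turbs$turbine_id[which.min(d)])
    expect_equal(got$distance[i], min(d))
  }
})

test_that("annotation reproduces a hand-computed single-point fixture", {
  # bird at 36.05 N, -5.70 E heading east; turbine due east; wind from west
  tr <- make_tracks(n = 1, heading = 90, height = 100)
  tb <- make_turbines(lon = -5.69, lat = 36.05, rotor = 80)  # max height 120
  wind <- make_wind(direction = 270, speed = 10)
  terr <- make_terrain(aspect = 270, slope = 30, temp = 305)
  ann <- annotate_tracks(tr, tb, wind, terr)
  expect_equal(ann$nearest_turbine_id, "T001")
  expect_equal(ann$distance_to_turbine,
               great_circle_distance(36.05, -5.70, 36.05, -5.69))
  expect_lt(abs(ann$bearing_to_turbine - 90), 0.01)
  expect_lt(ann$heading_deviation, 0.01)
  expect_equal(ann$facing, 1L)                      # pointing at the turbine
  expect_equal(as.character(ann$height_class), "low")
  expect_equal(ann$turbine_max_height, 120)
  expect_equal(ann$wind_component, 10, tolerance = 1e-6)   # pure tailwind
  # slope faces the wind squarely: w = 10 * sin(30 deg) * cos(0) = 5
  expect_equal(ann$orographic_uplift, 5, tolerance = 1e-6)
  # single terrain cell: reference temp equals cell temp -> zero thermal
  expect_equal(ann$thermal_uplift, 0)
  expect_false(ann$covariate_missing)
})

test_that("annotation is idempotent", {
  scn <- simulate_scenario(small_config(101))
  ann1 <- run_pipeline(scn)
  ann2 <- annotate_tracks(ann1, scn$turbines, scn$wind, scn$terrain)
  expect_equal(ann2, ann1, ignore_attr = TRUE)
})

test_that("analysis subsets apply inclusive cut-offs and nest correctly", {
  ann <- data.frame(
    distance_to_turbine = c(1501, 1500, 800, 750, 700, 700),
    height_class = factor(c("low", "low", "low", "low", "low", "medium"),
                          levels = height_class_levels()),
    facing = 1L, covariate_missing = FALSE
  )
  sg <- subset_gamm(ann)
  expect_equal(sg$distance_to_turbine, c(1500, 800, 750, 700, 700))
  sl <- subset_glmm(ann)
  expect_equal(sl$distance_to_turbine, c(750, 700))
  expect_true(all(as.character(sl$height_class) == "low"))
  # nesting on a simulated scenario
  scn <- simulate_scenario(small_config(102))
  a <- run_pipeline(scn)
  key <- function(d) paste(d$bird_id, d$timestamp)
  expect_true(all(key(subset_glmm(a)) %in% key(subset_gamm(a))))
  expect_equal(nrow(subset_gamm(ann[0, ])), 0)
})

test_that("predictor correlation flags collinear pairs", {
  set.seed(91)
  n <- 10000
  df <- data.frame(a = rnorm(n))
  df$b <- df$a
  df$c <- -df$a
  df$d <- rnorm(n)
  ct <- predictor_correlation(df, vars = c("a", "b", "c", "d"))
  r_ab <- ct$r[ct$var1 == "a" & ct$var2 == "b"]
  r_ac <- ct$r[ct$var1 == "a" & ct$var2 == "c"]
  r_ad <- ct$r[ct$var1 == "a" & ct$var2 == "d"]
  expect_equal(r_ab, 1)
  expect_equal(r_ac, -1)
  expect_lt(abs(r_ad), 0.1)
  expect_true(ct$flagged[ct$var1 == "a" & ct$var2 == "b"])
  expect_false(ct$flagged[ct$var1 == "a" & ct$var2 == "d"])
})

test_that("filter reports compose and conserve counts through the pipeline", {
  scn <- simulate_scenario(small_config(103))
  tr <- scn$tracks
  tr$ground_speed[1:7] <- 0.5
  f1 <- filter_flying(tr)
  f2 <- exclude_high_frequency(f1$tracks)
  rep_all <- combine_filter_reports(f1$report, f2$report)
  expect_equal(rep_all$input, nrow(tr))
  expect_equal(sum(unlist(rep_all$dropped)) + rep_all$retained, rep_all$input)
})
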