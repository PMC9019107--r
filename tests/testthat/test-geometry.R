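# Geometric primitives against independent oracles (geosphere, direct
# vector arithmetic) and their circular-statistics properties.

test_that("haversine distance matches the closed form and an independent geodesic routine", {
  expect_equal(great_circle_distance(36.0, -5.6, 36.0, -5.6), 0)
  # one-hundredth of a degree of longitude at 36 N
  d <- great_circle_distance(36.0, -5.6, 36.0, -5.59)
  expect_equal(d, 899.7, tolerance = 0.001)
  skip_if_not_installed("geosphere")
  set.seed(11)
  lat1 <- runif(50, 35, 37); lon1 <- runif(50, -6, -5)
  lat2 <- lat1 + runif(50, -0.05, 0.05); lon2 <- lon1 + runif(50, -0.05, 0.05)
  ours <- great_circle_distance(lat1, lon1, lat2, lon2)
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371000)
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("distance is symmetric, non-negative and zero only at identity", {
  set.seed(21)
  lat1 <- runif(100, -60, 60); lon1 <- runif(100, -179, 179)
  lat2 <- runif(100, -60, 60); lon2 <- runif(100, -179, 179)
  d12 <- great_circle_distance(lat1, lon1, lat2, lon2)
  d21 <- great_circle_distance(lat2, lon2, lat1, lon1)
  expect_equal(d12, d21)
  expect_true(all(d12 >= 0))
  expect_true(all(d12[lat1 != lat2 | lon1 != lon2] > 0))
  expect_error(great_circle_distance(NA, 0, 0, 0), "lat1")
})

test_that("initial bearing handles cardinal directions and reciprocals", {
  expect_equal(initial_bearing(36.0, -5.6, 36.1, -5.6), 0)
  expect_lt(abs(initial_bearing(36.0, -5.6, 36.0, -5.59) - 90), 0.1)
  expect_error(initial_bearing(36, -5.6, 36, -5.6), "identical")
  # near-antipodal bearing property for nearby points
  set.seed(31)
  lat1 <- runif(100, 35, 37); lon1 <- runif(100, -6, -5)
  lat2 <- lat1 + runif(100, -0.02, 0.02); lon2 <- lon1 + runif(100, -0.02, 0.02)
  b12 <- initial_bearing(lat1, lon1, lat2, lon2)
  b21 <- initial_bearing(lat2, lon2, lat1, lon1)
  diff <- angular_deviation(b12, b21)
  expect_true(all(abs(diff - 180) < 0.1))
  skip_if_not_installed("geosphere")
  # spherical reference (f = 0); the ellipsoidal default differs by < 0.2 deg
  ref <- (geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2),
                             f = 0) + 360) %% 360
  expect_equal(b12, ref, tolerance = 1e-6)
  ref_ell <- (geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) +
                360) %% 360
  expect_true(all(angular_deviation(b12, ref_ell) < 0.2))
})

test_that("angular deviation is the minimal circular difference", {
  expect_equal(angular_deviation(0, 0), 0)
  expect_equal(angular_deviation(350, 10), 20)
  expect_equal(angular_deviation(90, 300), 150)
  set.seed(41)
  h <- runif(500, -720, 720); b <- runif(500, -720, 720)
  d <- angular_deviation(h, b)
  expect_true(all(d >= 0 & d <= 180))
  expect_equal(d, angular_deviation(b, h))
  # invariance to full turns
  expect_equal(d, angular_deviation(h + 360 * sample(-2:2, 500, TRUE), b))
  # independent oracle: angle between unit vectors
  vec_angle <- function(a1, a2) {
    acos(pmin(pmax(cos(a1 * pi / 180) * cos(a2 * pi / 180) +
                     sin(a1 * pi / 180) * sin(a2 * pi / 180), -1), 1)) * 180 / pi
  }
  expect_equal(d, vec_angle(h, b), tolerance = 1e-9)
})

test_that("facing indicator uses the strict 60-degree rule", {
  expect_identical(facing_indicator(0), 1L)
  expect_identical(facing_indicator(59.99), 1L)
  expect_identical(facing_indicator(60), 0L)
  expect_identical(facing_indicator(180), 0L)
  expect_error(facing_indicator(-1), "0, 180")
  expect_error(facing_indicator(181), "0, 180")
})

test_that("uniform random headings face a fixed bearing one-third of the time", {
  set.seed(51)
  n <- 100000
  headings <- runif(n, 0, 360)
  p_hat <- mean(facing_indicator(angular_deviation(headings, 0)))
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(p_hat - 1 / 3), 3 * se)
})

test_that("wind component projects the wind vector onto the bearing", {
  expect_equal(wind_component_towards(10, 270, 90), 10)
  expect_equal(wind_component_towards(10, 270, 270), -10)
  expect_lt(abs(wind_component_towards(10, 270, 0)), 1e-9)
  expect_error(wind_component_towards(-1, 0, 0), "non-negative")
  set.seed(61)
  s <- runif(200, 0, 20); dfrom <- runif(200, 0, 360); b <- runif(200, 0, 360)
  wc <- wind_component_towards(s, dfrom, b)
  expect_true(all(abs(wc) <= s + 1e-12))
  # reversing the bearing flips the sign
  expect_equal(wc, -wind_component_towards(s, dfrom, b + 180))
  # independent oracle: explicit 2-D dot product with the blowing-to vector
  to <- (dfrom + 180) * pi / 180
  oracle <- s * (sin(to) * sin(b * pi / 180) + cos(to) * cos(b * pi / 180))
  expect_equal(wc, oracle, tolerance = 1e-12)
})

test_that("maximum turbine height uses hub + radius or the 1.5 x rotor rule", {
  expect_equal(max_turbine_height(80), 120)
  expect_equal(max_turbine_height(80, hub_height = 80), 120)
  expect_equal(max_turbine_height(90, hub_height = 100), 145)
  expect_error(max_turbine_height(0), "positive")
  expect_equal(max_turbine_height(c(80, 60), c(NA, 70)), c(120, 100))
})

test_that("height classes partition heights with inclusive boundaries", {
  expect_equal(as.character(height_class(100, 120)), "low")
  expect_equal(as.character(height_class(120, 120)), "low")
  expect_equal(as.character(height_class(120.1, 120)), "medium")
  expect_equal(as.character(height_class(240, 120)), "medium")
  expect_equal(as.character(height_class(300, 120)), "high")
  expect_error(height_class(10, 0), "positive")
  # exhaustive and mutually exclusive over a grid
  h <- seq(-10, 500, by = 7.3)
  for (H in c(60, 120, 150)) {
    cls <- suppressWarnings(height_class(h, H))
    expect_false(any(is.na(cls)))
  }
  # negative AGL clamps into low with a warning
  expect_warning(cls <- height_class(c(-5, 10), 120), "clamped")
  expect_equal(as.character(cls), c("low", "low"))
  expect_equal(attr(cls, "n_negative_clamped"), 1L)
})
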