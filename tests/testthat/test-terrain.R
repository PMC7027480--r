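test_that("warmth index sums monthly excesses above 5 degrees", {
  expect_equal(warmth_index(rep(10, 12)), 60)
  expect_equal(warmth_index(c(2, 4, 6, 8, 10, 12, 14, 16, 14, 10, 6, 3)), 51)
  expect_equal(warmth_index(rep(5, 12)), 0)
  expect_equal(warmth_index(rep(-20, 12)), 0)
  expect_error(warmth_index(rep(10, 11)), "12")
  expect_error(warmth_index(c(rep(10, 11), NA)), "12")
})

test_that("slope of an inclined plane equals atan of its gradient", {
  d <- gen_dem("plane", c(12, 15), cell_size = 20, gradient = c(0.1, 0))
  s <- slope_angle(d)
  expect_equal(max(abs(s$values - atan(0.1) * 180 / pi)), 0,
               tolerance = 0.01)
  dy <- gen_dem("plane", c(12, 15), cell_size = 20, gradient = c(0, 0.25))
  expect_equal(max(abs(slope_angle(dy)$values - atan(0.25) * 180 / pi)), 0,
               tolerance = 0.01)
  flat <- raster_grid(matrix(3, 8, 8), 20)
  expect_equal(max(slope_angle(flat)$values), 0)
  expect_true(all(s$values < 90))
  # nodata propagates through the window
  zz <- d$values; zz[5, 5] <- NA
  sn <- slope_angle(raster_grid(zz, 20))
  expect_true(all(is.na(sn$values[4:6, 4:6])))
  expect_false(anyNA(sn$values[1:2, 1:2]))
})

test_that("openness is 90 on a flat plane, less in pits, more on peaks", {
  flat <- raster_grid(matrix(7, 9, 9), 20)
  expect_equal(positive_openness(flat, 100, 8)$values,
               matrix(90, 9, 9))
  z <- matrix(0, 9, 9); z[5, 5] <- -3
  po <- positive_openness(raster_grid(z, 10), 50, 8)
  card <- atan(3 / 10); diag <- atan(3 / (10 * sqrt(2)))
  expect_equal(po$values[5, 5],
               90 - mean(c(rep(card, 4), rep(diag, 4))) * 180 / pi,
               tolerance = 1e-10)
  zp <- matrix(0, 9, 9); zp[5, 5] <- 3
  expect_gt(positive_openness(raster_grid(zp, 10), 50, 8)$values[5, 5], 90)
  valley <- gen_dem("valley", c(9, 9), 10, valley_slope = 0.3)
  expect_lt(positive_openness(valley, 40, 8)$values[5, 5], 90)
  expect_error(positive_openness(flat, 5, 8), "cell size")
  expect_error(positive_openness(flat, 100, 3), "azimuths")
})

test_that("slope, openness and radiation ignore a constant elevation shift", {
  d <- gen_dem("random_smooth", c(8, 8), 20, seed = 2, amplitude = 15)
  d2 <- raster_grid(d$values + 250, 20)
  expect_equal(slope_angle(d2)$values, slope_angle(d)$values)
  expect_equal(positive_openness(d2, 100)$values,
               positive_openness(d, 100)$values)
  expect_equal(potential_solar_radiation(d2, 36, day_step = 30)$values,
               potential_solar_radiation(d, 36, day_step = 30)$values)
})

test_that("D8 accumulation counts upslope cells on a plane and conserves mass", {
  # plane dipping west: flow runs straight west along each row
  d <- gen_dem("plane", c(6, 6), 10, gradient = c(0.1, 0))
  ca <- catchment_area(d)
  expect_equal(ca$values / 100,
               matrix(rep(6:1, each = 6), 6, 6))
  # outlet column carries exactly the routed cell count
  expect_equal(sum(ca$values[, 1] / 100), 36)
  # closed bowl: depression filling still routes every cell
  n <- 9
  x <- abs(outer(rep(1, n), 1:n) - 5); y <- abs(outer(1:n, rep(1, n)) - 5)
  bowl <- raster_grid(pmax(x, y) * 2, 10)
  cb <- catchment_area(bowl)
  expect_true(all(is.finite(cb$values)))
  expect_true(all(cb$values >= 100))      # every cell carries its own area
  expect_error(catchment_area(raster_grid(matrix(NA_real_, 5, 5), 10)),
               "nodata")
})

test_that("relative radiation is 1 on flat ground and splits by aspect", {
  flat <- raster_grid(matrix(0, 6, 6), 20)
  r <- potential_solar_radiation(flat, 36, day_step = 15)
  expect_equal(r$values, matrix(1, 6, 6))
  south <- potential_solar_point(36, 30, 180, day_step = 5)
  north <- potential_solar_point(36, 30, 0, day_step = 5)
  expect_gt(south, 1)
  expect_lt(north, 1)
  expect_error(potential_solar_radiation(flat, 80), "polar")
})

test_that("point radiation matches an independent fine-step integration", {
  # independent oracle: direct clear-sky incidence integration at 0.25 h
  oracle <- function(lat, slope, aspect) {
    phi <- lat * pi / 180; s <- slope * pi / 180; a <- aspect * pi / 180
    nrm <- c(sin(s) * sin(a), sin(s) * cos(a), cos(s))
    surf <- flat <- 0
    for (day in 1:365) {
      dec <- 23.45 * pi / 180 * sin(2 * pi * (284 + day) / 365)
      for (h in seq(0.125, 23.875, by = 0.25)) {
        H <- 15 * (h - 12) * pi / 180
        up <- sin(dec) * sin(phi) + cos(dec) * cos(H) * cos(phi)
        if (up <= 0) next
        sunv <- c(-cos(dec) * sin(H),
                  sin(dec) * cos(phi) - cos(dec) * cos(H) * sin(phi), up)
        surf <- surf + max(0, sum(nrm * sunv))
        flat <- flat + up
      }
    }
    surf / flat
  }
  got <- potential_solar_point(36, 20, 180, day_step = 1, hour_step = 1)
  expect_equal(got, oracle(36, 20, 180), tolerance = 0.01)
})
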