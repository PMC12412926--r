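test_that("Kelvin to Celsius conversion is the constant offset, shape-preserving", {
  expect_equal(kelvin_to_celsius(273.15), 0)
  expect_equal(kelvin_to_celsius(c(273.15, 300.15)), c(0, 27))
  m <- matrix(c(273.15, 293.05, 283.15, 303.15), 2)
  expect_equal(dim(kelvin_to_celsius(m)), dim(m))
  expect_equal(kelvin_to_celsius(293.05), 19.9)
  expect_error(kelvin_to_celsius(Inf), "non-finite")
})

test_that("hourly values average to daily means under the completeness rule", {
  day <- as.POSIXct("2015-03-01 00:00", tz = "UTC") + 3600 * (0:23)
  expect_equal(hourly_to_daily_mean(day, rep(20, 24))$value, 20)
  expect_equal(hourly_to_daily_mean(day, rep(c(10, 30), each = 12))$value, 20)
  # 23 of 24 hours present -> missing under the default all-24 rule
  out <- hourly_to_daily_mean(day[-5], rep(20, 23))
  expect_true(is.na(out$value))
  expect_equal(hourly_to_daily_mean(day[-5], rep(20, 23), min_hours = 20)$value, 20)
  empty <- hourly_to_daily_mean(as.POSIXct(character(), tz = "UTC"), numeric())
  expect_equal(nrow(empty), 0)
})

test_that("hourly mode with a zero-mean diurnal cycle reproduces daily means exactly", {
  daily <- data.frame(date = as.Date("2015-01-01") + 0:9, value = rnorm(10, 20, 5))
  hourly <- simulate_hourly_from_daily(daily, diurnal_amplitude = 6)
  redaily <- hourly_to_daily_mean(hourly$timestamp, hourly$value)
  expect_equal(redaily$value, daily$value, tolerance = 1e-12)
})

test_that("Tetens relative humidity matches the ratio formula and its contracts", {
  expect_equal(tetens_rh(20, 20), 100)
  expect_equal(tetens_rh(20, 10), 52.5, tolerance = 0.1 / 52.5)
  expect_warning(rh <- tetens_rh(20, 25), "clamped")
  expect_equal(rh, 100)
  # strictly increasing in dewpoint at fixed air temperature
  td <- seq(-5, 19.9, length.out = 40)
  expect_true(all(diff(tetens_rh(rep(20, 40), td)) > 0))
  expect_true(all(tetens_rh(rep(20, 40), td) < 100))
  expect_error(tetens_rh(-250, -260), "Tetens")
})

test_that("grid values average to municipality values over member cells", {
  gv <- data.frame(cell_id = c("c1", "c2"), date = as.Date("2015-01-01"),
                   value = c(20, 22))
  mem1 <- data.frame(municipality_id = "A", cell_id = c("c1", "c2"))
  expect_equal(grid_to_municipality(gv, mem1)$value, 21)
  # one cell per municipality -> identity
  mem2 <- data.frame(municipality_id = c("A", "B"), cell_id = c("c1", "c2"))
  expect_equal(grid_to_municipality(gv, mem2)$value, c(20, 22))
  # 3 municipalities x 4 cells, hand-computed means over two dates
  cells <- paste0("g", 1:4)
  gv3 <- expand.grid(cell_id = cells, date = as.Date("2015-01-01") + 0:1,
                     stringsAsFactors = FALSE)
  gv3$value <- c(10, 20, 30, 40, 11, 21, 31, 41)
  mem3 <- data.frame(municipality_id = c("A", "A", "B", "C"), cell_id = cells)
  out <- grid_to_municipality(gv3, mem3)
  expect_equal(out$value[out$municipality_id == "A"], c(15, 16))
  expect_equal(out$value[out$municipality_id == "B"], c(30, 31))
  expect_equal(out$value[out$municipality_id == "C"], c(40, 41))
  mem_bad <- data.frame(municipality_id = "Z", cell_id = "nope")
  expect_error(grid_to_municipality(gv, rbind(mem1, mem_bad)[c(1, 3), ]), "Z")
})

test_that("weighted quantiles follow the midpoint plotting-position rule", {
  expect_equal(weighted_quantile(1:5, probs = 0.5), 3)
  expect_equal(weighted_quantile(c(10, 20, 30), c(1, 1, 2), 0.5), 23.33,
               tolerance = 0.01 / 23.33)
  expect_equal(weighted_quantile(7, 2, c(0, 0.3, 1)), c(7, 7, 7))
  expect_error(weighted_quantile(numeric()), "empty")
  # equal weights reduce to the unweighted midpoint-rule quantile (type 5)
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(40)
    p <- runif(3, 0.05, 0.95)
    expect_equal(weighted_quantile(x, probs = p),
                 unname(quantile(x, p, type = 5)), tolerance = 1e-12)
  }
  # monotonicity across probabilities, any weights
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(30); w <- rexp(30) + 0.1
    q <- weighted_quantile(x, w, c(0.05, 0.5, 0.95))
    expect_true(q[1] <= q[2] && q[2] <= q[3])
  }
})

test_that("percentile thresholds respond to population weighting", {
  clim <- data.frame(municipality_id = rep(c("A", "B"), each = 100),
                     date = rep(as.Date("2015-01-01") + 0:99, 2),
                     tmean_c = c(rep(10, 100), rep(30, 100)),
                     rh_pct = 70)
  thr <- percentile_thresholds(clim, c(A = 9, B = 1))
  expect_equal(unname(thr$p["p50"]), 10)
  thr2 <- percentile_thresholds(clim, c(A = 1, B = 9))
  expect_equal(unname(thr2$p["p50"]), 30)
  expect_true(all(diff(thr$p) >= 0))
})

test_that("lagged exposures index history correctly and flag incomplete rows", {
  clim <- data.frame(municipality_id = "A",
                     date = as.Date("2015-06-01") + 0:4,
                     tmean_c = c(21, 18, 25, 30, 16), rh_pct = 60 + 0:4)
  e0 <- build_lagged_exposures(clim, 0L)
  expect_equal(e0$x_lag0, clim$tmean_c)
  expect_equal(e0$rh_mean, clim$rh_pct)
  e1 <- build_lagged_exposures(clim, 1L)
  # day with T=25 preceded by T=18: x_lag = [25, 18]
  row <- e1[e1$date == as.Date("2015-06-03"), ]
  expect_equal(c(row$x_lag0, row$x_lag1), c(25, 18))
  expect_equal(row$rh_mean, mean(c(62, 61)))
  expect_false(e1$complete[1])
  expect_true(all(e1$complete[-1]))
})

test_that("shifting all dates shifts lagged exposures without changing values", {
  set.seed(3)
  clim <- data.frame(municipality_id = "A", date = as.Date("2015-06-01") + 0:29,
                     tmean_c = rnorm(30, 20, 4), rh_pct = runif(30, 40, 90))
  e <- build_lagged_exposures(clim, 2L)
  clim_k <- transform(clim, date = date + 11)
  e_k <- build_lagged_exposures(clim_k, 2L)
  expect_equal(e_k$date, e$date + 11)
  expect_equal(e_k$x_lag0, e$x_lag0)
  expect_equal(e_k$x_lag2, e$x_lag2)
  expect_equal(e_k$rh_mean, e$rh_mean)
})

test_that("climate CSV round-trips through read/write", {
  clim <- data.frame(municipality_id = "A", date = as.Date("2015-01-01") + 0:2,
                     tmean_c = c(20.5, 21, 19), rh_pct = c(70, 75, 80))
  f <- tempfile(fileext = ".csv")
  write_climate(clim, f)
  back <- read_climate(f)
  expect_equal(back$tmean_c, clim$tmean_c)
  expect_equal(back$date, clim$date)
  unlink(f)
})
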