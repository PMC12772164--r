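linked_stub <- function(lat, pounds, time_forward = 60, lon = -126,
                        day = "2015-08-01", vessel = NULL) {
  n <- length(lat)
  data.frame(timestamp = as.POSIXct(day, tz = "UTC") + 3600 * seq_len(n),
             vessel_id = if (is.null(vessel)) rep("V001", n) else vessel,
             lat = lat, lon = rep_len(lon, n), event_type = "at_sea",
             time_forward = rep_len(time_forward, n), speed = 2,
             gis_flag = FALSE, ticket_id = "T1",
             allocated_pounds = pounds, stringsAsFactors = FALSE)
}

test_that("daily centroid is the pounds-weighted mean latitude", {
  s <- daily_effort_centroid(linked_stub(lat = c(40, 46), pounds = c(1, 2)))
  expect_equal(s$value, 44)
  s2 <- daily_effort_centroid(linked_stub(lat = c(40, 46), pounds = c(1, 1)))
  expect_equal(s2$value, 43)
  s3 <- daily_effort_centroid(linked_stub(lat = 41.3, pounds = 5))
  expect_equal(s3$value, 41.3)
  # all-zero weights on a day yield a missing value
  s4 <- daily_effort_centroid(linked_stub(lat = c(40, 46), pounds = c(0, 0)))
  expect_true(is.na(s4$value))
})

test_that("distance to shore is pounds-weighted great-circle distance", {
  coast <- synthetic_coastline(-124.5, c(38, 49))
  lat0 <- 44
  km_per_deg <- 111.320 * cos(lat0 * pi / 180)
  lon_at <- function(km) -124.5 - km / km_per_deg
  l <- linked_stub(lat = c(lat0, lat0), pounds = c(1, 3),
                   lon = c(lon_at(10), lon_at(40)))
  s <- daily_distance_to_shore(l, coast)
  expect_equal(s$value, 32.5, tolerance = 0.01)
  # a ping on the coastline contributes zero distance
  l0 <- linked_stub(lat = lat0, pounds = 1, lon = -124.5)
  expect_equal(daily_distance_to_shore(l0, coast)$value, 0, tolerance = 1e-6)
  # equal weights reduce to the arithmetic mean
  le <- linked_stub(lat = c(lat0, lat0), pounds = c(2, 2),
                    lon = c(lon_at(10), lon_at(40)))
  expect_equal(daily_distance_to_shore(le, coast)$value, 25, tolerance = 0.01)
  expect_error(daily_distance_to_shore(l, NULL), "coastline")
})

test_that("point-to-coast distances agree with geosphere::dist2Line", {
  coast <- synthetic_coastline(-124.5, c(38, 49))
  set.seed(1)
  lon <- runif(20, -130, -125); lat <- runif(20, 39, 48)
  mine <- dist_to_coast(lon, lat, coast)
  ref <- geosphere::dist2Line(cbind(lon, lat), coast)[, "distance"] / 1000
  expect_equal(mine, unname(ref), tolerance = 0.005)
})

test_that("daily CPUE divides daily pounds by daily minutes", {
  l <- linked_stub(lat = c(44, 44), pounds = c(400, 600),
                   time_forward = c(40, 60))
  expect_equal(daily_cpue(l)$value, 10)
  lz <- linked_stub(lat = 44, pounds = 0, time_forward = 100)
  expect_equal(daily_cpue(lz)$value, 0)
  expect_error(daily_cpue(linked_stub(lat = 44, pounds = -1)), "negative")
})

test_that("anomalies subtract the monthly climatology", {
  # two Julys with values 14 and 16: climatology 15, anomalies -1 and +1
  d <- as.Date(c("2014-07-15", "2015-07-15"))
  s <- indicator_series(d, c(14, 16), "x")
  a <- anomalize(s)
  jul <- format(a$date, "%m") == "07" & !is.na(a$value)
  expect_equal(sort(a$value[jul]), c(-1, 1))
  clim <- attr(a, "climatology")
  expect_equal(clim$mean_value[7], 15)
  expect_equal(clim$n_days[7], 2)

  # a series equal to its climatology anomalizes to zero
  s2 <- series_from(rep(5, 60))
  a2 <- anomalize(s2)
  expect_true(all(a2$value == 0))

  # adding a constant leaves anomalies unchanged
  set.seed(2)
  v <- rnorm(365)
  a3 <- anomalize(series_from(v))
  a4 <- anomalize(series_from(v + 100))
  expect_equal(a3$value, a4$value)
})

test_that("anomalies have zero monthly means over the climatology period", {
  set.seed(3)
  s <- series_from(rnorm(365 * 3, mean = 10), start = "2013-01-01")
  a <- anomalize(s)
  mo <- format(a$date, "%m")
  monthly <- tapply(a$value, mo, mean)
  expect_true(all(abs(monthly) < 1e-9))
})

test_that("30-day right-aligned smoothing behaves like a windowed mean", {
  # constant series stays constant where coverage is sufficient
  s <- smooth_series(series_from(rep(4, 60)))
  expect_true(all(s$value[30:60] == 4))
  expect_true(all(is.na(s$value[1:14])))  # below minimum coverage

  # an impulse of height 30 contributes 1 to the next 30 days
  v <- rep(0, 100); v[50] <- 30
  si <- smooth_series(series_from(v))
  expect_equal(si$value[50:79], rep(1, 30))
  expect_equal(si$value[80], 0)

  # linear ramp: fully covered windows give t - 14.5
  sr <- smooth_series(series_from(1:100))
  expect_equal(sr$value[30:100], (30:100) - 14.5)

  # coverage rule: windows with fewer than min_coverage days stay missing
  v2 <- c(rep(NA, 20), rep(1, 10), rep(NA, 70))
  sc <- smooth_series(series_from(v2))
  expect_true(all(is.na(sc$value)))
  expect_error(smooth_series(series_from(1:10), window = 0), "window")
})

test_that("season restriction keeps July-October days", {
  s <- series_from(rep(1, 365), start = "2015-01-01")
  r <- restrict_season(smooth_series(anomalize(s)))
  expect_equal(nrow(r), 123)  # Jul + Aug + Sep + Oct of 2015
  expect_true(all(as.integer(format(r$date, "%m")) %in% 7:10))
  expect_false(as.Date("2015-06-30") %in% r$date)
  expect_true(as.Date("2015-07-01") %in% r$date)
  expect_true(as.Date("2015-10-31") %in% r$date)
  # a series entirely outside the season restricts to nothing
  w <- series_from(rep(1, 28), start = "2015-02-01")
  expect_equal(nrow(restrict_season(w)), 0)
})

test_that("processing order is anomalize, smooth, then restrict", {
  set.seed(4)
  s <- series_from(rnorm(730), start = "2014-01-01")
  canonical <- process_indicator(s)
  reordered <- smooth_series(restrict_season(anomalize(s)))
  reordered <- reordered[as.integer(format(reordered$date, "%m")) %in% 7:10, ]
  # restricting before smoothing changes season-edge values: early-July
  # windows lose their late-June days
  jul1 <- canonical$date == as.Date("2014-07-15")
  jul2 <- reordered$date == as.Date("2014-07-15")
  expect_false(isTRUE(all.equal(canonical$value[jul1], reordered$value[jul2])))
})

test_that("annual CPUE averages the fishing season and anomalizes across years", {
  d <- seq(as.Date("2014-01-01"), as.Date("2016-12-31"), by = "day")
  v <- rep(10, length(d))
  v[format(d, "%Y") == "2016"] <- 5  # one poor year at half the CPUE
  s <- indicator_series(d, v, "vms_cpue")
  a <- annual_cpue(s)
  expect_equal(a$value, c(10, 10, 5))
  expect_equal(a$anomaly, c(10, 10, 5) - mean(c(10, 10, 5)))
  # constant series: all anomalies zero
  a2 <- annual_cpue(indicator_series(d, rep(10, length(d)), "vms_cpue"))
  expect_true(all(a2$anomaly == 0))
})

test_that("effort gridding suppresses cells with fewer than four vessels", {
  l <- rbind(
    linked_stub(lat = rep(44.01, 4), pounds = 1, vessel = paste0("V", 1:4)),
    linked_stub(lat = rep(45.51, 3), pounds = 1, vessel = paste0("V", 1:3)))
  g <- grid_effort(l, resolution = 0.1, min_vessels = 4)
  c4 <- g[g$n_vessels == 4, ]; c3 <- g[g$n_vessels == 3, ]
  expect_false(c4$suppressed)
  expect_true(c3$suppressed)
  # conservation: mapped hours equal the total time-forward
  expect_equal(sum(g$hours), sum(l$time_forward) / 60)
  share <- attr(g, "suppressed_share")
  expect_equal(unname(share["hours"]), 3 / 7)
})
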