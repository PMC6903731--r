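mk_track <- function(lon, lat, start = "2017-04-01", by = 7200) {
  data.frame(time = as.POSIXct(start, tz = "UTC") + by * (seq_along(lon) - 1),
             lon = lon, lat = lat)
}

test_that("maximum distance matches spherical oracles", {
  origin <- c(-60.789, -60)
  expect_equal(max_distance(mk_track(rep(-60.789, 5), rep(-60, 5)), origin), 0)
  # one degree of longitude at 60 S
  tr <- mk_track(c(-60.789, -60.3, -59.789), c(-60, -60, -60))
  loc <- 6371 * acos(pmin(1, sin(-60 * pi / 180)^2 +
                            cos(-60 * pi / 180)^2 * cos(pi / 180)))
  expect_equal(max_distance(tr, origin), loc, tolerance = 1e-6)
  expect_equal(max_distance(tr, origin), 55.6, tolerance = 0.002)
})

test_that("classification uses the 500 km radius and net direction", {
  origin <- c(-60, -62)
  # oscillating under the radius: local
  th <- seq(0, 6 * pi, length.out = 200)
  r_km <- 499 * abs(sin(th))
  lat <- -62 + (r_km / 111.19493) * cos(th)
  lon <- -60 + (r_km / (111.19493 * cos(-62 * pi / 180))) * sin(th)
  expect_equal(classify_migration(mk_track(lon, lat), origin), "local")
  # monotone westward to ~1500 km: west
  lonw <- seq(-60, -60 - 1500 / (111.19493 * cos(-62 * pi / 180)),
              length.out = 300)
  expect_equal(classify_migration(mk_track(lonw, rep(-62, 300)), origin),
               "west")
  # eastward: east
  expect_equal(classify_migration(mk_track(rev(lonw), rep(-62, 300)),
                                  c(lonw[300], -62)), "east")
})

test_that("dateline crossings classify by unwrapped longitude", {
  # heading west from 170 W across the antimeridian to 170 E
  lon <- normalize_lon(seq(-170, -190, length.out = 150))
  tr <- mk_track(lon, rep(-60, 150))
  expect_true(any(tr$lon > 0))  # wrapped representation flips sign
  expect_equal(classify_migration(tr, c(-170, -60)), "west")
  # and eastwards across the antimeridian from 170 E
  lon_e <- normalize_lon(seq(170, 195, length.out = 150))
  expect_equal(classify_migration(mk_track(lon_e, rep(-60, 150)),
                                  c(170, -60)), "east")
})

test_that("classification is invariant to time-resolution refinement", {
  origin <- c(-60, -62)
  lon_c <- seq(-60, -75, length.out = 1441)  # continuous westward path
  lat_c <- rep(-62, 1441)
  coarse <- mk_track(lon_c[seq(1, 1441, by = 12)], lat_c[seq(1, 1441, by = 12)],
                     by = 86400)
  fine <- mk_track(lon_c, lat_c, by = 7200)
  expect_identical(classify_migration(coarse, origin),
                   classify_migration(fine, origin))
})

test_that("net swim speeds follow the weighted-month definition", {
  # stationary: both zero
  st <- mk_track(rep(-60, 50), rep(-62, 50))
  sp0 <- swim_speeds(st)
  expect_equal(sp0$mean_daily, 0)
  expect_equal(sp0$max_daily, 0)

  # constant 0.2 m/s due east over two full months
  tt <- seq(as.POSIXct("2017-04-01", tz = "UTC"),
            as.POSIXct("2017-05-31 22:00", tz = "UTC"), by = 7200)
  dist_km <- 0.2 * 7200 / 1000 * (seq_along(tt) - 1)
  lon <- -100 + dist_km / (111.19493 * cos(-60 * pi / 180))
  sp <- swim_speeds(data.frame(time = tt, lon = lon, lat = rep(-60, length(tt))))
  expect_equal(sp$mean_daily, 0.2, tolerance = 1e-3)
  expect_equal(sp$max_daily, 0.2, tolerance = 1e-3)
  expect_equal(nrow(sp$monthly), 2)
  expect_equal(sp$monthly$days_tracked, c(30, 31))

  # local wander: net speed below gross path speed
  cfg <- sim_config(seed = 66)
  tr <- simulate_true_track(small_dep("sw", duration_days = 45), "local", cfg)
  spl <- swim_speeds(data.frame(time = tr$time, lon = tr$lon, lat = tr$lat))
  gross <- sum(haversine_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                            tr$lon[-1], tr$lat[-1])) * 1000 /
    as.numeric(difftime(max(tr$time), min(tr$time), units = "secs"))
  expect_lt(spl$mean_daily, gross)

  # shifting the series by one day only re-bins month edges
  sh <- swim_speeds(data.frame(time = tt + 86400, lon = lon,
                               lat = rep(-60, length(tt))))
  expect_equal(sh$mean_daily, 0.2, tolerance = 1e-3)
})

test_that("single-position months are excluded from the statistics", {
  tt <- c(as.POSIXct("2017-03-31 23:00", tz = "UTC"),
          seq(as.POSIXct("2017-04-01 01:00", tz = "UTC"), by = 7200,
              length.out = 100))
  lon <- seq(-60, -61, length.out = 101)
  sp <- swim_speeds(data.frame(time = tt, lon = lon, lat = rep(-62, 101)))
  mm <- sp$monthly
  expect_true(is.na(mm$speed_ms[mm$month == "2017-03"]))
  expect_false(is.na(sp$mean_daily))
})

test_that("the summary table carries the deployment grouping keys", {
  cfg <- sim_config(seed = 14)
  deps <- data.frame(deployment_id = c("a", "b"),
                     colony = c("Cape Shirreff", "Cierva Cove"),
                     lon = c(-60.789, -60.984), lat = c(-62.46, -64.143),
                     stage = c("adult", "juvenile"))
  paths <- list(
    a = simulate_true_track(small_dep("a", duration_days = 40), "west", cfg),
    b = simulate_true_track(list(deployment_id = "b", colony = "Cierva Cove",
                                 lon = -60.984, lat = -64.143,
                                 release_time = as.POSIXct("2017-02-25",
                                                           tz = "UTC"),
                                 duration_days = 12), "local", cfg))
  ms <- migration_summary(paths, deps)
  expect_equal(ms$direction, c("west", "local"))
  expect_true(all(ms$max_distance_km >= 0))
  tab <- migration_group_table(ms)
  expect_true(all(c("colony", "direction", "stage", "n_tags") %in% names(tab)))
  expect_equal(sum(tab$n_tags), 2)
})
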