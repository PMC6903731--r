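cfg <- sim_config(seed = 55)

write_fix_lines <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c(paste("deployment_id", "timestamp", "lon", "lat", "lc_class",
                     "ellipse_semi_major_m", "ellipse_semi_minor_m",
                     "ellipse_orientation_deg", sep = ","), lines), path)
  path
}

test_that("reader parses, sorts, wraps longitudes, and reports bad rows", {
  p <- write_fix_lines(c(
    "d1,2017-03-02T13:00:00Z,-60.1,-62.1,3,250,250,0",
    "d1,2017-03-01T13:00:00Z,181,-62.0,1,1500,1500,0",
    "d1,2017-03-03T13:00:00Z,-60.3,-62.3,B,10000,10000,0",
    "d1,not-a-time,-60.4,-62.4,2,500,500,0"))
  fx <- read_argos_csv(p)
  expect_equal(nrow(fx), 3)
  expect_true(!is.unsorted(fx$timestamp))
  expect_equal(fx$lon[1], -179)  # 181 wraps west
  expect_equal(nrow(attr(fx, "rejected")), 1)
  # missing required column is a named hard error
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("deployment_id,timestamp,lon,lat", "d1,2017-03-01T13:00:00Z,0,0"), p2)
  expect_error(read_argos_csv(p2), "lc_class")
})

test_that("generated fix tables round-trip through the reader losslessly", {
  tr <- simulate_true_track(small_dep("rt", duration_days = 40), "west", cfg)
  fx <- observe_argos(tr, cfg)
  expect_gt(nrow(fx), 100)
  path <- tempfile(fileext = ".csv")
  write_fixes_csv(fx, path)
  back <- read_argos_csv(path)
  expect_equal(nrow(back), nrow(fx))
  expect_equal(as.numeric(back$timestamp), as.numeric(fx$timestamp))
  expect_equal(back$lon, fx$lon, tolerance = 1e-12)
  expect_equal(back$lat, fx$lat, tolerance = 1e-12)
  expect_identical(back$lc_class, fx$lc_class)
  expect_identical(is.na(back$ellipse_semi_major_m),
                   is.na(fx$ellipse_semi_major_m))
  expect_equal(nrow(attr(back, "rejected")), 0)
})

test_that("quality screening removes Z classes and unspecified ellipses", {
  fx <- data.frame(deployment_id = "d", lc_class = c("3", "Z", "1", "B", "Z",
                                                     "0", "2", "A", "3", "1"),
                   timestamp = as.POSIXct("2017-03-01", tz = "UTC") +
                     3600 * (1:10),
                   lon = -60, lat = -62,
                   ellipse_semi_major_m = c(250, NA, 1500, NA, NA,
                                            5000, 500, 5000, 250, 1500),
                   ellipse_semi_minor_m = 1, ellipse_orientation_deg = 0)
  out <- filter_quality(fx)
  expect_equal(nrow(out), 7)
  expect_equal(unname(attr(out, "qc_removed")["n_z"]), 2)
  expect_equal(unname(attr(out, "qc_removed")["n_no_ellipse"]), 1)
  expect_identical(out$timestamp, fx$timestamp[!(fx$lc_class == "Z" |
                                                   is.na(fx$ellipse_semi_major_m))])
  # clean input passes through unchanged
  clean <- fx[fx$lc_class != "Z" & !is.na(fx$ellipse_semi_major_m), ]
  out2 <- filter_quality(clean)
  expect_equal(nrow(out2), nrow(clean))
})

test_that("quality screening agrees with generator bookkeeping", {
  tr <- simulate_true_track(small_dep("bk", duration_days = 60), "local", cfg)
  fx <- observe_argos(tr, cfg)
  out <- filter_quality(fx)
  n_z <- sum(fx$lc_class == "Z")
  n_miss <- sum(is.na(fx$ellipse_semi_major_m) & fx$lc_class != "Z")
  expect_equal(nrow(out), nrow(fx) - n_z - n_miss)
})

test_that("speed filter uses an inclusive 2.5 m/s bound", {
  t0 <- as.POSIXct("2017-03-01 13:00:00", tz = "UTC")
  # exactly 9 km in 1 h = 2.5 m/s -> retained
  at_limit <- data.frame(deployment_id = "d", timestamp = c(t0, t0 + 3600),
                         lon = c(-60, -60), lat = c(-62, -62 + 9 / 111.19493),
                         lc_class = "3", ellipse_semi_major_m = 250,
                         ellipse_semi_minor_m = 250,
                         ellipse_orientation_deg = 0)
  expect_equal(nrow(speed_filter(at_limit)), 2)
  # 10 km in 1 h = 2.78 m/s -> second dropped
  too_fast <- at_limit
  too_fast$lat[2] <- -62 + 10 / 111.19493
  out <- speed_filter(too_fast)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_speed_removed"), 1L)
})

test_that("speed-filter output always satisfies the pairwise bound and is idempotent", {
  cfg_fast <- cfg
  cfg_fast$argos_class_probs <- c(`3` = 0.2, `2` = 0.2, `1` = 0.2, `0` = 0.1,
                                  A = 0.1, B = 0.2, Z = 0)
  for (s in 1:3) {
    tr <- simulate_true_track(small_dep(paste0("sf", s), duration_days = 30),
                              "west", sim_config(seed = 200 + s))
    fx <- filter_quality(observe_argos(tr, cfg_fast,
                                       seed = derive_seed(300L + s, "sf")))
    out <- speed_filter(fx, vmax = 2.5)
    d_m <- haversine_km(out$lon[-nrow(out)], out$lat[-nrow(out)],
                        out$lon[-1], out$lat[-1]) * 1000
    dt_s <- diff(as.numeric(out$timestamp))
    expect_true(all(d_m / dt_s <= 2.5 + 1e-9))
    again <- speed_filter(out, vmax = 2.5)
    expect_equal(nrow(again), nrow(out))
    expect_equal(again$lon, out$lon)
  }
})

test_that("deployments below seven tracked days are removed", {
  mk <- function(id, days) data.frame(
    deployment_id = id,
    timestamp = as.POSIXct("2017-03-01 12:00", tz = "UTC") +
      seq(0, days * 86400, by = 7200),
    lon = -60, lat = -62, lc_class = "3", ellipse_semi_major_m = 250,
    ellipse_semi_minor_m = 250, ellipse_orientation_deg = 0)
  fx <- rbind(mk("short", 6.9), mk("long", 7.0))
  deps <- data.frame(deployment_id = c("short", "long"),
                     colony = "X", stage = "adult")
  ret <- retain_min_duration(fx, deps, min_days = 7)
  expect_identical(ret$report$retained, c(FALSE, TRUE))
  expect_true(all(ret$fixes$deployment_id == "long"))
})

test_that("filters commute with deployment partitioning", {
  trs <- lapply(1:3, function(i)
    observe_argos(simulate_true_track(small_dep(paste0("p", i),
                                                duration_days = 15),
                                      "local", cfg), cfg))
  all_fx <- do.call(rbind, trs)
  whole <- filter_quality(all_fx)
  parts <- do.call(rbind, lapply(trs, filter_quality))
  rownames(whole) <- rownames(parts) <- NULL
  attr(whole, "qc_removed") <- attr(parts, "qc_removed") <- NULL
  expect_equal(whole, parts)
})
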