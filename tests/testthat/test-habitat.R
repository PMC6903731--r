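cfg <- sim_config(seed = 91)
env <- generate_env_grids(cfg)
hexg <- build_hexgrid(25)

test_that("hexagon covariate means recover analytic fields", {
  # constant field: every cell mean equals the constant
  lon <- seq(-70, -50, by = 0.5); lat <- seq(-66, -56, by = 0.25)
  const <- env_grid("sst", lon, lat,
                    matrix(1.7, length(lon), length(lat)), "2017-05")
  # hex cells that actually lie inside the test grid
  anchor <- project_laea(c(-60, -59, -61.5), c(-62, -60.5, -63.2))
  cells <- hex_cell_of(hexg, anchor[, "x"], anchor[, "y"])
  hud <- mk_hud("2017-05", q = cells$q, deployment_id = "a1",
                colony = "A", r = cells$r)
  cm <- cell_mean_covariate(hud, hexg, const)
  expect_equal(cm$value, rep(1.7, 3))
  expect_false(any(cm$fallback))

  # linear-in-latitude field: cell mean ~ field at the hex centroid
  lin <- env_grid("sst", lon, lat,
                  outer(rep(1, length(lon)), 0.5 * (lat + 60)), "2017-05")
  cm2 <- cell_mean_covariate(hud, hexg, lin)
  cc <- hex_centroid(hexg, hud$q, hud$r)
  ll <- unproject_laea(cc[, "x"], cc[, "y"])
  expect_lt(max(abs(cm2$value - 0.5 * (ll[, "lat"] + 60))), 0.1)

  # grid much coarser than a hexagon: nearest-center fallback is flagged
  coarse <- env_grid("sst", seq(-70, -50, by = 5), seq(-66, -56, by = 5),
                     matrix(3, 5, 3), "2017-05")
  cm3 <- cell_mean_covariate(hud, hexg, coarse)
  expect_true(any(cm3$fallback))
  expect_equal(cm3$value, rep(3, 3))
})

test_that("covariate summaries pool occupied cells equally by colony-month", {
  anchor <- project_laea(c(-60, -59, -100), c(-62, -60.5, -63))
  cells <- hex_cell_of(hexg, anchor[, "x"], anchor[, "y"])
  hud <- structure(data.frame(month = "2017-05", q = cells$q, r = cells$r,
                              deployment_id = c("a1", "a1", "b1"),
                              colony = c("A", "A", "B"), stage = "adult",
                              weight = 1L),
                   class = c("hud", "data.frame"), cell_area = hexg$cell_area)
  sm <- hud_covariate_summary(hud, hexg, env, vars = c("sst", "depth"))
  expect_setequal(unique(sm$colony), c("A", "B"))
  expect_setequal(unique(sm$var), c("sst", "depth"))
  a_sst <- sm[sm$colony == "A" & sm$var == "sst", ]
  expect_equal(a_sst$n_cells, 2)
  # the pooled mean is the mean of the SST field at the two cell centroids
  cc <- hex_centroid(hexg, cells$q[1:2], cells$r[1:2])
  ll <- unproject_laea(cc[, "x"], cc[, "y"])
  p <- env$params
  truth <- mean(p$sst_base + p$sst_slope * (ll[, "lat"] + 75) +
                  p$sst_amp * cos(2 * pi * (5 - p$sst_peak_month) / 12))
  expect_lt(abs(a_sst$mean - truth), 0.02)
})

test_that("along-track matching is nearest-cell on the fix's UTC day", {
  g <- daily_env_grid(env, "sic", "2017-07-10")
  # a fix exactly at a grid-cell center matches that cell's value
  i <- 150; j <- 40
  fx <- data.frame(timestamp = as.POSIXct("2017-07-10 14:00", tz = "UTC"),
                   lon = g$lon[i], lat = g$lat[j])
  m <- along_track_match(fx, env)
  expect_equal(m$sic, g$data[i, j])
  expect_false(m$flag_missing)

  # fixes poleward of the 50% isocline latitude match SIC > 50
  lat50 <- sic_isocline_lat(env$params, 7, 50)
  fx2 <- data.frame(timestamp = as.POSIXct("2017-07-10 14:00", tz = "UTC") +
                      (0:9) * 3600,
                    lon = seq(-140, -80, length.out = 10),
                    lat = lat50 - 2)
  m2 <- along_track_match(fx2, env)
  expect_true(all(m2$sic > 50))

  # a day outside the grid year is flagged, not interpolated
  fx3 <- data.frame(timestamp = as.POSIXct("2031-07-10 14:00", tz = "UTC"),
                    lon = -100, lat = -60)
  m3 <- along_track_match(fx3, env)
  expect_true(m3$flag_missing)
  expect_true(is.na(m3$sic))
})

test_that("ice residence fraction counts interval-weighted time in ice", {
  t0 <- as.POSIXct("2017-07-01", tz = "UTC")
  mk <- function(sic) data.frame(time = t0 + 3600 * seq_along(sic) - 3600,
                                 lon = -100, lat = -60, sic = sic,
                                 sst = 0, flag_missing = FALSE)
  expect_equal(ice_residence_fraction(mk(rep(0, 50)))$fraction, 0)
  expect_equal(ice_residence_fraction(mk(rep(80, 50)))$fraction, 1)
  # 1 of 100 equal intervals in ice -> 0.01 (101 fixes, one in-ice interval)
  sic <- rep(0, 101); sic[7] <- 40
  r <- ice_residence_fraction(mk(sic))
  expect_equal(r$fraction, 0.01, tolerance = 1e-12)
  expect_equal(r$mean_sic_in_ice, 40)
})

test_that("isocline polygons close correctly against the domain", {
  lon <- seq(-120, -80, by = 1); lat <- seq(-70, -50, by = 0.5)
  # field = latitude: the -60 contour is a single boundary-closed region
  latfield <- list(lon = lon, lat = lat,
                   data = outer(rep(1, length(lon)), lat))
  rings <- extract_isocline_polygons(latfield, -60, "below")
  expect_equal(length(rings), 1)
  a <- polygon_set_area(rings)
  # oracle: spherical area of the lon/lat band south of -60
  R <- 6371
  band <- R^2 * (40 * pi / 180) *
    (sin(-60 * pi / 180) - sin(-70 * pi / 180))
  expect_equal(a, band, tolerance = 0.02)

  # constant field: full domain or empty per inequality side
  constf <- list(lon = lon, lat = lat,
                 data = matrix(10, length(lon), length(lat)))
  expect_equal(length(extract_isocline_polygons(constf, 5, "below")), 0)
  full <- extract_isocline_polygons(constf, 5, "above")
  expect_equal(length(full), 1)
  dom <- R^2 * (40 * pi / 180) * (sin(-50 * pi / 180) - sin(-70 * pi / 180))
  expect_equal(polygon_set_area(full), dom, tolerance = 0.02)

  # {SIC >= 50} band area under the July logistic field vs closed form
  sicJ <- env$sic[["2017-07"]]
  ice <- extract_isocline_polygons(sicJ, 50, "above")
  a_ice <- polygon_set_area(ice)
  lat50 <- sic_isocline_lat(env$params, 7, 50)
  closed <- R^2 * (180 * pi / 180) *
    (sin(lat50 * pi / 180) - sin(-75 * pi / 180))
  expect_equal(a_ice, closed, tolerance = 0.02)
})

test_that("habitat areas behave on degenerate inputs", {
  lon <- seq(-150, -60, by = 1); lat <- seq(-70, -52, by = 0.5)
  z0 <- matrix(0, length(lon), length(lat))
  sst0 <- env_grid("sst", lon, lat, z0, "2017-06")
  sic0 <- env_grid("sic", lon, lat, z0, "2017-06")
  ha <- habitat_area(sst0, sic0, land = list(), lon_window = c(-180, 0))
  R <- 6371
  dom <- R^2 * (90 * pi / 180) * (sin(-52 * pi / 180) - sin(-70 * pi / 180))
  expect_equal(ha$open_water_km2, dom, tolerance = 0.01)
  expect_equal(ha$miz_km2, 0)
  # land covering the whole domain removes everything
  all_land <- list(list(lon = c(-160, -50, -50, -160),
                        lat = c(-71, -71, -51, -51)))
  ha2 <- habitat_area(sst0, sic0, land = all_land)
  expect_equal(ha2$open_water_km2, 0, tolerance = 1e-6)
  expect_equal(ha2$miz_km2, 0)
})

test_that("polygon habitat areas match the rasterized oracle within 2%", {
  for (m in c("2017-05", "2017-07", "2017-09")) {
    hp <- habitat_area(env$sst[[m]], env$sic[[m]], env$land,
                       method = "polygon")
    hr <- habitat_area(env$sst[[m]], env$sic[[m]], env$land,
                       method = "raster")
    expect_equal(hp$open_water_km2, hr$open_water_km2, tolerance = 0.02)
    expect_equal(hp$miz_km2, hr$miz_km2, tolerance = 0.02)
  }
})

test_that("open water and MIZ regions are disjoint and monotone in SST", {
  m <- "2017-07"
  sic <- env$sic[[m]]; sst <- env$sst[[m]]
  # raster masks are exactly disjoint by the SIC threshold convention
  in_ow <- sst$data <= 2 & sic$data < 5
  in_mz <- sic$data >= 5 & sic$data <= 50
  expect_false(any(in_ow & in_mz))
  # warming the SST field can only shrink open water
  warm <- env_grid("sst", sst$lon, sst$lat, sst$data + 1, m)
  h0 <- habitat_area(sst, sic, env$land, method = "polygon")
  h1 <- habitat_area(warm, sic, env$land, method = "polygon")
  expect_lte(h1$open_water_km2, h0$open_water_km2 + 1)
  expect_equal(h1$miz_km2, h0$miz_km2)
})

test_that("area agreement between methods tightens with resolution", {
  mk_env <- function(lat_step) {
    c2 <- cfg
    c2$grid_spec$lat_step <- lat_step
    c2$grid_spec$lon_step <- 2 * lat_step
    generate_env_grids(c2)
  }
  rel_err <- vapply(c(1, 0.25), function(st) {
    e <- mk_env(st)
    hp <- habitat_area(e$sst[["2017-07"]], e$sic[["2017-07"]], e$land,
                       method = "polygon")
    hr <- habitat_area(e$sst[["2017-07"]], e$sic[["2017-07"]], e$land,
                       method = "raster")
    abs(hp$miz_km2 - hr$miz_km2) / hr$miz_km2
  }, 0)
  expect_lt(rel_err[2], rel_err[1])
})
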