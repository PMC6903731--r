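cfg <- sim_config(seed = 101)

test_that("identical seeds give identical generated data", {
  d <- small_dep()
  t1 <- simulate_true_track(d, "west", cfg)
  t2 <- simulate_true_track(d, "west", cfg)
  expect_identical(t1, t2)
  f1 <- observe_argos(t1, cfg)
  f2 <- observe_argos(t2, cfg)
  expect_identical(f1, f2)
  # and a different seed changes them
  t3 <- simulate_true_track(d, "west", sim_config(seed = 102))
  expect_false(identical(t1$x, t3$x))
})

test_that("tracks start at the release location and honor degenerate params", {
  d <- small_dep(duration_days = 10)
  tr <- simulate_true_track(d, "local", cfg)
  expect_equal(c(tr$lon[1], tr$lat[1]), c(d$lon, d$lat), tolerance = 1e-9)
  expect_true(all(diff(as.numeric(tr$time)) == 7200))
  expect_true(all(is.finite(tr$x) & is.finite(tr$y)))

  cfg0 <- cfg
  cfg0$ctcrw_params$local$sigma <- 0
  tr0 <- simulate_true_track(d, "local", cfg0)
  expect_equal(max(abs(tr0$x - tr0$x[1])), 0)
  expect_equal(max(abs(tr0$y - tr0$y[1])), 0)
  cfg_bad <- cfg
  cfg_bad$ctcrw_params$local$beta <- 0
  expect_error(simulate_true_track(d, "local", cfg_bad), "beta")
})

test_that("westward drift dominates: negative net longitude, > 500 km reach", {
  cfgw <- cfg
  cfgw$drift_speed <- 40
  cfgw$ctcrw_params$west$sigma <- 5
  d <- small_dep("w1", duration_days = 100)
  tr <- simulate_true_track(d, "west", cfgw)
  lu <- pengwinter:::unwrap_lon(tr$lon)
  expect_lt(lu[length(lu)] - lu[1], 0)
  md <- max_distance(tr, c(d$lon, d$lat))
  expect_gt(md, 500)
  expect_equal(md, 4000, tolerance = 0.1)
})

test_that("local stationary spread matches the OU closed form", {
  cfgl <- sim_config(seed = 77)
  d <- small_dep("ou", duration_days = 10000)
  tr <- simulate_true_track(d, "local", cfgl)
  a <- cfgl$local_attraction
  b <- cfgl$ctcrw_params$local$beta
  s <- cfgl$ctcrw_params$local$sigma
  sd_theory <- sqrt(s^2 / (2 * a * b * (a + b)))
  c0 <- project_laea(d$lon, d$lat)
  burn <- 2000
  emp <- c(sd(tr$x[-(1:burn)] - c0[1, 1]), sd(tr$y[-(1:burn)] - c0[1, 2]))
  expect_equal(emp[1], sd_theory, tolerance = 0.1)
  expect_equal(emp[2], sd_theory, tolerance = 0.1)
})

test_that("fix times fall inside the daily duty-cycle window", {
  d <- small_dep("duty", duration_days = 60)
  fx <- observe_argos(simulate_true_track(d, "local", cfg), cfg)
  hrs <- as.numeric(format(fx$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(fx$timestamp, "%M", tz = "UTC")) / 60
  expect_true(all(hrs >= 12 & hrs < 18))
  expect_true(!is.unsorted(fx$timestamp))
})

test_that("argos observation error matches the class model", {
  # zero error everywhere: observed == interpolated truth
  cfg0 <- cfg
  cfg0$argos_class_probs <- c(`3` = 1, `2` = 0, `1` = 0, `0` = 0,
                              A = 0, B = 0, Z = 0)
  cfg0$argos_class_sd <- c(`3` = 0, `2` = 0, `1` = 0, `0` = 0, A = 0, B = 0)
  cfg0$missing_ellipse_frac <- 0
  d <- small_dep("z0", duration_days = 20)
  tr <- simulate_true_track(d, "local", cfg0)
  fx <- observe_argos(tr, cfg0)
  ti <- as.numeric(tr$time)
  x_true <- approx(ti, tr$x, xout = as.numeric(fx$timestamp))$y
  fxy <- project_laea(fx$lon, fx$lat)
  expect_equal(fxy[, "x"], x_true, tolerance = 1e-6)

  # Monte-Carlo: 10 000 class-B fixes at sd 10 km recover the sd within 2%
  cfgB <- cfg
  cfgB$argos_class_probs <- c(`3` = 0, `2` = 0, `1` = 0, `0` = 0,
                              A = 0, B = 1, Z = 0)
  cfgB$fixes_per_window <- 25
  cfgB$missing_ellipse_frac <- 0
  dB <- small_dep("mc", duration_days = 420)
  cfgB2 <- cfgB; cfgB2$ctcrw_params$local$sigma <- 0
  trB <- simulate_true_track(dB, "local", cfgB2)
  fxB <- observe_argos(trB, cfgB2)
  expect_gt(nrow(fxB), 10000)
  exy <- project_laea(fxB$lon, fxB$lat)
  c0 <- project_laea(dB$lon, dB$lat)
  expect_equal(sd(exy[, "x"] - c0[1, 1]), 10, tolerance = 0.02)
  expect_equal(sd(exy[, "y"] - c0[1, 2]), 10, tolerance = 0.02)
})

test_that("synthetic environmental fields honor their analytic forms", {
  env <- generate_env_grids(cfg)
  p <- env$params
  # July: everything south of the ice-edge latitude has SIC > 50%
  sicJ <- env$sic[["2017-07"]]
  edge <- sic_isocline_lat(p, 7, 50)
  south <- sicJ$lat < edge - 1e-9
  expect_true(all(sicJ$data[, south] > 50))
  # ice edge advances north from March to September
  edges <- vapply(3:9, function(m) sic_isocline_lat(p, m, 50), 0)
  expect_true(all(diff(edges) > 0))
  # the 5% isocline at 100 W sits within one grid cell of the closed form
  lat5 <- sic_isocline_lat(p, 7, 5)
  i <- which.min(abs(sicJ$lon + 100))
  prof <- sicJ$data[i, ]
  j <- max(which(prof >= 5))
  expect_true(lat5 >= sicJ$lat[j] - 0.25 && lat5 <= sicJ$lat[j + 1] + 0.25)
  # zero seasonal+meridional amplitude makes SST constant
  cfg_flat <- cfg
  cfg_flat$env_params$sst_amp <- 0
  cfg_flat$env_params$sst_slope <- 0
  env_flat <- generate_env_grids(cfg_flat)
  expect_equal(diff(range(env_flat$sst[["2017-07"]]$data)), 0)
  # SIC bounds
  for (m in c("2017-03", "2017-09"))
    expect_true(all(env$sic[[m]]$data >= 0 & env$sic[[m]]$data <= 100))
  # extent must cover the colonies
  cfg_small <- cfg
  cfg_small$grid_spec$lat_max <- -70
  expect_error(generate_env_grids(cfg_small), "colony")
})

test_that("daily grids stay consistent with their monthly field", {
  env <- generate_env_grids(cfg)
  g_m <- env$sic[["2017-07"]]
  for (dd in c("2017-07-03", "2017-07-21")) {
    g_d <- daily_env_grid(env, "sic", dd)
    dev <- abs(g_d$data - g_m$data)
    # field-wide AR(1) perturbation: bounded well within a few sds
    expect_lt(max(dev), 6 * env$params$daily_ar1_sd /
                sqrt(1 - env$params$daily_ar1_phi^2))
    expect_true(all(g_d$data >= 0 & g_d$data <= 100))
  }
  expect_error(daily_env_grid(env, "sic", "2031-01-01"), "outside")
})

test_that("environmental grids and land mask round-trip through text files", {
  cfg_tiny <- cfg
  cfg_tiny$grid_spec <- list(lon_min = -70, lon_max = -50, lon_step = 2,
                             lat_min = -66, lat_max = -56, lat_step = 2)
  env <- generate_env_grids(cfg_tiny)
  dir <- tempfile("envio")
  write_env_grids(env, dir)
  back <- read_env_grids(dir)
  expect_equal(back$sst[["2017-07"]]$data, env$sst[["2017-07"]]$data)
  expect_equal(back$depth$data, env$depth$data)
  expect_equal(back$land, env$land)
  expect_equal(back$daily_noise$sic, env$daily_noise$sic)
})
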