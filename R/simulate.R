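# Synthetic telemetry generator: study configuration, behaviour-specific
# true tracks, and duty-cycled Argos observations with class-dependent error.
#
# The generator is first-class, tested code: its defaults define the study
# conditions (three Antarctic Peninsula colonies, a 12:00-18:00 UTC duty
# cycle, ~6 fixes per day, local/east/west movement behaviours) and every
# downstream stage is exercised against it.

KM_PER_DEG_LAT <- pi * EARTH_RADIUS_KM / 180  # 111.195 km

#' Default Argos location-class error model
#'
#' Isotropic per-axis Gaussian error standard deviations by location class,
#' in km. Class Z carries no usable location (grossly corrupted in the
#' generator, screened out by QC).
#'
#' @return named numeric vector over classes 3, 2, 1, 0, A, B.
#' @export
argos_class_sd <- function() {
  c(`3` = 0.25, `2` = 0.5, `1` = 1.5, `0` = 5, A = 5, B = 10)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: colonies, stage and behaviour
#' mixes, movement-model parameters per behaviour, the Argos sampling model,
#' the environmental-field parameters, and the master seed. Defaults follow
#' the deployment design of the study being emulated: three colonies
#' (Admiralty Bay, Cape Shirreff, Cierva Cove), tags transmitting daily
#' 12:00--18:00 UTC with about 6 fixes per day, and local / eastbound /
#' westbound winter movement behaviours.
#'
#' @param colony_locations data.frame with `colony`, `lon`, `lat`.
#' @param stage_mix named fractions over `adult`, `juvenile` (sum 1).
#' @param behavior_mix named fractions over `local`, `east`, `west` (sum 1).
#' @param release_window UTC date range (length 2, `Date`) of tag releases.
#' @param track_length_days list with `meanlog`, `sdlog` per stage for the
#'   lognormal transmission-lifetime draw.
#' @param ctcrw_params list per behaviour of `beta` (velocity
#'   autocorrelation rate, 1/day) and `sigma` (velocity volatility,
#'   km/day^1.5).
#' @param local_attraction position mean-reversion rate toward the colony
#'   for local birds (1/day).
#' @param front_attraction cross-front position mean-reversion rate for
#'   migrants (1/day).
#' @param drift_speed along-front drift for migrants, km/day.
#' @param front_lats latitudes (deg) of the synthetic front polylines:
#'   `pf` (Polar Front) and `saccf` (migration corridor).
#' @param argos_class_probs distribution over classes 3,2,1,0,A,B,Z (sum 1).
#' @param argos_class_sd per-class isotropic error sd, km (see
#'   [argos_class_sd()]).
#' @param z_corrupt_km scale of the gross corruption applied to class-Z
#'   positions, km.
#' @param missing_ellipse_frac fraction of fixes with unspecified
#'   error-ellipse fields.
#' @param duty_cycle daily UTC transmission window, hours (length 2,
#'   default 12--18, a 6 h window).
#' @param fixes_per_window mean number of fixes per daily window.
#' @param grid_spec environmental grid extent/resolution.
#' @param env_params analytic field parameters (see [generate_env_grids()]).
#' @param seed master integer seed; together with the configuration it
#'   fully determines all generated data.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(
    colony_locations = data.frame(
      colony = c("Admiralty Bay", "Cape Shirreff", "Cierva Cove"),
      lon = c(-58.469, -60.789, -60.984),
      lat = c(-62.236, -62.460, -64.143)),
    stage_mix = c(adult = 0.8, juvenile = 0.2),
    behavior_mix = c(local = 0.66, east = 0.07, west = 0.27),
    release_window = as.Date(c("2017-02-18", "2017-03-09")),
    track_length_days = list(adult = list(meanlog = log(75), sdlog = 0.7),
                             juvenile = list(meanlog = log(13), sdlog = 0.5)),
    ctcrw_params = list(local = list(beta = 1, sigma = 20),
                        east = list(beta = 1, sigma = 30),
                        west = list(beta = 1, sigma = 30)),
    local_attraction = 0.1,
    front_attraction = 0.05,
    drift_speed = 25,
    front_lats = c(pf = -58, saccf = -62),
    argos_class_probs = c(`3` = 0.10, `2` = 0.15, `1` = 0.20, `0` = 0.20,
                          A = 0.15, B = 0.15, Z = 0.05),
    argos_class_sd = pengwinter::argos_class_sd(),
    z_corrupt_km = 1000,
    missing_ellipse_frac = 0.03,
    duty_cycle = c(12, 18),
    fixes_per_window = 6,
    grid_spec = list(lon_min = -180, lon_max = 0, lon_step = 0.5,
                     lat_min = -75, lat_max = -50, lat_step = 0.05),
    env_params = default_env_params(),
    seed = 1L) {
  stopifnot(abs(sum(behavior_mix) - 1) < 1e-8,
            abs(sum(argos_class_probs) - 1) < 1e-8,
            abs(sum(stage_mix) - 1) < 1e-8,
            all(argos_class_sd >= 0),
            diff(duty_cycle) > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %d colonies, behaviors %s, duty %02d:00-%02d:00 UTC, seed %d>\n",
              nrow(x$colony_locations),
              paste(sprintf("%s %.2f", names(x$behavior_mix), x$behavior_mix),
                    collapse = ", "),
              x$duty_cycle[1], x$duty_cycle[2], x$seed))
  invisible(x)
}

# exact transition (T) and innovation covariance (Q) over an interval dt for
# the linear state (p, v): dp = -alpha p dt + v dt, dv = -beta v dt + sigma dW.
# alpha = 0 is the plain continuous-time correlated random walk.
ou2_step <- function(alpha, beta, sigma, dt) {
  eb <- exp(-beta * dt)
  if (alpha == 0) {
    Tm <- matrix(c(1, 0, (1 - eb) / beta, eb), 2, 2)
    q11 <- sigma^2 / beta^2 *
      (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta))
    q12 <- sigma^2 * (1 - eb)^2 / (2 * beta^2)
  } else {
    if (abs(alpha - beta) < 1e-10) alpha <- beta * (1 + 1e-8)
    ea <- exp(-alpha * dt)
    d <- beta - alpha
    Tm <- matrix(c(ea, 0, (ea - eb) / d, eb), 2, 2)
    e2a <- ea^2; e2b <- eb^2; eab <- ea * eb
    q11 <- sigma^2 / d^2 *
      ((1 - e2a) / (2 * alpha) - 2 * (1 - eab) / (alpha + beta) +
         (1 - e2b) / (2 * beta))
    q12 <- sigma^2 / d *
      ((1 - eab) / (alpha + beta) - (1 - e2b) / (2 * beta))
  }
  q22 <- sigma^2 * (1 - eb^2) / (2 * beta)
  list(T = Tm, Q = matrix(c(q11, q12, q12, q22), 2, 2))
}

# simulate one axis of the (p, v) system from p0, v0 = 0 over n steps of dt
sim_ou2_axis <- function(n, alpha, beta, sigma, dt, p0 = 0) {
  sq <- ou2_step(alpha, beta, sigma, dt)
  p <- numeric(n + 1); v <- numeric(n + 1)
  p[1] <- p0
  if (all(sq$Q == 0)) {
    L <- matrix(0, 2, 2)
  } else {
    L <- t(chol(sq$Q + diag(1e-12, 2)))
  }
  Tm <- sq$T
  z <- matrix(stats::rnorm(2 * n), 2, n)
  for (i in seq_len(n)) {
    e <- L %*% z[, i]
    p[i + 1] <- Tm[1, 1] * p[i] + Tm[1, 2] * v[i] + e[1]
    v[i + 1] <- Tm[2, 2] * v[i] + e[2]
  }
  list(p = p, v = v)
}

#' Simulate a behaviour-specific true track on a 2-h clock
#'
#' Integrates the continuous-time correlated random walk exactly on the
#' output clock. Local birds add mean-reversion of position toward the
#' colony; migrants add a constant along-front drift (eastward positive,
#' westward negative) plus cross-front mean-reversion toward the synthetic
#' SACCF front latitude. The first position is exactly the release location.
#'
#' @param deployment list/row with `deployment_id`, `colony`, `lon`, `lat`
#'   (colony location), `release_time` (POSIXct UTC), `duration_days`.
#' @param behavior `"local"`, `"east"` or `"west"`.
#' @param config a [sim_config()].
#' @param seed integer; defaults to a sub-seed derived from the config seed
#'   and the deployment id.
#' @param step_hours output clock interval.
#' @return a `data.frame` of class `"true_track"` with `time`, `x`, `y`
#'   (km, working plane), `lon`, `lat`, `vx`, `vy` (km/day) and attributes
#'   `deployment_id`, `behavior`.
#' @export
simulate_true_track <- function(deployment, behavior, config = sim_config(),
                                seed = NULL, step_hours = 2) {
  behavior <- match.arg(behavior, c("local", "east", "west"))
  pars <- config$ctcrw_params[[behavior]]
  if (pars$beta <= 0) stop("beta must be strictly positive")
  if (pars$sigma < 0) stop("sigma must be non-negative")
  if (is.null(seed))
    seed <- derive_seed(config$seed, paste0("track-", deployment$deployment_id))
  dt <- step_hours / 24
  n <- max(1L, floor(deployment$duration_days * 24 / step_hours))
  times <- as.POSIXct(deployment$release_time, tz = "UTC") +
    seq(0, n) * step_hours * 3600
  res <- with_seed(seed, {
    if (behavior == "local") {
      c0 <- project_laea(deployment$lon, deployment$lat)
      ax <- sim_ou2_axis(n, config$local_attraction, pars$beta, pars$sigma, dt)
      ay <- sim_ou2_axis(n, config$local_attraction, pars$beta, pars$sigma, dt)
      x <- ax$p + c0[1, "x"]; y <- ay$p + c0[1, "y"]
      ll <- unproject_laea(x, y)
      list(x = x, y = y, lon = ll[, "lon"], lat = ll[, "lat"],
           vx = ax$v, vy = ay$v)
    } else {
      # front-following frame: s = along-front km, q = cross-front km
      fl <- config$front_lats[["saccf"]]
      dir <- if (behavior == "east") 1 else -1
      as_ <- sim_ou2_axis(n, 0, pars$beta, pars$sigma, dt)
      q0 <- (deployment$lat - fl) * KM_PER_DEG_LAT
      aq <- sim_ou2_axis(n, config$front_attraction, pars$beta, pars$sigma, dt,
                         p0 = q0)
      s <- as_$p + dir * config$drift_speed * dt * seq(0, n)
      lat <- fl + aq$p / KM_PER_DEG_LAT
      lon <- normalize_lon(deployment$lon +
                             s / (KM_PER_DEG_LAT * cos(fl * pi / 180)))
      xy <- project_laea(lon, lat)
      list(x = xy[, "x"], y = xy[, "y"], lon = lon, lat = lat,
           vx = as_$v + dir * config$drift_speed, vy = aq$v)
    }
  })
  out <- data.frame(time = times, x = res$x, y = res$y,
                    lon = res$lon, lat = res$lat, vx = res$vx, vy = res$vy)
  attr(out, "deployment_id") <- deployment$deployment_id
  attr(out, "behavior") <- behavior
  class(out) <- c("true_track", "data.frame")
  out
}

#' Observe a true track through the Argos sampling model
#'
#' Fix times are drawn only inside the daily duty-cycle window (Poisson
#' count per day, uniform within the window), positions are linearly
#' interpolated from the true track and perturbed with isotropic Gaussian
#' error of the sampled location class; class-Z fixes get grossly corrupted
#' positions; a configured fraction of fixes have missing error-ellipse
#' fields. Output rows are time-sorted.
#'
#' @param track a [simulate_true_track()] result.
#' @param config a [sim_config()].
#' @param seed integer; defaults to a sub-seed from config seed + id.
#' @return data.frame with columns `deployment_id`, `timestamp`, `lon`,
#'   `lat`, `lc_class`, `ellipse_semi_major_m`, `ellipse_semi_minor_m`,
#'   `ellipse_orientation_deg`.
#' @export
observe_argos <- function(track, config = sim_config(), seed = NULL) {
  id <- attr(track, "deployment_id")
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("argos-", id))
  t0 <- track$time[1]; t1 <- track$time[nrow(track)]
  days <- seq(as.Date(t0, tz = "UTC"), as.Date(t1, tz = "UTC"), by = "day")
  with_seed(seed, {
    counts <- stats::rpois(length(days), config$fixes_per_window)
    day0 <- as.POSIXct(paste0(format(days, "%Y-%m-%d"), " 00:00:00"),
                       tz = "UTC")
    tt <- rep(day0, counts) +
      stats::runif(sum(counts), config$duty_cycle[1] * 3600,
                   config$duty_cycle[2] * 3600)
    tt <- round(tt)  # Argos reports whole seconds
    tt <- sort(unique(tt[tt >= t0 & tt <= t1]))
    nf <- length(tt)
    if (nf == 0) return_empty <- TRUE else return_empty <- FALSE
    if (return_empty) {
      empty_fix_table()
    } else {
    tn <- as.numeric(track$time); tq <- as.numeric(tt)
    x <- stats::approx(tn, track$x, xout = tq)$y
    y <- stats::approx(tn, track$y, xout = tq)$y
    cls <- sample(names(config$argos_class_probs), nf, replace = TRUE,
                  prob = config$argos_class_probs)
    sd_km <- ifelse(cls == "Z", 0, config$argos_class_sd[cls])
    x <- x + stats::rnorm(nf, 0, sd_km)
    y <- y + stats::rnorm(nf, 0, sd_km)
    isZ <- cls == "Z"
    if (any(isZ)) {
      th <- stats::runif(sum(isZ), 0, 2 * pi)
      rr <- config$z_corrupt_km * (0.5 + stats::runif(sum(isZ)))
      x[isZ] <- x[isZ] + rr * cos(th)
      y[isZ] <- y[isZ] + rr * sin(th)
    }
    ll <- unproject_laea(x, y)
    semi <- sd_km * 1000
    semi[isZ] <- NA_real_
    miss <- stats::runif(nf) < config$missing_ellipse_frac
    semi[miss] <- NA_real_
    orient <- ifelse(is.na(semi), NA_real_, 0)
    data.frame(deployment_id = id, timestamp = tt,
               lon = ll[, "lon"], lat = ll[, "lat"], lc_class = cls,
               ellipse_semi_major_m = semi, ellipse_semi_minor_m = semi,
               ellipse_orientation_deg = orient)
    }
  })
}

empty_fix_table <- function() {
  data.frame(deployment_id = character(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             lon = numeric(0), lat = numeric(0), lc_class = character(0),
             ellipse_semi_major_m = numeric(0),
             ellipse_semi_minor_m = numeric(0),
             ellipse_orientation_deg = numeric(0))
}

#' Write an Argos fix table as CSV
#'
#' Timestamps are written as ISO-8601 UTC; missing ellipse fields are
#' written empty.
#'
#' @param fixes a fix table (see [observe_argos()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(as.POSIXct(fixes$timestamp, tz = "UTC"),
                          "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a deployment metadata table as CSV
#' @param deployments deployment table (see [generate_deployments()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deployments_csv <- function(deployments, path) {
  out <- deployments
  out$release_time <- format(as.POSIXct(out$release_time, tz = "UTC"),
                             "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a deployment metadata table written by [write_deployments_csv()]
#' @param path CSV file.
#' @return deployment data.frame with POSIXct `release_time`.
#' @export
read_deployments_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$release_time <- as.POSIXct(d$release_time, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%OSZ")
  d
}

#' Draw a deployment table from the simulation configuration
#'
#' Samples colony (uniform over colonies unless `n_per_colony` given),
#' stage, behaviour and transmission lifetime for `n` deployments inside
#' the release window.
#'
#' @param config a [sim_config()].
#' @param n number of deployments.
#' @param n_per_colony optional integer vector over colonies (overrides `n`).
#' @return data.frame with `deployment_id`, `colony`, `lon`, `lat`,
#'   `stage`, `behavior`, `release_time`, `duration_days`.
#' @export
generate_deployments <- function(config = sim_config(), n = 50,
                                 n_per_colony = NULL) {
  cl <- config$colony_locations
  with_seed(derive_seed(config$seed, "deployments"), {
    if (is.null(n_per_colony)) {
      ci <- sample(nrow(cl), n, replace = TRUE)
    } else {
      stopifnot(length(n_per_colony) == nrow(cl))
      ci <- rep(seq_len(nrow(cl)), n_per_colony)
      n <- length(ci)
    }
    stage <- sample(names(config$stage_mix), n, replace = TRUE,
                    prob = config$stage_mix)
    behavior <- sample(names(config$behavior_mix), n, replace = TRUE,
                       prob = config$behavior_mix)
    rel <- as.POSIXct(config$release_window[1], tz = "UTC") +
      stats::runif(n) * as.numeric(diff(config$release_window)) * 86400
    dur <- vapply(stage, function(s) {
      tl <- config$track_length_days[[s]]
      stats::rlnorm(1, tl$meanlog, tl$sdlog)
    }, 0)
    data.frame(deployment_id = sprintf("dep%03d", seq_len(n)),
               colony = cl$colony[ci], lon = cl$lon[ci], lat = cl$lat[ci],
               stage = stage, behavior = behavior,
               release_time = trunc(rel, "hours"),
               duration_days = pmax(1, dur))
  })
}
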