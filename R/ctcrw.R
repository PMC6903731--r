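# Continuous-time correlated random walk (CTCRW) state-space model.
#
# Per axis the state is (position p, velocity v) with Ornstein-Uhlenbeck
# velocity: dv = -beta v dt + sigma dW, dp = v dt. Over an interval D the
# exact discretization is
#   v' = e^(-bD) v + N(0, s^2 (1 - e^(-2bD)) / (2b))
#   p' = p + v (1 - e^(-bD)) / b + noise,
#     Var(p) = (s^2/b^2) (D - 2(1 - e^(-bD))/b + (1 - e^(-2bD))/(2b))
#     Cov(p, v) = (s^2/(2 b^2)) (1 - e^(-bD))^2
# The x and y axes of the working equal-area plane are independent given
# (beta, sigma), which are shared between axes (isotropic movement).
# Observations are fix positions with class-dependent Gaussian error.

DIFFUSE_VEL_VAR <- 1e6  # initial velocity variance, km^2/day^2

# interval-wise transition/innovation coefficients, vectorized over dt
# (days); expm1 and a short-interval series keep q11 accurate where the
# closed form cancels catastrophically (beta * dt << 1)
ctcrw_disc <- function(beta, sigma, dt) {
  x <- beta * dt
  om <- -expm1(-x)          # 1 - e^(-beta dt), cancellation-free
  om2 <- -expm1(-2 * x)     # 1 - e^(-2 beta dt)
  q11 <- sigma^2 / beta^2 * (dt - 2 * om / beta + om2 / (2 * beta))
  small <- x < 1e-4
  if (any(small))            # q11 = sigma^2 (dt^3/3 - beta dt^4/4 + ...)
    q11[small] <- sigma^2 * dt[small]^3 * (1 / 3 - x[small] / 4)
  list(tb = 1 - om,
       k1 = om / beta,
       q11 = q11,
       q12 = sigma^2 * om^2 / (2 * beta^2),
       q22 = sigma^2 * om2 / (2 * beta))
}

# Kalman filter (and optional RTS smoother) for one axis.
# t: times in days (strictly increasing); z: observations (NA = no obs);
# r2: observation variances (km^2) aligned with z.
# Initial state at t[1]: mean (z_first, 0), var diag(r2_first, DIFFUSE_VEL_VAR);
# the first observation is then assimilated like any other.
kf_axis <- function(t, z, r2, beta, sigma, smooth = FALSE) {
  n <- length(t)
  if (n < 1) stop("need at least one time point")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  iobs <- which(!is.na(z))
  if (!length(iobs)) stop("need at least one observation")
  d <- ctcrw_disc(beta, sigma, diff(t))
  mp <- matrix(0, n, 2); Pp <- matrix(0, n, 3)  # predicted (p11, p12, p22)
  mf <- matrix(0, n, 2); Pf <- matrix(0, n, 3)
  i1 <- iobs[1]
  m1 <- 0; m2 <- 0; p11 <- 0; p12 <- 0; p22 <- 0
  ll <- 0
  for (k in seq_len(n)) {
    if (k == 1) {
      m1 <- z[i1]; m2 <- 0
      p11 <- r2[i1]; p12 <- 0; p22 <- DIFFUSE_VEL_VAR
      if (i1 != 1) { m1 <- z[i1] }  # position prior centered on first obs
    } else {
      j <- k - 1
      tb <- d$tb[j]; k1 <- d$k1[j]
      m1n <- m1 + k1 * m2
      m2n <- tb * m2
      p11n <- p11 + 2 * k1 * p12 + k1 * k1 * p22 + d$q11[j]
      p12n <- tb * (p12 + k1 * p22) + d$q12[j]
      p22n <- tb * tb * p22 + d$q22[j]
      m1 <- m1n; m2 <- m2n; p11 <- p11n; p12 <- p12n; p22 <- p22n
    }
    mp[k, ] <- c(m1, m2); Pp[k, ] <- c(p11, p12, p22)
    if (!is.na(z[k])) {
      S <- p11 + r2[k]
      if (S <= 0) stop("degenerate innovation variance")
      K1 <- p11 / S; K2 <- p12 / S
      innov <- z[k] - m1
      ll <- ll - 0.5 * (log(2 * pi * S) + innov * innov / S)
      m1 <- m1 + K1 * innov
      m2 <- m2 + K2 * innov
      # Joseph-form update keeps the covariance PSD
      one <- 1 - K1
      np11 <- one * one * p11 + K1 * K1 * r2[k]
      np12 <- one * (p12 - K2 * p11) + K1 * K2 * r2[k]
      np22 <- p22 - 2 * K2 * p12 + K2 * K2 * p11 + K2 * K2 * r2[k]
      p11 <- np11; p12 <- np12; p22 <- np22
    }
    mf[k, ] <- c(m1, m2); Pf[k, ] <- c(p11, p12, p22)
  }
  out <- list(loglik = ll, mp = mp, Pp = Pp, mf = mf, Pf = Pf)
  if (smooth) {
    ms <- mf; Ps <- Pf
    for (k in rev(seq_len(n - 1))) {
      tb <- d$tb[k]; k1 <- d$k1[k]
      # D = Pf_k T', J = D inv(Pp_{k+1})
      d11 <- Pf[k, 1] + k1 * Pf[k, 2]; d12 <- tb * Pf[k, 2]
      d21 <- Pf[k, 2] + k1 * Pf[k, 3]; d22 <- tb * Pf[k, 3]
      pp11 <- Pp[k + 1, 1]; pp12 <- Pp[k + 1, 2]; pp22 <- Pp[k + 1, 3]
      det <- pp11 * pp22 - pp12 * pp12
      if (det <= 1e-12 * max(1, pp11 * pp22)) det <- det + 1e-12
      J11 <- (d11 * pp22 - d12 * pp12) / det
      J12 <- (-d11 * pp12 + d12 * pp11) / det
      J21 <- (d21 * pp22 - d22 * pp12) / det
      J22 <- (-d21 * pp12 + d22 * pp11) / det
      dm1 <- ms[k + 1, 1] - mp[k + 1, 1]; dm2 <- ms[k + 1, 2] - mp[k + 1, 2]
      ms[k, 1] <- mf[k, 1] + J11 * dm1 + J12 * dm2
      ms[k, 2] <- mf[k, 2] + J21 * dm1 + J22 * dm2
      e11 <- Ps[k + 1, 1] - pp11; e12 <- Ps[k + 1, 2] - pp12
      e22 <- Ps[k + 1, 3] - pp22
      # J E J' with E symmetric
      a11 <- J11 * e11 + J12 * e12; a12 <- J11 * e12 + J12 * e22
      a21 <- J21 * e11 + J22 * e12; a22 <- J21 * e12 + J22 * e22
      Ps[k, 1] <- Pf[k, 1] + a11 * J11 + a12 * J12
      Ps[k, 2] <- Pf[k, 2] + a11 * J21 + a12 * J22
      Ps[k, 3] <- Pf[k, 3] + a21 * J21 + a22 * J22
      Ps[k, c(1, 3)] <- pmax(Ps[k, c(1, 3)], 0)
    }
    out$ms <- ms; out$Ps <- Ps
  }
  out
}

# project fixes, build the union time base (fix times + output clock),
# and per-fix observation sds
prep_ctcrw_data <- function(fixes, error_model, error_scale = 1,
                            step_hours = 2, release_time = NULL) {
  stopifnot(nrow(fixes) >= 2)
  fixes <- fixes[order(fixes$timestamp), , drop = FALSE]
  dup <- duplicated(fixes$timestamp)
  if (any(dup)) fixes <- fixes[!dup, , drop = FALSE]
  ts <- as.POSIXct(fixes$timestamp, tz = "UTC")
  if (is.null(release_time)) release_time <- ts[1]
  release_time <- as.POSIXct(release_time, tz = "UTC")
  grid <- seq(release_time, ts[length(ts)], by = step_hours * 3600)
  t0 <- min(release_time, ts[1])
  tf_days <- as.numeric(difftime(ts, t0, units = "days"))
  tg_days <- as.numeric(difftime(grid, t0, units = "days"))
  allt <- sort(unique(round(c(tf_days, tg_days), 9)))
  xy <- project_laea(fixes$lon, fixes$lat)
  zx <- rep(NA_real_, length(allt)); zy <- zx; r <- zx
  io <- match(round(tf_days, 9), allt)
  zx[io] <- xy[, "x"]; zy[io] <- xy[, "y"]
  sd_km <- unname(error_model[as.character(fixes$lc_class)]) * error_scale
  if (any(is.na(sd_km)))
    stop("fix location classes without an error model entry: ",
         paste(unique(fixes$lc_class[is.na(sd_km)]), collapse = ", "))
  r[io] <- sd_km^2
  gi <- match(round(tg_days, 9), allt)
  list(t = allt, zx = zx, zy = zy, r2 = r, t0 = t0,
       is_grid = seq_along(allt) %in% gi, grid_idx = gi,
       grid_times = grid, release_time = release_time,
       fix_times = ts, n_fixes = length(ts))
}

#' Exact CTCRW log-likelihood via the Kalman filter
#'
#' Gaussian marginal log-likelihood of the observed fix positions under the
#' linear-Gaussian CTCRW, x and y axes independent given the parameters.
#'
#' @param params list with `beta` (1/day) and `sigma` (km/day^1.5), both
#'   strictly positive; optional `error_scale` multiplier on the class sds.
#' @param fixes fix data.frame (`timestamp`, `lon`, `lat`, `lc_class`) with
#'   at least two rows and strictly increasing times.
#' @param error_model named per-class sd vector in km
#'   (default [argos_class_sd()]).
#' @return the log-likelihood (scalar).
#' @export
kalman_loglik <- function(params, fixes, error_model = argos_class_sd()) {
  stopifnot(params$beta > 0, params$sigma > 0)
  scl <- if (is.null(params$error_scale)) 1 else params$error_scale
  ts <- as.POSIXct(fixes$timestamp, tz = "UTC")
  if (any(diff(as.numeric(ts)) <= 0)) stop("fix times must be increasing")
  t <- as.numeric(difftime(ts, ts[1], units = "days"))
  xy <- project_laea(fixes$lon, fixes$lat)
  r2 <- (unname(error_model[as.character(fixes$lc_class)]) * scl)^2
  kf_axis(t, xy[, "x"], r2, params$beta, params$sigma)$loglik +
    kf_axis(t, xy[, "y"], r2, params$beta, params$sigma)$loglik
}

#' Fit the CTCRW state-space model to a filtered Argos track
#'
#' Maximizes the Kalman-filter likelihood over `log(beta)` and `log(sigma)`
#' (optionally also a log error-scale on the class sds) with BFGS from a
#' default start and one jittered restart, then runs the fixed-interval
#' (RTS) smoother over the union of the fix times and the output clock.
#'
#' @param fixes QC-retained fixes of one deployment (>= 2 rows).
#' @param error_model named per-class position-error sd, km.
#' @param init optional list with starting `beta`, `sigma`.
#' @param params optional list with fixed `beta`, `sigma`
#'   (and `error_scale`); when supplied no optimization is performed.
#' @param fit_error_scale estimate a common multiplier on the class sds.
#' @param step_hours output clock interval (2 h default).
#' @param release_time start of the output clock (default: first fix).
#' @return an object of class `"ctcrw"`; see [predict.ctcrw()],
#'   [simulate.ctcrw()], [residuals.ctcrw()].
#' @examples
#' cfg <- sim_config(seed = 7)
#' dep <- list(deployment_id = "d1", colony = "Cape Shirreff",
#'             lon = -60.789, lat = -62.46,
#'             release_time = as.POSIXct("2017-03-01", tz = "UTC"),
#'             duration_days = 30)
#' trk <- simulate_true_track(dep, "local", cfg)
#' fx <- observe_argos(trk, cfg)
#' fx <- filter_quality(fx)
#' fit <- fit_ctcrw(fx)
#' coef(fit)
#' @export
fit_ctcrw <- function(fixes, error_model = argos_class_sd(), init = NULL,
                      params = NULL, fit_error_scale = FALSE,
                      step_hours = 2, release_time = NULL) {
  dat <- prep_ctcrw_data(fixes, error_model, step_hours = step_hours,
                         release_time = release_time)
  io <- which(!is.na(dat$zx))
  to <- dat$t[io]; zxo <- dat$zx[io]; zyo <- dat$zy[io]; r2o <- dat$r2[io]
  nll <- function(theta) {
    b <- exp(theta[1]); s <- exp(theta[2])
    scl <- if (length(theta) > 2) exp(theta[3]) else 1
    v <- tryCatch(
      -(kf_axis(to, zxo, r2o * scl^2, b, s)$loglik +
          kf_axis(to, zyo, r2o * scl^2, b, s)$loglik),
      error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  if (is.null(params)) {
    if (is.null(init)) {
      # crude moment start: rms displacement speed sets sigma's scale
      io <- which(!is.na(dat$zx))
      dts <- pmax(diff(dat$t[io]), 1e-3)
      sp <- sqrt(diff(dat$zx[io])^2 + diff(dat$zy[io])^2) / dts
      init <- list(beta = 1, sigma = max(1, stats::median(sp)))
    }
    th0 <- c(log(init$beta), log(init$sigma))
    if (fit_error_scale) th0 <- c(th0, 0)
    starts <- list(th0, th0 + c(0.7, -0.7, rep(0, length(th0) - 2)))
    opts <- lapply(starts, function(s)
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-10)))
    best <- opts[[which.min(vapply(opts, `[[`, 0, "value"))]]
    converged <- any(vapply(opts, function(o) o$convergence == 0, TRUE))
    theta <- best$par
    params <- list(beta = exp(theta[1]), sigma = exp(theta[2]),
                   error_scale = if (fit_error_scale) exp(theta[3]) else 1)
    value <- -best$value
    optim_out <- best
  } else {
    if (is.null(params$error_scale)) params$error_scale <- 1
    theta <- c(log(params$beta), log(params$sigma))
    value <- -nll(theta)
    converged <- TRUE
    optim_out <- NULL
  }
  r2 <- dat$r2 * params$error_scale^2
  sx <- kf_axis(dat$t, dat$zx, r2, params$beta, params$sigma, smooth = TRUE)
  sy <- kf_axis(dat$t, dat$zy, r2, params$beta, params$sigma, smooth = TRUE)
  structure(list(params = params, loglik = value, converged = converged,
                 optim = optim_out, data = dat, sx = sx, sy = sy,
                 error_model = error_model, step_hours = step_hours,
                 deployment_id = if (nrow(fixes)) fixes$deployment_id[1]
                                 else NA_character_,
                 call = match.call()),
            class = "ctcrw")
}

#' @export
print.ctcrw <- function(x, ...) {
  cat("Continuous-time correlated random walk fit\n")
  cat(sprintf("  deployment: %s  (%d fixes, %.1f days)\n", x$deployment_id,
              x$data$n_fixes,
              diff(range(x$data$t))))
  cat(sprintf("  beta  = %.4g 1/day\n  sigma = %.4g km/day^1.5\n",
              x$params$beta, x$params$sigma))
  if (x$params$error_scale != 1)
    cat(sprintf("  error scale = %.4g\n", x$params$error_scale))
  cat(sprintf("  log-likelihood: %.2f   converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

#' @export
coef.ctcrw <- function(object, ...) {
  c(beta = object$params$beta, sigma = object$params$sigma,
    error_scale = object$params$error_scale)
}

#' @export
logLik.ctcrw <- function(object, ...) {
  structure(object$loglik,
            df = 2 + (object$params$error_scale != 1),
            nobs = object$data$n_fixes, class = "logLik")
}

#' @export
summary.ctcrw <- function(object, ...) {
  est <- coef(object)
  vel_sd <- object$params$sigma / sqrt(2 * object$params$beta)
  out <- list(coef = est, loglik = object$loglik,
              converged = object$converged,
              n_fixes = object$data$n_fixes,
              span_days = diff(range(object$data$t)),
              stationary_speed_sd = vel_sd,
              deployment_id = object$deployment_id)
  class(out) <- "summary.ctcrw"
  out
}

#' @export
print.summary.ctcrw <- function(x, ...) {
  cat("CTCRW fit summary\n")
  cat(sprintf("  deployment %s: %d fixes over %.1f days\n",
              x$deployment_id, x$n_fixes, x$span_days))
  print(x$coef)
  cat(sprintf("  stationary per-axis speed sd: %.2f km/day\n",
              x$stationary_speed_sd))
  cat(sprintf("  logLik %.2f, converged %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Smoothed track from a CTCRW fit
#'
#' Returns the smoothing-distribution mean (and position variances) of the
#' track, by default on the regular output clock.
#'
#' @param object a [fit_ctcrw()] object.
#' @param which `"grid"` for the regular clock (release to last fix),
#'   `"all"` for the union of clock and fix times.
#' @param ... unused.
#' @return data.frame with `time`, `x`, `y` (km), `lon`, `lat`,
#'   `var_x`, `var_y` (km^2), `vx`, `vy` (km/day).
#' @export
predict.ctcrw <- function(object, which = c("grid", "all"), ...) {
  which <- match.arg(which)
  idx <- if (which == "grid") object$data$grid_idx
         else seq_along(object$data$t)
  x <- object$sx$ms[idx, 1]; y <- object$sy$ms[idx, 1]
  ll <- unproject_laea(x, y)
  data.frame(time = if (which == "grid") object$data$grid_times
             else object$data$t0 + object$data$t[idx] * 86400,
             x = x, y = y, lon = ll[, "lon"], lat = ll[, "lat"],
             vx = object$sx$ms[idx, 2], vy = object$sy$ms[idx, 2],
             var_x = object$sx$Ps[idx, 1], var_y = object$sy$Ps[idx, 1])
}

#' Standardized one-step-ahead innovations of a CTCRW fit
#'
#' @param object a [fit_ctcrw()] object.
#' @param ... unused.
#' @return data.frame with `time`, `resid_x`, `resid_y` at fix times; under
#'   a well-specified model these are approximately iid standard normal.
#' @export
residuals.ctcrw <- function(object, ...) {
  d <- object$data
  io <- which(!is.na(d$zx))
  r2 <- d$r2[io] * object$params$error_scale^2
  sx_ <- (d$zx[io] - object$sx$mp[io, 1]) / sqrt(object$sx$Pp[io, 1] + r2)
  sy_ <- (d$zy[io] - object$sy$mp[io, 1]) / sqrt(object$sy$Pp[io, 1] + r2)
  data.frame(time = d$t0 + d$t[io] * 86400, resid_x = sx_, resid_y = sy_)
}

#' Diagnostic plot of a CTCRW fit
#'
#' Observed fixes and the smoothed mean path in the working plane.
#'
#' @param x a [fit_ctcrw()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ctcrw <- function(x, ...) {
  d <- x$data
  io <- which(!is.na(d$zx))
  graphics::plot(d$zx[io], d$zy[io], pch = 16, cex = 0.5, col = "grey50",
                 xlab = "x (km)", ylab = "y (km)", asp = 1, ...)
  graphics::lines(x$sx$ms[, 1], x$sy$ms[, 1], col = "firebrick")
  graphics::legend("topleft", bty = "n", pch = c(16, NA), lty = c(NA, 1),
                   col = c("grey50", "firebrick"),
                   legend = c("fixes", "smoothed path"))
  invisible(x)
}

# one simulation-smoothing draw for one axis (Durbin-Koopman):
# simulate an unconditional state path and observations, smooth them, and
# mean-correct against the smoothed means from the real observations.
dk_draw_axis <- function(d, real_smooth, beta, sigma, r2) {
  t <- d$t; n <- length(t)
  io <- which(!is.na(r2) & r2 >= 0 & !is.na(d$zx_axis))
  disc <- ctcrw_disc(beta, sigma, diff(t))
  # unconditional path from the model's initial law
  p <- numeric(n); v <- numeric(n)
  i1 <- which(!is.na(d$zx_axis))[1]
  p[1] <- stats::rnorm(1, d$zx_axis[i1], sqrt(r2[i1]))
  v[1] <- stats::rnorm(1, 0, sqrt(DIFFUSE_VEL_VAR))
  for (k in seq_len(n - 1)) {
    q11 <- disc$q11[k]; q12 <- disc$q12[k]; q22 <- disc$q22[k]
    # correlated (p, v) innovation via 2x2 Cholesky
    l11 <- sqrt(max(q11, 0))
    l21 <- if (l11 > 0) q12 / l11 else 0
    l22 <- sqrt(max(q22 - l21 * l21, 0))
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    p[k + 1] <- p[k] + disc$k1[k] * v[k] + l11 * z1
    v[k + 1] <- disc$tb[k] * v[k] + l21 * z1 + l22 * z2
  }
  zplus <- rep(NA_real_, n)
  zplus[io] <- p[io] + stats::rnorm(length(io), 0, sqrt(r2[io]))
  sm_plus <- kf_axis(t, zplus, r2, beta, sigma, smooth = TRUE)
  real_smooth$ms[, 1] + (p - sm_plus$ms[, 1])
}

#' Draw imputed tracks from the smoothing distribution
#'
#' Joint draws of the whole track from the fitted model's smoothing
#' distribution via simulation smoothing: an unconditional state path and
#' matching observations are simulated, both are smoothed, and the draw is
#' the real smoothed mean plus the simulated smoothing error. Draws are
#' therefore jointly correct samples, not independent per-time noise.
#'
#' @param object a converged [fit_ctcrw()] object.
#' @param nsim number of track draws.
#' @param seed integer seed (required for reproducibility across calls).
#' @param ... unused.
#' @return an `"imputed_tracks"` object: `times` (POSIXct, exact output
#'   clock from release to last fix), arrays `x`, `y` of dim
#'   `(n_times, nsim)` (km), `deployment_id`, `seed`.
#' @export
simulate.ctcrw <- function(object, nsim = 100, seed = NULL, ...) {
  if (!object$converged) stop("refusing to impute from a non-converged fit")
  if (is.null(seed)) seed <- derive_seed(0L, paste0("imp-", object$deployment_id))
  d <- object$data
  r2 <- d$r2 * object$params$error_scale^2
  if (all(!is.finite(r2) | is.na(r2)))
    stop("no usable observations")
  gi <- d$grid_idx
  n <- length(gi)
  xs <- matrix(NA_real_, n, nsim)
  ys <- matrix(NA_real_, n, nsim)
  with_seed(seed, {
    for (s in seq_len(nsim)) {
      dx <- d; dx$zx_axis <- d$zx
      xs[, s] <- dk_draw_axis(dx, object$sx, object$params$beta,
                              object$params$sigma, r2)[gi]
      dy <- d; dy$zx_axis <- d$zy
      ys[, s] <- dk_draw_axis(dy, object$sy, object$params$beta,
                              object$params$sigma, r2)[gi]
    }
  })
  structure(list(times = d$grid_times, x = xs, y = ys,
                 deployment_id = object$deployment_id, seed = seed,
                 step_hours = object$step_hours),
            class = "imputed_tracks")
}

#' Multiple track imputation from a CTCRW fit
#'
#' Convenience wrapper over [simulate.ctcrw()] using the study default of
#' 100 alternative tracks per deployment.
#'
#' @param fit a converged [fit_ctcrw()] object.
#' @param n_draws number of alternative tracks.
#' @param seed integer seed.
#' @return an `"imputed_tracks"` object.
#' @export
impute_tracks <- function(fit, n_draws = 100, seed = 1L) {
  simulate(fit, nsim = n_draws, seed = seed)
}

#' @export
print.imputed_tracks <- function(x, ...) {
  cat(sprintf("<imputed_tracks %s: %d draws x %d times (%g-h clock), seed %d>\n",
              x$deployment_id, ncol(x$x), nrow(x$x), x$step_hours, x$seed))
  invisible(x)
}

#' Convert imputed tracks to a long data.frame
#'
#' @param x an `"imputed_tracks"` object.
#' @param ... unused.
#' @return data.frame with `deployment_id`, `draw`, `time`, `x`, `y`,
#'   `lon`, `lat`.
#' @export
as.data.frame.imputed_tracks <- function(x, ...) {
  nd <- ncol(x$x); nt <- nrow(x$x)
  ll <- unproject_laea(as.vector(x$x), as.vector(x$y))
  data.frame(deployment_id = x$deployment_id,
             draw = rep(seq_len(nd), each = nt),
             time = rep(x$times, nd),
             x = as.vector(x$x), y = as.vector(x$y),
             lon = ll[, "lon"], lat = ll[, "lat"])
}
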