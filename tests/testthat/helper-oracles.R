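# Shared fixtures and independent oracles used across the suite.

# a minimal deployment record at the Cape Shirreff tagging site
small_dep <- function(id = "d1", duration_days = 30,
                      lon = -60.789, lat = -62.46,
                      release = "2017-03-01") {
  list(deployment_id = id, colony = "Cape Shirreff", lon = lon, lat = lat,
       release_time = as.POSIXct(release, tz = "UTC"),
       duration_days = duration_days)
}

# simulate fixes directly from the CTCRW (no behaviour terms): an
# independent generator for the parameter-recovery and oracle tests
sim_ctcrw_fixes <- function(seed, days = 200, beta = 1, sigma = 30,
                            class_sd = 0.25, fixes_per_day = 6,
                            lc = "3") {
  set.seed(seed)
  dt <- 2 / 24
  n <- days * 12
  eb <- exp(-beta * dt)
  q11 <- sigma^2 / beta^2 * (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta))
  q12 <- sigma^2 * (1 - eb)^2 / (2 * beta^2)
  q22 <- sigma^2 * (1 - eb^2) / (2 * beta)
  L <- t(chol(matrix(c(q11, q12, q12, q22), 2, 2)))
  px <- py <- vx <- vy <- numeric(n + 1)
  for (i in 1:n) {
    ex <- L %*% rnorm(2); ey <- L %*% rnorm(2)
    px[i + 1] <- px[i] + (1 - eb) / beta * vx[i] + ex[1]
    vx[i + 1] <- eb * vx[i] + ex[2]
    py[i + 1] <- py[i] + (1 - eb) / beta * vy[i] + ey[1]
    vy[i + 1] <- eb * vy[i] + ey[2]
  }
  tt <- as.POSIXct("2017-03-01", tz = "UTC") + (0:n) * 7200
  hrs <- as.numeric(format(tt, "%H", tz = "UTC"))
  cand <- which(hrs >= 12 & hrs < 18)
  keep <- sort(sample(cand, min(length(cand), days * fixes_per_day)))
  x0 <- project_laea(-60, -62)
  xs <- px[keep] + x0[1, 1] + rnorm(length(keep), 0, class_sd)
  ys <- py[keep] + x0[1, 2] + rnorm(length(keep), 0, class_sd)
  ll <- unproject_laea(xs, ys)
  data.frame(deployment_id = sprintf("sim%03d", seed),
             timestamp = tt[keep], lon = ll[, 1], lat = ll[, 2],
             lc_class = lc)
}

# brute-force joint-Gaussian CTCRW log-likelihood: builds the full joint
# state covariance by explicit propagation and evaluates the marginal
# density of the observed positions directly (no Kalman recursion)
joint_ctcrw_loglik <- function(params, fixes,
                               error_model = argos_class_sd()) {
  beta <- params$beta; sigma <- params$sigma
  ts <- as.POSIXct(fixes$timestamp, tz = "UTC")
  t <- as.numeric(difftime(ts, ts[1], units = "days"))
  xy <- project_laea(fixes$lon, fixes$lat)
  r2 <- (unname(error_model[as.character(fixes$lc_class)]))^2
  n <- length(t)
  ll <- 0
  for (axis in 1:2) {
    z <- xy[, axis]
    m <- numeric(2 * n)
    C <- matrix(0, 2 * n, 2 * n)
    m[1:2] <- c(z[1], 0)
    C[1:2, 1:2] <- diag(c(r2[1], 1e6))
    for (i in seq_len(n - 1)) {
      dt <- t[i + 1] - t[i]
      eb <- exp(-beta * dt)
      Tm <- matrix(c(1, 0, (1 - eb) / beta, eb), 2, 2)
      q11 <- sigma^2 / beta^2 *
        (dt - 2 * (1 - eb) / beta + (1 - eb^2) / (2 * beta))
      q12 <- sigma^2 * (1 - eb)^2 / (2 * beta^2)
      q22 <- sigma^2 * (1 - eb^2) / (2 * beta)
      ii <- (2 * i - 1):(2 * i); jj <- ii + 2
      m[jj] <- Tm %*% m[ii]
      for (k in seq_len(i)) {
        kk <- (2 * k - 1):(2 * k)
        C[jj, kk] <- Tm %*% C[ii, kk]
        C[kk, jj] <- t(C[jj, kk])
      }
      C[jj, jj] <- Tm %*% C[ii, ii] %*% t(Tm) +
        matrix(c(q11, q12, q12, q22), 2, 2)
    }
    H <- matrix(0, n, 2 * n)
    for (i in seq_len(n)) H[i, 2 * i - 1] <- 1
    S <- H %*% C %*% t(H) + diag(r2, n)
    mu <- as.vector(H %*% m)
    ll <- ll - 0.5 * (n * log(2 * pi) +
                        as.numeric(determinant(S)$modulus) +
                        as.numeric(t(z - mu) %*% solve(S, z - mu)))
  }
  ll
}

# hand-built HUD with unit cell area, for overlap set-arithmetic oracles
mk_hud <- function(month, q, deployment_id, colony, r = 0,
                   stage = "adult", cell_area = 1) {
  structure(data.frame(month = month, q = q, r = r,
                       deployment_id = deployment_id, colony = colony,
                       stage = stage, weight = 1L),
            class = c("hud", "data.frame"), cell_area = cell_area)
}
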