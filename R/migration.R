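# Migration-strategy classification and deployment movement summaries:
# maximum great-circle distance from the tagging site, local/east/west
# binning, and the month-weighted net swim speeds.

#' Maximum great-circle distance from an origin
#'
#' @param track data.frame with `lon`, `lat` (normally the smoothed mean
#'   path on the 2-h clock).
#' @param origin length-2 `(lon, lat)` of the tagging location.
#' @return maximum haversine distance in km.
#' @export
max_distance <- function(track, origin) {
  stopifnot(nrow(track) >= 1)
  max(haversine_km(origin[1], origin[2], track$lon, track$lat))
}

# dateline-safe cumulative longitudes: wrap successive differences into
# (-180, 180] and accumulate
unwrap_lon <- function(lon) {
  d <- diff(lon)
  d <- ((d + 180) %% 360) - 180
  cumsum(c(lon[1], d))
}

#' Classify a deployment as local, east or west
#'
#' Local if the whole track stays within `radius` km of the tagging
#' location. Otherwise the bin is the sign of the net longitudinal
#' displacement (dateline-unwrapped) at the time of maximum distance;
#' if that is zero the displacement at the last position decides, and a
#' track that is still zero is returned as `NA` with a warning.
#'
#' @param track data.frame with `lon`, `lat` (smoothed mean path).
#' @param origin length-2 `(lon, lat)` of the tagging location.
#' @param radius local-bin radius, km (study value 500).
#' @return `"local"`, `"east"`, `"west"`, or `NA_character_`.
#' @export
classify_migration <- function(track, origin, radius = 500) {
  dd <- haversine_km(origin[1], origin[2], track$lon, track$lat)
  if (max(dd) <= radius) return("local")
  lu <- unwrap_lon(c(origin[1], track$lon))[-1]
  dlon <- lu - origin[1]
  disp <- dlon[which.max(dd)]
  if (disp == 0) disp <- dlon[length(dlon)]
  if (disp == 0) {
    warning("non-local track with zero net longitudinal displacement")
    return(NA_character_)
  }
  if (disp > 0) "east" else "west"
}

#' Net swim speeds from a smoothed track
#'
#' Monthly net speed is the great-circle distance between the first and
#' last position inside the calendar month (month windows are closed, so a
#' position on the month boundary closes one month and opens the next)
#' divided by the elapsed time between those positions. The mean daily
#' speed is the mean of the monthly net speeds weighted by the number of
#' calendar days tracked in each month; the maximum daily speed is the
#' largest single-day net displacement divided by 86400 s. Months or days
#' with fewer than two positions are excluded.
#'
#' @param track data.frame with `time` (POSIXct UTC), `lon`, `lat`.
#' @return list with `mean_daily` and `max_daily` (m/s), and `monthly`,
#'   a data.frame of per-month net distances (km), elapsed days, speeds
#'   and day weights.
#' @export
swim_speeds <- function(track) {
  stopifnot(nrow(track) >= 1)
  tt <- as.POSIXct(track$time, tz = "UTC")
  o <- order(tt)
  tt <- tt[o]; lon <- track$lon[o]; lat <- track$lat[o]
  mon_keys <- sort(unique(format(tt, "%Y-%m", tz = "UTC")))
  rows <- lapply(mon_keys, function(m) {
    m0 <- as.POSIXct(paste0(m, "-01 00:00:00"), tz = "UTC")
    m1 <- as.POSIXct(paste0(format(seq(as.Date(paste0(m, "-01")),
                                       by = "month", length.out = 2)[2]),
                            " 00:00:00"), tz = "UTC")
    k <- which(tt >= m0 & tt <= m1)
    ndays <- length(unique(format(tt[k[tt[k] < m1]], "%Y-%m-%d", tz = "UTC")))
    if (length(k) < 2)
      return(data.frame(month = m, net_km = NA_real_, elapsed_days = NA_real_,
                        speed_ms = NA_real_, days_tracked = ndays))
    i <- k[1]; j <- k[length(k)]
    net <- haversine_km(lon[i], lat[i], lon[j], lat[j])
    el <- as.numeric(difftime(tt[j], tt[i], units = "secs"))
    data.frame(month = m, net_km = net, elapsed_days = el / 86400,
               speed_ms = if (el > 0) net * 1000 / el else NA_real_,
               days_tracked = ndays)
  })
  monthly <- do.call(rbind, rows)
  ok <- !is.na(monthly$speed_ms)
  mean_daily <- if (any(ok))
    sum(monthly$speed_ms[ok] * monthly$days_tracked[ok]) /
      sum(monthly$days_tracked[ok]) else NA_real_
  # per-day net displacement over closed day windows
  day_keys <- unique(format(tt, "%Y-%m-%d", tz = "UTC"))
  dmax <- NA_real_
  for (dk in day_keys) {
    d0 <- as.POSIXct(paste0(dk, " 00:00:00"), tz = "UTC")
    k <- which(tt >= d0 & tt <= d0 + 86400)
    if (length(k) < 2) next
    net_m <- haversine_km(lon[k[1]], lat[k[1]],
                          lon[k[length(k)]], lat[k[length(k)]]) * 1000
    sp <- net_m / 86400
    if (is.na(dmax) || sp > dmax) dmax <- sp
  }
  list(mean_daily = mean_daily, max_daily = dmax, monthly = monthly)
}

#' Per-deployment migration summary table
#'
#' One row per deployment with the classification, tracked duration,
#' maximum distance and net swim speeds, mirroring the grouping keys of
#' the study's deployment summary (colony, direction, stage).
#'
#' @param paths named list of smoothed mean paths (data.frames with
#'   `time`, `lon`, `lat`), names = deployment ids.
#' @param meta deployment metadata with `deployment_id`, `colony`,
#'   `stage`, `lon`, `lat` (tagging location).
#' @param radius local-bin radius, km.
#' @return data.frame of class `"migration_summary"`.
#' @export
migration_summary <- function(paths, meta, radius = 500) {
  rows <- lapply(names(paths), function(id) {
    tr <- paths[[id]]
    d <- meta[meta$deployment_id == id, , drop = FALSE]
    if (!nrow(d)) stop("no metadata for deployment ", id)
    origin <- c(d$lon[1], d$lat[1])
    sp <- swim_speeds(tr)
    data.frame(deployment_id = id, colony = d$colony[1], stage = d$stage[1],
               direction = classify_migration(tr, origin, radius),
               duration_days = as.numeric(difftime(max(tr$time),
                                                   min(tr$time),
                                                   units = "days")),
               max_distance_km = max_distance(tr, origin),
               mean_daily_swim_speed_ms = sp$mean_daily,
               max_daily_swim_speed_ms = sp$max_daily)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("migration_summary", "data.frame")
  out
}

#' Group a migration summary by colony, direction and stage
#'
#' @param summary a [migration_summary()] result.
#' @return data.frame with per-group tag counts, mean (range) duration and
#'   maximum distance, and mean swim speeds.
#' @export
migration_group_table <- function(summary) {
  f <- interaction(summary$colony, summary$direction, summary$stage,
                   drop = TRUE)
  rows <- lapply(split(summary, f), function(s)
    data.frame(colony = s$colony[1], direction = s$direction[1],
               stage = s$stage[1], n_tags = nrow(s),
               mean_duration_d = mean(s$duration_days),
               min_duration_d = min(s$duration_days),
               max_duration_d = max(s$duration_days),
               mean_max_distance_km = mean(s$max_distance_km),
               min_max_distance_km = min(s$max_distance_km),
               max_max_distance_km = max(s$max_distance_km),
               mean_daily_speed_ms = mean(s$mean_daily_swim_speed_ms,
                                          na.rm = TRUE),
               max_daily_speed_ms = max(s$max_daily_swim_speed_ms,
                                        na.rm = TRUE)))
  out <- do.call(rbind, rows)
  out <- out[order(out$colony, out$direction, out$stage), , drop = FALSE]
  rownames(out) <- NULL
  out
}
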