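# Environmental covariate extraction and the two-part habitat-area index.
#
# Isoclines are extracted as marching-squares contour lines
# (grDevices::contourLines) and closed against the domain boundary into
# region polygons. Region intersections ({SST <= 2} with {SIC < 5}; the
# 5--50% SIC band) are contoured from the pointwise max of the signed
# level-set fields, which equals the polygon intersection up to sub-cell
# interpolation. Land differencing clips region rings against the convex
# components of the land mask (Sutherland-Hodgman). Areas are evaluated by
# projecting ring vertices into the equal-area plane and applying the
# shoelace formula; a rasterized cell-count method is provided as an
# independent cross-check.

#' Mean covariate value per HUD hexagon
#'
#' The mean of the environmental grid cells whose centers fall inside each
#' occupied hexagon; hexagons containing no grid center fall back to the
#' value at the grid center nearest the hexagon centroid and are flagged.
#' Missing grid values are excluded from means.
#'
#' @param hud an [assign_cells()] result (all months, or pre-filtered).
#' @param hexgrid the [build_hexgrid()] that produced the HUD.
#' @param grid an [env_grid()]. If the grid carries a `"YYYY-MM"` time key,
#'   only HUD cells of that month are summarized.
#' @return data.frame with `month`, `q`, `r`, `value`, `n_grid_cells`,
#'   `fallback` (logical), `missing` (logical, all grid values NA).
#' @export
cell_mean_covariate <- function(hud, hexgrid, grid) {
  h <- hud
  if (!is.na(grid$time) && nchar(grid$time) == 7)
    h <- hud[hud$month == grid$time, , drop = FALSE]
  cells <- unique(h[, c("month", "q", "r")])
  if (!nrow(cells)) return(cells)
  gl <- expand.grid(lon = grid$lon, lat = grid$lat)
  gxy <- project_laea(gl$lon, gl$lat)
  gcell <- hex_cell_of(hexgrid, gxy[, "x"], gxy[, "y"])
  gval <- as.vector(grid$data)
  key <- paste(gcell$q, gcell$r)
  ckey <- paste(cells$q, cells$r)
  means <- tapply(gval, key, function(v) mean(v, na.rm = TRUE))
  counts <- tapply(!is.na(gval), key, sum)
  cells$value <- as.numeric(means[ckey])
  cells$n_grid_cells <- as.integer(counts[ckey])
  cells$n_grid_cells[is.na(cells$n_grid_cells)] <- 0L
  cells$fallback <- is.na(match(ckey, names(means)))
  if (any(cells$fallback)) {
    cc <- hex_centroid(hexgrid, cells$q[cells$fallback],
                       cells$r[cells$fallback])
    for (i in seq_len(sum(cells$fallback))) {
      di <- (gxy[, "x"] - cc[i, "x"])^2 + (gxy[, "y"] - cc[i, "y"])^2
      cells$value[cells$fallback][i] <- gval[which.min(di)]
    }
  }
  cells$missing <- !is.finite(cells$value)
  rownames(cells) <- NULL
  cells
}

#' Per-colony monthly covariate distributions over the HUD
#'
#' Pools the per-hexagon mean covariate values by colony and month (each
#' occupied cell weighted equally) and summarizes their distribution —
#' the numbers behind monthly environmental-condition boxplots.
#'
#' @param hud an [assign_cells()] result.
#' @param hexgrid the [build_hexgrid()] that produced it.
#' @param env an env grid set (see [generate_env_grids()]).
#' @param vars variables to summarize.
#' @return data.frame with `colony`, `month`, `var`, `n_cells`, `median`,
#'   `q25`, `q75`, `mean`.
#' @export
hud_covariate_summary <- function(hud, hexgrid, env,
                                  vars = c("sst", "sic", "depth",
                                           "u_current")) {
  rows <- list()
  for (v in vars) {
    monthly <- !inherits(env[[v]], "env_grid")
    for (m in sort(unique(hud$month))) {
      grid <- if (monthly) env[[v]][[m]] else env[[v]]
      if (is.null(grid)) next
      cm <- cell_mean_covariate(hud[hud$month == m, , drop = FALSE],
                                hexgrid, grid)
      if (!nrow(cm)) next
      key <- paste(cm$q, cm$r)
      for (cc in sort(unique(hud$colony[hud$month == m]))) {
        hsub <- hud[hud$month == m & hud$colony == cc, , drop = FALSE]
        vals <- cm$value[key %in% paste(hsub$q, hsub$r)]
        vals <- vals[is.finite(vals)]
        if (!length(vals)) next
        qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          colony = cc, month = m, var = v, n_cells = length(vals),
          median = qs[2], q25 = qs[1], q75 = qs[3], mean = mean(vals))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match fixes with daily environmental values along the track
#'
#' Nearest-grid-cell, same-UTC-day matching of each fix with the daily SST
#' and SIC fields. Days without a grid are flagged, never interpolated.
#'
#' @param fixes fix table with `timestamp`, `lon`, `lat`.
#' @param env an env grid set (see [generate_env_grids()]).
#' @return data.frame `time`, `lon`, `lat`, `sst`, `sic`, `flag_missing`.
#' @export
along_track_match <- function(fixes, env) {
  tt <- as.POSIXct(fixes$timestamp, tz = "UTC")
  day <- format(tt, "%Y-%m-%d", tz = "UTC")
  out <- data.frame(time = tt, lon = fixes$lon, lat = fixes$lat,
                    sst = NA_real_, sic = NA_real_, flag_missing = FALSE)
  for (dk in unique(day)) {
    k <- day == dk
    g_sic <- tryCatch(daily_env_grid(env, "sic", dk), error = function(e) NULL)
    g_sst <- tryCatch(daily_env_grid(env, "sst", dk), error = function(e) NULL)
    if (is.null(g_sic) || is.null(g_sst)) {
      out$flag_missing[k] <- TRUE
      next
    }
    out$sic[k] <- env_value_at(g_sic, fixes$lon[k], fixes$lat[k])
    out$sst[k] <- env_value_at(g_sst, fixes$lon[k], fixes$lat[k])
    out$flag_missing[k] <- is.na(out$sic[k]) & is.na(out$sst[k])
  }
  out
}

#' Fraction of tracked time spent in ice-covered water
#'
#' Each matched fix owns the interval to the next fix (the last fix owns
#' none). The fraction is in-ice time over total matched time; the mean
#' SIC over in-ice fixes is reported alongside.
#'
#' @param matches an [along_track_match()] result (single deployment,
#'   time-sorted).
#' @param ice_threshold SIC threshold in percent defining "in ice".
#' @return list with `fraction`, `mean_sic_in_ice`, `time_in_ice_days`,
#'   `total_days`.
#' @export
ice_residence_fraction <- function(matches, ice_threshold = 5) {
  stopifnot(nrow(matches) >= 1)
  tt <- as.numeric(as.POSIXct(matches$time, tz = "UTC"))
  o <- order(tt)
  tt <- tt[o]; sic <- matches$sic[o]
  n <- length(tt)
  if (n == 1)
    return(list(fraction = 0, mean_sic_in_ice = NA_real_,
                time_in_ice_days = 0, total_days = 0))
  iv <- diff(tt)
  in_ice <- !is.na(sic[-n]) & sic[-n] >= ice_threshold
  tot <- sum(iv)
  ice_t <- sum(iv[in_ice])
  ice_fixes <- !is.na(sic) & sic >= ice_threshold
  list(fraction = if (tot > 0) ice_t / tot else 0,
       mean_sic_in_ice = if (any(ice_fixes)) mean(sic[ice_fixes])
                         else NA_real_,
       time_in_ice_days = ice_t / 86400, total_days = tot / 86400)
}

# ---- region polygons from gridded fields --------------------------------

bilinear_at <- function(lon, lat, data, px, py) {
  px <- pmin(max(lon), pmax(min(lon), px))
  py <- pmin(max(lat), pmax(min(lat), py))
  i <- pmin(findInterval(px, lon), length(lon) - 1L)
  j <- pmin(findInterval(py, lat), length(lat) - 1L)
  tx <- (px - lon[i]) / (lon[i + 1] - lon[i])
  ty <- (py - lat[j]) / (lat[j + 1] - lat[j])
  (1 - tx) * (1 - ty) * data[cbind(i, j)] +
    tx * (1 - ty) * data[cbind(i + 1, j)] +
    (1 - tx) * ty * data[cbind(i, j + 1)] +
    tx * ty * data[cbind(i + 1, j + 1)]
}

# boundary parameter of a point on the domain rectangle, walking CCW from
# (x0, y0): bottom, right, top, left
boundary_param <- function(px, py, x0, x1, y0, y1, tol) {
  w <- x1 - x0; h <- y1 - y0
  if (abs(py - y0) < tol) return(px - x0)
  if (abs(px - x1) < tol) return(w + (py - y0))
  if (abs(py - y1) < tol) return(w + h + (x1 - px))
  if (abs(px - x0) < tol) return(2 * w + h + (y1 - py))
  NA_real_
}

# rectangle corner points passed when walking CCW from t1 to t2 (cyclic)
corners_between <- function(t1, t2, x0, x1, y0, y1) {
  w <- x1 - x0; h <- y1 - y0; P <- 2 * (w + h)
  corner_t <- c(w, w + h, w + h + w)           # BR, TR, TL (t=0 is BL)
  corner_x <- c(x1, x1, x0); corner_y <- c(y0, y1, y1)
  # corners at params strictly between t1 and t2 walking forward
  span <- (t2 - t1) %% P
  if (span == 0) span <- P
  dt <- (corner_t - t1) %% P
  # include the BL corner (t = 0)
  dt <- c(dt, (0 - t1) %% P)
  cx <- c(corner_x, x0); cy <- c(corner_y, y0)
  sel <- which(dt > 1e-9 & dt < span - 1e-9)
  if (!length(sel)) return(list(x = numeric(0), y = numeric(0)))
  o <- order(dt[sel])
  list(x = cx[sel][o], y = cy[sel][o])
}

#' Region polygons of a gridded field at a level
#'
#' Marching-squares contours at `level`, closed against the domain
#' boundary, returned as rings oriented so the region satisfying the
#' inequality is the interior (outer rings counter-clockwise, holes
#' clockwise). Coordinates are in the grid's lon/lat degrees.
#'
#' @param grid an [env_grid()] (or any list with `lon`, `lat`, `data`).
#' @param level contour level.
#' @param inside `"below"` for the region `field <= level`, `"above"` for
#'   `field >= level`.
#' @return list of rings `list(x, y, hole)`; empty list if the region is
#'   empty.
#' @export
extract_isocline_polygons <- function(grid, level, inside = c("below", "above")) {
  inside <- match.arg(inside)
  lon <- grid$lon; lat <- grid$lat; z <- grid$data
  stopifnot(length(lon) >= 2, length(lat) >= 2)
  satisfies <- if (inside == "below") function(v) v <= level
               else function(v) v >= level
  x0 <- min(lon); x1 <- max(lon); y0 <- min(lat); y1 <- max(lat)
  tol <- 1e-7 * max(x1 - x0, y1 - y0)
  eps <- 0.25 * min(diff(lon)[1], diff(lat)[1])
  cl <- if (diff(range(z, na.rm = TRUE)) == 0) list()  # constant field
        else grDevices::contourLines(lon, lat, z, levels = level)
  rings <- list()
  opens <- list()
  for (cc in cl) {
    n <- length(cc$x)
    is_closed <- abs(cc$x[1] - cc$x[n]) < tol && abs(cc$y[1] - cc$y[n]) < tol
    if (is_closed) {
      rx <- cc$x[-n]; ry <- cc$y[-n]
      # interior sample: a grid center inside the ring, else skip tiny ring
      gl <- expand.grid(lon = lon, lat = lat)
      ins <- point_in_polygon(gl$lon, gl$lat, rx, ry)
      if (!any(ins)) next
      v <- bilinear_at(lon, lat, z, gl$lon[ins][1], gl$lat[ins][1])
      inside_region <- satisfies(v)
      a <- polygon_area(rx, ry)
      if (inside_region && a < 0) { rx <- rev(rx); ry <- rev(ry) }
      if (!inside_region && a > 0) { rx <- rev(rx); ry <- rev(ry) }
      rings[[length(rings) + 1]] <- list(x = rx, y = ry,
                                         hole = !inside_region)
    } else {
      # orient so the region lies to the left of the traversal
      i <- max(1, floor(n / 2))
      dx <- cc$x[i + 1] - cc$x[i]; dy <- cc$y[i + 1] - cc$y[i]
      nn <- sqrt(dx^2 + dy^2)
      if (nn == 0) next
      mx <- (cc$x[i] + cc$x[i + 1]) / 2 - eps * dy / nn
      my <- (cc$y[i] + cc$y[i + 1]) / 2 + eps * dx / nn
      ok_left <- satisfies(bilinear_at(lon, lat, z, mx, my))
      xs <- cc$x; ys <- cc$y
      if (!ok_left) { xs <- rev(xs); ys <- rev(ys) }
      ts <- boundary_param(xs[1], ys[1], x0, x1, y0, y1, tol * 1e4)
      te <- boundary_param(xs[n], ys[n], x0, x1, y0, y1, tol * 1e4)
      if (is.na(ts) || is.na(te)) next   # does not touch the boundary frame
      opens[[length(opens) + 1]] <- list(x = xs, y = ys, ts = ts, te = te)
    }
  }
  if (!length(opens)) {
    # boundary entirely inside or outside the region; the corner decides
    if (satisfies(z[1, 1])) {
      rings <- c(list(list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1),
                           hole = FALSE)), rings)
    }
    return(rings)
  }
  # stitch open contours with boundary arcs, region kept on the left
  used <- rep(FALSE, length(opens))
  P <- 2 * ((x1 - x0) + (y1 - y0))
  while (any(!used)) {
    s0 <- which(!used)[1]
    used[s0] <- TRUE
    cur <- opens[[s0]]
    ringx <- cur$x; ringy <- cur$y
    t_end <- cur$te; t_close <- opens[[s0]]$ts
    repeat {
      cand <- which(!used)
      dt_close <- (t_close - t_end) %% P
      if (dt_close == 0) dt_close <- P
      nxt <- 0
      best <- dt_close
      for (k in cand) {
        d <- (opens[[k]]$ts - t_end) %% P
        if (d == 0) d <- P
        if (d < best) { best <- d; nxt <- k }
      }
      if (nxt == 0) {
        cb <- corners_between(t_end, t_close, x0, x1, y0, y1)
        ringx <- c(ringx, cb$x); ringy <- c(ringy, cb$y)
        break
      }
      cb <- corners_between(t_end, opens[[nxt]]$ts, x0, x1, y0, y1)
      ringx <- c(ringx, cb$x, opens[[nxt]]$x)
      ringy <- c(ringy, cb$y, opens[[nxt]]$y)
      t_end <- opens[[nxt]]$te
      used[nxt] <- TRUE
    }
    rings[[length(rings) + 1]] <- list(x = ringx, y = ringy, hole = FALSE)
  }
  rings
}

# signed equal-area area (km^2) of a lon/lat ring: densify, project, shoelace
ring_area_km2 <- function(x, y, max_edge_deg = 0.25) {
  if (length(x) < 3) return(0)
  dd <- densify_ring(x, y, max_edge_deg)
  xy <- project_laea(dd$x, dd$y)
  if (any(!is.finite(xy))) stop("projection failure in polygon area")
  polygon_area(xy[, "x"], xy[, "y"])
}

#' Total area of a region polygon set, km^2
#'
#' Signed sum over rings (holes contribute negatively), evaluated in the
#' equal-area working plane.
#'
#' @param rings list of rings from [extract_isocline_polygons()].
#' @return area in km^2.
#' @export
polygon_set_area <- function(rings) {
  if (!length(rings)) return(0)
  sum(vapply(rings, function(r) ring_area_km2(r$x, r$y), 0))
}

# clip every ring against a convex lon/lat ring; orientation is preserved
clip_rings <- function(rings, cx, cy) {
  out <- list()
  for (r in rings) {
    cl <- clip_polygon_convex(r$x, r$y, cx, cy)
    if (length(cl$x) >= 3)
      out[[length(out) + 1]] <- list(x = cl$x, y = cl$y, hole = r$hole)
  }
  out
}

# area of a region polygon set inside a lon window, minus land (km^2)
region_area_minus_land <- function(rings, land, lon_window, lat_range) {
  wx <- c(lon_window[1], lon_window[2], lon_window[2], lon_window[1])
  wy <- c(lat_range[1], lat_range[1], lat_range[2], lat_range[2])
  win <- clip_rings(rings, wx, wy)
  a <- polygon_set_area(win)
  for (lm in land) {
    a <- a - polygon_set_area(clip_rings(win, lm$lon, lm$lat))
  }
  max(a, 0)
}

#' Two-part monthly habitat-area index
#'
#' Open-water habitat is the area with SST at or below `sst_max` and SIC
#' strictly below `sic_open` (between the ice edge, or the coastline when
#' ice is absent, and the isotherm); the marginal ice zone (MIZ) is the
#' area with SIC between `sic_open` and `sic_miz_max`. Both are restricted
#' to the longitude window, clipped against the land mask, and reported in
#' km^2 from the equal-area plane. The two regions are disjoint by
#' construction (SIC < 5 vs SIC >= 5).
#'
#' @param sst,sic monthly [env_grid()]s on a common grid.
#' @param land land-mask polygon list (`list(lon, lat)` convex components).
#' @param lon_window longitude window in degrees (study value 180W--0W).
#' @param sst_max open-water isotherm, degC (inclusive).
#' @param sic_open open-water/MIZ ice isocline, percent (exclusive for
#'   open water, inclusive for the MIZ).
#' @param sic_miz_max outer MIZ isocline, percent (inclusive).
#' @param method `"polygon"` for isocline polygons with land differencing,
#'   `"raster"` for the independent cell-count evaluation.
#' @return one-row data.frame with `month`, `open_water_km2`, `miz_km2`.
#' @export
habitat_area <- function(sst, sic, land, lon_window = c(-180, 0),
                         sst_max = 2, sic_open = 5, sic_miz_max = 50,
                         method = c("polygon", "raster")) {
  method <- match.arg(method)
  stopifnot(identical(sst$lon, sic$lon), identical(sst$lat, sic$lat))
  lon <- sst$lon; lat <- sst$lat
  if (method == "raster") {
    on_land <- matrix(FALSE, length(lon), length(lat))
    gl <- expand.grid(lon = lon, lat = lat)
    for (lm in land)
      on_land <- on_land | matrix(point_in_polygon(gl$lon, gl$lat,
                                                   lm$lon, lm$lat),
                                  length(lon), length(lat))
    in_win <- lon >= lon_window[1] & lon <= lon_window[2]
    ow <- sst$data <= sst_max & sic$data < sic_open & in_win & !on_land
    mz <- sic$data >= sic_open & sic$data <= sic_miz_max & in_win & !on_land
    # exact spherical lon/lat cell areas
    dlam <- (lon[2] - lon[1]) * pi / 180
    dphi2 <- (lat[2] - lat[1]) / 2
    band <- EARTH_RADIUS_KM^2 * dlam *
      (sin((lat + dphi2) * pi / 180) - sin((lat - dphi2) * pi / 180))
    cell_a <- matrix(band, length(lon), length(lat), byrow = TRUE)
    ow_a <- sum(cell_a[ow]); mz_a <- sum(cell_a[mz])
  } else {
    # combined signed level-set fields: region = {g <= 0}
    g_open <- pmax(sst$data - sst_max, sic$data - sic_open)
    g_miz <- pmax(sic_open - sic$data, sic$data - sic_miz_max)
    lat_range <- range(lat)
    r_open <- extract_isocline_polygons(list(lon = lon, lat = lat,
                                             data = g_open), 0, "below")
    r_miz <- extract_isocline_polygons(list(lon = lon, lat = lat,
                                            data = g_miz), 0, "below")
    ow_a <- region_area_minus_land(r_open, land, lon_window, lat_range)
    mz_a <- region_area_minus_land(r_miz, land, lon_window, lat_range)
  }
  data.frame(month = if (is.na(sst$time)) NA_character_ else sst$time,
             open_water_km2 = ow_a, miz_km2 = mz_a)
}

#' Monthly habitat-area series over an environmental grid set
#'
#' @param env an env grid set (see [generate_env_grids()]).
#' @param months subset of `"YYYY-MM"` keys (default: all).
#' @param ... passed to [habitat_area()].
#' @return data.frame with one row per month.
#' @export
habitat_area_series <- function(env, months = names(env$sst), ...) {
  rows <- lapply(months, function(m)
    habitat_area(env$sst[[m]], env$sic[[m]], env$land, ...))
  do.call(rbind, rows)
}
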