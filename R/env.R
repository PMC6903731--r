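# Gridded environmental fields: container, synthetic generator, lookup, I/O.
#
# Grids are regular lon/lat rasters stored as plain matrices. The synthetic
# generator produces analytic fields (logistic sea-ice front, linear-in-
# latitude SST with a seasonal cycle) whose parameters are kept on the
# object, so tests can invert isocline positions in closed form.

#' Construct a gridded environmental field
#'
#' @param var one of `"sst"`, `"sic"`, `"depth"`, `"u_current"`.
#' @param lon,lat strictly increasing coordinate vectors (degrees); values
#'   are cell centers.
#' @param data numeric matrix of dim `length(lon) x length(lat)`.
#' @param time time key: `"YYYY-MM"` for monthly grids, `"YYYY-MM-DD"` for
#'   daily grids, `NA` for static grids.
#' @param units unit string (defaults per variable).
#' @return an object of class `"env_grid"`.
#' @export
env_grid <- function(var, lon, lat, data,
                     time = NA_character_, units = NULL) {
  var <- match.arg(var, c("sst", "sic", "depth", "u_current"))
  stopifnot(is.numeric(lon), is.numeric(lat),
            all(diff(lon) > 0), all(diff(lat) > 0),
            is.matrix(data), nrow(data) == length(lon),
            ncol(data) == length(lat))
  if (var == "sic" && any(data < 0 | data > 100, na.rm = TRUE))
    stop("SIC values must lie in [0, 100]")
  if (is.null(units))
    units <- c(sst = "degC", sic = "percent", depth = "m",
               u_current = "m/s")[[var]]
  structure(list(var = var, units = units, lon = lon, lat = lat,
                 data = data, time = time),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid %s [%s], %d x %d cells, lon %g..%g, lat %g..%g, time %s>\n",
              x$var, x$units, length(x$lon), length(x$lat),
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              ifelse(is.na(x$time), "static", x$time)))
  invisible(x)
}

#' Nearest-cell value lookup on a regular grid
#'
#' @param grid an [env_grid()].
#' @param lon,lat query coordinates (vectors).
#' @return numeric vector of cell values; `NA` outside the grid extent
#'   (beyond half a cell past the outermost centers).
#' @export
env_value_at <- function(grid, lon, lat) {
  ix <- nearest_index(grid$lon, lon)
  iy <- nearest_index(grid$lat, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(ix) & !is.na(iy)
  out[ok] <- grid$data[cbind(ix[ok], iy[ok])]
  out
}

nearest_index <- function(axis, v) {
  step <- if (length(axis) > 1) axis[2] - axis[1] else 1
  i <- round((v - axis[1]) / step) + 1
  i[i < 1 | i > length(axis) | is.na(i)] <- NA_integer_
  as.integer(i)
}

# ---- synthetic fields ----------------------------------------------------

# Analytic forms (lat in degrees, month 1..12):
#   SST(lat, m)  = sst_base + sst_slope*(lat + 75) + sst_amp*cos(2*pi*(m - sst_peak_month)/12)
#   SIC(lat, m)  = 100 / (1 + exp((lat - edge(m)) / sic_width))
#   edge(m)      = edge_mean + edge_amp*cos(2*pi*(m - edge_peak_month)/12)
#   depth(lat)   = shelf/basin blend via tanh around the shelf break
#   u(lat)       = u_base + u_amp*exp(-((lat - acc_lat)/acc_width)^2)
# The SIC p% isocline latitude is edge(m) + sic_width*log((100 - p)/p).

default_env_params <- function() {
  list(
    sst_base = -3.5, sst_slope = 0.32, sst_amp = 0.8, sst_peak_month = 2,
    sic_width = 1.5, edge_mean = -68, edge_amp = 5, edge_peak_month = 9,
    shelf_depth = -400, basin_depth = -4000,
    shelf_north = -61, shelf_south = -65.5, shelf_smooth = 0.7,
    u_base = 0.02, u_amp = 0.12, acc_lat = -58, acc_width = 4,
    daily_ar1_phi = 0.8, daily_ar1_sd = 1.0
  )
}

#' Latitude of a SIC isocline of the synthetic field (closed form)
#'
#' Inverts the logistic sea-ice front of [generate_env_grids()].
#'
#' @param params the `params` element of an env grid set.
#' @param month calendar month 1--12.
#' @param level concentration level in percent, strictly inside (0, 100).
#' @return latitude in degrees at which SIC equals `level`.
#' @export
sic_isocline_lat <- function(params, month, level) {
  stopifnot(level > 0, level < 100)
  edge <- params$edge_mean +
    params$edge_amp * cos(2 * pi * (month - params$edge_peak_month) / 12)
  edge + params$sic_width * log((100 - level) / level)
}

#' Latitude of an SST isotherm of the synthetic field (closed form)
#'
#' @param params the `params` element of an env grid set.
#' @param month calendar month 1--12.
#' @param level temperature in degC.
#' @return latitude in degrees at which SST equals `level`.
#' @export
sst_isotherm_lat <- function(params, month, level) {
  off <- params$sst_amp * cos(2 * pi * (month - params$sst_peak_month) / 12)
  -75 + (level - params$sst_base - off) / params$sst_slope
}

sst_field <- function(lon, lat, month, p) {
  off <- p$sst_amp * cos(2 * pi * (month - p$sst_peak_month) / 12)
  outer(rep(1, length(lon)), p$sst_base + p$sst_slope * (lat + 75) + off)
}

sic_field <- function(lon, lat, month, p) {
  edge <- p$edge_mean + p$edge_amp * cos(2 * pi * (month - p$edge_peak_month) / 12)
  outer(rep(1, length(lon)), 100 / (1 + exp((lat - edge) / p$sic_width)))
}

depth_field <- function(lon, lat, p) {
  shelf <- 0.5 * (tanh((lat - p$shelf_south) / p$shelf_smooth) -
                  tanh((lat - p$shelf_north) / p$shelf_smooth))
  d <- p$basin_depth + (p$shelf_depth - p$basin_depth) * shelf
  outer(rep(1, length(lon)), d)
}

u_field <- function(lon, lat, month, p) {
  u <- p$u_base + p$u_amp * exp(-((lat - p$acc_lat) / p$acc_width)^2)
  outer(rep(1, length(lon)), u) * (1 + 0.05 * cos(2 * pi * month / 12))
}

default_land_mask <- function() {
  # convex polygon components (lon/lat rings, counter-clockwise);
  # a peninsula block south of the colonies plus a continental margin strip
  list(
    list(lon = c(-66, -52, -52, -66), lat = c(-75, -75, -66, -66)),
    list(lon = c(-180, -90, -90, -180), lat = c(-75, -75, -72, -72))
  )
}

#' Generate the synthetic environmental grid set
#'
#' Builds monthly SST, SIC and zonal-current grids, a static bathymetry
#' grid, a land-mask polygon set, and the daily-perturbation series that
#' defines daily SIC/SST grids. SST warms northward with a seasonal offset;
#' SIC is a logistic front in latitude whose edge advances north from March
#' to September; depth has a shallow shelf band at colony latitudes. All
#' parameters of the analytic forms are returned on the object so isocline
#' positions can be computed in closed form.
#'
#' @param config a [sim_config()]; the grid extent must cover the colonies.
#' @param year calendar year of the monthly time axis.
#' @return an object of class `"env_grid_set"`: lists `sst`, `sic`,
#'   `u_current` keyed by `"YYYY-MM"`, a static `depth` grid, `land`
#'   (polygon rings), `params`, `grid_spec` and the daily AR(1) noise
#'   series used by [daily_env_grid()].
#' @export
generate_env_grids <- function(config = sim_config(), year = 2017) {
  gs <- config$grid_spec
  p <- config$env_params
  # cell-center registration (satellite-product convention): the first
  # center sits half a step inside the extent and cells tile it exactly
  lon <- seq(gs$lon_min + gs$lon_step / 2, gs$lon_max, by = gs$lon_step)
  lat <- seq(gs$lat_min + gs$lat_step / 2, gs$lat_max, by = gs$lat_step)
  cl <- config$colony_locations
  if (any(cl$lon < gs$lon_min | cl$lon > gs$lon_max |
          cl$lat < gs$lat_min | cl$lat > gs$lat_max))
    stop("grid extent does not cover all colony locations")
  months <- sprintf("%d-%02d", year, 1:12)
  sst <- sic <- u <- vector("list", 12)
  names(sst) <- names(sic) <- names(u) <- months
  for (m in 1:12) {
    sst[[m]] <- env_grid("sst", lon, lat, sst_field(lon, lat, m, p), months[m])
    sic[[m]] <- env_grid("sic", lon, lat, sic_field(lon, lat, m, p), months[m])
    u[[m]] <- env_grid("u_current", lon, lat, u_field(lon, lat, m, p), months[m])
  }
  depth <- env_grid("depth", lon, lat, depth_field(lon, lat, p))
  # field-wide AR(1) daily perturbations, deterministic in the seed
  ndays <- as.integer(as.Date(sprintf("%d-12-31", year)) -
                      as.Date(sprintf("%d-01-01", year))) + 1L
  rs <- local_rng(derive_seed(config$seed, "env-daily"))
  eps_sic <- as.numeric(stats::filter(stats::rnorm(ndays, 0, p$daily_ar1_sd),
                                      p$daily_ar1_phi, method = "recursive"))
  eps_sst <- as.numeric(stats::filter(stats::rnorm(ndays, 0, 0.2),
                                      p$daily_ar1_phi, method = "recursive"))
  restore_rng(rs)
  structure(list(sst = sst, sic = sic, u_current = u, depth = depth,
                 land = default_land_mask(), params = p,
                 grid_spec = gs, year = year,
                 daily_noise = list(sic = eps_sic, sst = eps_sst)),
            class = "env_grid_set")
}

#' @export
print.env_grid_set <- function(x, ...) {
  cat(sprintf("<env_grid_set %d: %d monthly fields x 3 vars + depth, %d land polygons>\n",
              x$year, length(x$sst), length(x$land)))
  invisible(x)
}

#' Daily grid derived from the monthly synthetic fields
#'
#' Daily SIC (or SST) equals the month's field plus a small field-wide AR(1)
#' perturbation, clipped to valid range, so daily grids stay consistent with
#' their monthly mean.
#'
#' @param env an [generate_env_grids()] result.
#' @param var `"sic"` or `"sst"`.
#' @param date a `Date` (or string) within the grid-set year.
#' @return an [env_grid()] with daily time key.
#' @export
daily_env_grid <- function(env, var = c("sic", "sst"), date) {
  var <- match.arg(var)
  date <- as.Date(date)
  doy <- as.integer(date - as.Date(sprintf("%d-01-01", env$year))) + 1L
  if (doy < 1 || doy > length(env$daily_noise[[var]]))
    stop("date outside the grid-set year: ", format(date))
  mon <- format(date, "%Y-%m")
  base <- env[[var]][[mon]]
  d <- base$data + env$daily_noise[[var]][doy]
  if (var == "sic") d <- pmin(pmax(d, 0), 100)
  env_grid(var, base$lon, base$lat, d, time = format(date))
}

# ---- I/O -----------------------------------------------------------------

#' Write an environmental grid set to plain-text files
#'
#' One long-format CSV per variable (`month, lon, lat, value`), the land
#' mask as GeoJSON, and the analytic parameters plus grid spec as JSON.
#'
#' @param env an env grid set.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_env_grids <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(gl) {
    do.call(rbind, lapply(gl, function(g)
      data.frame(time = ifelse(is.na(g$time), "static", g$time),
                 lon = rep(g$lon, times = length(g$lat)),
                 lat = rep(g$lat, each = length(g$lon)),
                 value = as.vector(g$data))))
  }
  for (v in c("sst", "sic", "u_current"))
    utils::write.csv(flat(env[[v]]), file.path(dir, paste0(v, ".csv")),
                     row.names = FALSE)
  utils::write.csv(flat(list(env$depth)), file.path(dir, "depth.csv"),
                   row.names = FALSE)
  write_land_geojson(env$land, file.path(dir, "land_mask.geojson"))
  meta <- list(year = env$year, grid_spec = env$grid_spec,
               params = env$params, daily_noise = env$daily_noise)
  jsonlite::write_json(meta, file.path(dir, "env_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a land-mask polygon set as GeoJSON
#' @param land list of rings, each `list(lon=, lat=)`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_land_geojson <- function(land, path) {
  feats <- lapply(land, function(r) {
    ring <- lapply(c(seq_along(r$lon), 1L),
                   function(i) c(r$lon[i], r$lat[i]))
    list(type = "Feature", properties = list(kind = "land"),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a land-mask polygon set from GeoJSON
#' @param path a GeoJSON FeatureCollection of polygons.
#' @return list of rings, each `list(lon=, lat=)` (closing vertex dropped).
#' @export
read_land_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    co <- f$geometry$coordinates[[1]]
    lon <- vapply(co, function(p) as.numeric(p[[1]]), 0)
    lat <- vapply(co, function(p) as.numeric(p[[2]]), 0)
    n <- length(lon)
    if (n > 1 && lon[1] == lon[n] && lat[1] == lat[n]) {
      lon <- lon[-n]; lat <- lat[-n]
    }
    list(lon = lon, lat = lat)
  })
}

#' Read an environmental grid set written by [write_env_grids()]
#' @param dir directory produced by [write_env_grids()].
#' @return an `"env_grid_set"`.
#' @export
read_env_grids <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "env_meta.json"),
                              simplifyVector = TRUE)
  unflat <- function(var) {
    df <- utils::read.csv(file.path(dir, paste0(var, ".csv")))
    out <- lapply(split(df, df$time), function(s) {
      lon <- sort(unique(s$lon)); lat <- sort(unique(s$lat))
      m <- matrix(NA_real_, length(lon), length(lat))
      m[cbind(match(s$lon, lon), match(s$lat, lat))] <- s$value
      env_grid(var, lon, lat, m, time = s$time[1])
    })
    out[order(names(out))]
  }
  structure(list(sst = unflat("sst"), sic = unflat("sic"),
                 u_current = unflat("u_current"),
                 depth = unflat("depth")[[1]],
                 land = read_land_geojson(file.path(dir, "land_mask.geojson")),
                 params = as.list(meta$params),
                 grid_spec = as.list(meta$grid_spec), year = meta$year,
                 daily_noise = lapply(meta$daily_noise, as.numeric)),
            class = "env_grid_set")
}
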