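# Quality control of raw Argos fixes: reader, quality/ellipse screening,
# constant-speed filter, and minimum-duration retention.

FIX_REQUIRED_COLS <- c("deployment_id", "timestamp", "lon", "lat", "lc_class",
                       "ellipse_semi_major_m", "ellipse_semi_minor_m",
                       "ellipse_orientation_deg")

#' Read an Argos fix table from CSV
#'
#' Expects the column layout written by [write_fixes_csv()]. Rows whose
#' timestamp or coordinates fail to parse are rejected and reported via the
#' `"rejected"` attribute, never silently dropped. Longitudes are wrapped to
#' `(-180, 180]`; output is time-sorted within deployment.
#'
#' @param path CSV file with a header.
#' @return fix data.frame (see [observe_argos()]) with attribute
#'   `"rejected"` holding the unparseable rows.
#' @export
read_argos_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(FIX_REQUIRED_COLS, names(raw))
  if (length(missing_cols))
    stop("fix table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%OSZ")
  # tolerate a plain "YYYY-mm-dd HH:MM:SS" fallback
  alt <- is.na(ts) & nzchar(raw$timestamp)
  if (any(alt))
    ts[alt] <- as.POSIXct(raw$timestamp[alt], tz = "UTC",
                          format = "%Y-%m-%d %H:%M:%OS")
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  bad <- is.na(ts) | is.na(lon) | is.na(lat) | abs(lat) > 90
  fixes <- data.frame(
    deployment_id = raw$deployment_id[!bad],
    timestamp = ts[!bad],
    lon = normalize_lon(lon[!bad]),
    lat = lat[!bad],
    lc_class = raw$lc_class[!bad],
    ellipse_semi_major_m = suppressWarnings(as.numeric(raw$ellipse_semi_major_m[!bad])),
    ellipse_semi_minor_m = suppressWarnings(as.numeric(raw$ellipse_semi_minor_m[!bad])),
    ellipse_orientation_deg = suppressWarnings(as.numeric(raw$ellipse_orientation_deg[!bad])))
  fixes <- fixes[order(fixes$deployment_id, fixes$timestamp), , drop = FALSE]
  rownames(fixes) <- NULL
  attr(fixes, "rejected") <- raw[bad, , drop = FALSE]
  fixes
}

#' Screen fixes by location class and error ellipse
#'
#' Removes every fix with location class Z and every fix whose error
#' ellipse is unspecified (missing or non-positive semi-major axis).
#' Order is preserved.
#'
#' @param fixes fix data.frame.
#' @param ellipse_missing predicate taking the fix table and returning a
#'   logical vector flagging unspecified ellipses.
#' @return the retained fixes, with attribute `"qc_removed"` giving counts
#'   `n_z` and `n_no_ellipse` (non-Z fixes lacking an ellipse).
#' @export
filter_quality <- function(fixes,
                           ellipse_missing = function(f)
                             is.na(f$ellipse_semi_major_m) |
                             f$ellipse_semi_major_m <= 0) {
  is_z <- fixes$lc_class == "Z"
  no_ell <- ellipse_missing(fixes)
  keep <- !is_z & !no_ell
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_removed") <- c(n_z = sum(is_z),
                               n_no_ellipse = sum(no_ell & !is_z))
  out
}

#' Constant-speed filter for Argos fixes
#'
#' Recursive forward filter anchored at a trusted position (the release
#' location): walking forward in time, a fix is dropped when the implied
#' great-circle speed from the last retained position exceeds `vmax`
#' (inclusive threshold: a speed exactly equal to `vmax` is retained).
#' After filtering, every consecutive retained pair satisfies the speed
#' bound. Duplicate timestamps with distinct positions keep the first
#' occurrence; later duplicates are reported as removed.
#'
#' @param fixes time-sorted fixes for a single deployment.
#' @param vmax maximum sustained speed, m/s.
#' @param anchor length-2 numeric `(lon, lat)` of the trusted release
#'   location; if `NULL` the first fix is trusted instead.
#' @param anchor_time POSIXct release time of the anchor; when given, the
#'   first retained fix must itself satisfy the speed bound from the
#'   anchor, otherwise the anchor contributes its position only and the
#'   first fix is accepted as the starting point.
#' @return retained fixes with attribute `"n_speed_removed"`.
#' @export
speed_filter <- function(fixes, vmax = 2.5, anchor = NULL,
                         anchor_time = NULL) {
  n <- nrow(fixes)
  if (n == 0) {
    attr(fixes, "n_speed_removed") <- 0L
    return(fixes)
  }
  if (is.unsorted(fixes$timestamp)) stop("fixes must be time-sorted")
  keep <- logical(n)
  if (is.null(anchor) || is.null(anchor_time)) {
    keep[1] <- TRUE
    lon0 <- fixes$lon[1]; lat0 <- fixes$lat[1]; t0 <- fixes$timestamp[1]
    start <- 2L
  } else {
    lon0 <- anchor[1]; lat0 <- anchor[2]
    t0 <- as.POSIXct(anchor_time, tz = "UTC")
    start <- 1L
  }
  for (i in seq.int(start, length.out = n - start + 1L)) {
    dt <- as.numeric(difftime(fixes$timestamp[i], t0, units = "secs"))
    if (dt <= 0) next  # duplicate/earlier timestamp: keep first occurrence
    d_m <- haversine_km(lon0, lat0, fixes$lon[i], fixes$lat[i]) * 1000
    if (d_m / dt <= vmax) {
      keep[i] <- TRUE
      lon0 <- fixes$lon[i]; lat0 <- fixes$lat[i]; t0 <- fixes$timestamp[i]
    }
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_speed_removed") <- as.integer(n - sum(keep))
  out
}

#' Retain deployments with a minimum tracked duration
#'
#' A deployment is retained iff the span from its first to its last fix
#' (after quality and speed filtering) is at least `min_days` days.
#'
#' @param fixes filtered fix table (possibly several deployments).
#' @param deployments deployment metadata with `deployment_id`, `colony`,
#'   `stage`.
#' @param min_days minimum tracked span, days.
#' @return list with `fixes` (retained deployments' fixes) and `report`, a
#'   per-deployment data.frame (`deployment_id`, `colony`, `stage`,
#'   `n_fixes`, `duration_days`, `retained`).
#' @export
retain_min_duration <- function(fixes, deployments, min_days = 7) {
  ids <- deployments$deployment_id
  span <- vapply(ids, function(id) {
    tt <- fixes$timestamp[fixes$deployment_id == id]
    if (length(tt) < 2) 0
    else as.numeric(difftime(max(tt), min(tt), units = "days"))
  }, 0)
  nfx <- vapply(ids, function(id) sum(fixes$deployment_id == id), 0L)
  report <- data.frame(deployment_id = ids,
                       colony = deployments$colony,
                       stage = deployments$stage,
                       n_fixes = nfx,
                       duration_days = span,
                       retained = span >= min_days)
  rownames(report) <- NULL
  list(fixes = fixes[fixes$deployment_id %in% ids[report$retained], ,
                     drop = FALSE],
       report = report)
}

#' Run the full QC chain on a raw fix table
#'
#' Applies [filter_quality()], then [speed_filter()] per deployment
#' (anchored at the colony release location), then [retain_min_duration()].
#'
#' @param fixes raw fix table.
#' @param deployments deployment metadata (`deployment_id`, `colony`,
#'   `stage`, `lon`, `lat`).
#' @param vmax speed threshold, m/s.
#' @param min_days retention threshold, days.
#' @return list with `fixes`, `report` (per-deployment QC accounting with
#'   per-filter removal counts) and `summary` (counts by stage).
#' @export
qc_pipeline <- function(fixes, deployments, vmax = 2.5, min_days = 7) {
  per_dep <- lapply(seq_len(nrow(deployments)), function(i) {
    d <- deployments[i, ]
    f <- fixes[fixes$deployment_id == d$deployment_id, , drop = FALSE]
    n_raw <- nrow(f)
    f1 <- filter_quality(f)
    rq <- attr(f1, "qc_removed")
    f2 <- speed_filter(f1, vmax = vmax, anchor = c(d$lon, d$lat),
                       anchor_time = if ("release_time" %in% names(d))
                         d$release_time else NULL)
    list(fixes = f2,
         counts = data.frame(deployment_id = d$deployment_id,
                             n_raw = n_raw,
                             n_z = rq[["n_z"]],
                             n_no_ellipse = rq[["n_no_ellipse"]],
                             n_speed = attr(f2, "n_speed_removed")))
  })
  clean <- do.call(rbind, lapply(per_dep, `[[`, "fixes"))
  counts <- do.call(rbind, lapply(per_dep, `[[`, "counts"))
  ret <- retain_min_duration(clean, deployments, min_days = min_days)
  report <- merge(counts, ret$report, by = "deployment_id", sort = FALSE)
  summary <- stats::aggregate(
    cbind(n_deployed = rep(1, nrow(report)), n_retained = report$retained)
    ~ stage, data = report, FUN = sum)
  list(fixes = ret$fixes, report = report, summary = summary)
}
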