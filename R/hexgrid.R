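# Equal-area hexagonal tessellation and habitat-utilization distributions.
#
# Flat-top hexagons in the working plane, anchored at the projection
# origin. With centroid spacing d between adjacent cells the hexagon
# circumradius is d/sqrt(3) and every cell area is (sqrt(3)/2) d^2 --
# 541.266 km^2 at the 25 km spacing used throughout.

#' Build the hexagonal tessellation
#'
#' Deterministic flat-top axial tessellation of the working equal-area
#' plane, anchored at the projection origin. Cell (0, 0) is centered at
#' the origin; axial coordinates `(q, r)` index columns and diagonals.
#'
#' @param spacing centroid spacing between adjacent cells, km.
#' @return an object of class `"hexgrid"` with the spacing, circumradius
#'   and exact cell area.
#' @export
build_hexgrid <- function(spacing = 25) {
  stopifnot(spacing > 0)
  structure(list(spacing = spacing,
                 size = spacing / sqrt(3),          # circumradius
                 cell_area = sqrt(3) / 2 * spacing^2),
            class = "hexgrid")
}

#' @export
print.hexgrid <- function(x, ...) {
  cat(sprintf("<hexgrid: flat-top, %g km spacing, cell area %.3f km^2>\n",
              x$spacing, x$cell_area))
  invisible(x)
}

#' Centroid of hexagon cells
#'
#' @param grid a [build_hexgrid()].
#' @param q,r axial cell indices (vectors).
#' @return two-column matrix of centroid `x`, `y` in km.
#' @export
hex_centroid <- function(grid, q, r) {
  s <- grid$size
  cbind(x = 1.5 * s * q, y = sqrt(3) * s * (r + q / 2))
}

#' Assign points to hexagon cells
#'
#' Nearest-centroid assignment via exact axial (cube) rounding; every point
#' maps to exactly one cell, boundary points deterministically.
#'
#' @param grid a [build_hexgrid()].
#' @param x,y point coordinates in the working plane, km.
#' @return data.frame with integer columns `q`, `r`.
#' @export
hex_cell_of <- function(grid, x, y) {
  s <- grid$size
  qf <- (2 / 3) * x / s
  rf <- (-1 / 3 * x + sqrt(3) / 3 * y) / s
  # cube rounding: round (q, r, s3 = -q-r), fix the largest rounding error
  sf <- -qf - rf
  qi <- round(qf); ri <- round(rf); si <- round(sf)
  dq <- abs(qi - qf); dr <- abs(ri - rf); ds <- abs(si - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  qi[fix_q] <- -ri[fix_q] - si[fix_q]
  ri[fix_r] <- -qi[fix_r] - si[fix_r]
  data.frame(q = as.integer(qi), r = as.integer(ri))
}

#' Polygon of one hexagon cell
#'
#' @param grid a [build_hexgrid()].
#' @param q,r axial indices of the cell (scalars).
#' @return list with vertex vectors `x`, `y` (6 vertices, counter-clockwise).
#' @export
hex_polygon <- function(grid, q = 0, r = 0) {
  cc <- hex_centroid(grid, q, r)
  ang <- seq(0, 5) * pi / 3  # flat-top: vertices at 0, 60, ..., 300 degrees
  list(x = cc[1, "x"] + grid$size * cos(ang),
       y = cc[1, "y"] + grid$size * sin(ang))
}

#' Pool imputed positions into monthly habitat-utilization distributions
#'
#' Every 2-h draw position of every imputed track contributes to exactly
#' one (calendar month, hexagon cell). Individual presence is deduplicated
#' across draws: a cell "contains" an individual in a month if at least one
#' of its imputed positions that month falls in the cell; the visit weight
#' counts the draw positions.
#'
#' @param imputed one `"imputed_tracks"` object or a list of them.
#' @param grid a [build_hexgrid()].
#' @param meta deployment metadata (`deployment_id`, `colony`, `stage`)
#'   used to attribute presence.
#' @return an object of class `"hud"`: data.frame with `month`
#'   (`"YYYY-MM"`), `q`, `r`, `deployment_id`, `colony`, `stage`,
#'   `weight`; attribute `"cell_area"`.
#' @export
assign_cells <- function(imputed, grid, meta) {
  if (inherits(imputed, "imputed_tracks")) imputed <- list(imputed)
  parts <- lapply(imputed, function(tr) {
    nd <- ncol(tr$x); nt <- nrow(tr$x)
    mon <- format(tr$times, "%Y-%m", tz = "UTC")
    cells <- hex_cell_of(grid, as.vector(tr$x), as.vector(tr$y))
    data.frame(deployment_id = tr$deployment_id,
               month = rep(mon, nd), q = cells$q, r = cells$r)
  })
  long <- do.call(rbind, parts)
  agg <- stats::aggregate(list(weight = rep(1L, nrow(long))),
                          long[, c("month", "q", "r", "deployment_id")],
                          FUN = sum)
  mi <- match(agg$deployment_id, meta$deployment_id)
  agg$colony <- meta$colony[mi]
  agg$stage <- meta$stage[mi]
  agg <- agg[order(agg$month, agg$q, agg$r, agg$deployment_id), ,
             drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("hud", "data.frame"), cell_area = grid$cell_area)
}

#' @export
print.hud <- function(x, ...) {
  cat(sprintf("<hud: %d months, %d occupied (month, cell) pairs, %d individuals>\n",
              length(unique(x$month)),
              nrow(unique(x[, c("month", "q", "r")])),
              length(unique(x$deployment_id))))
  invisible(x)
}

overlap_record <- function(month, scope, overlap_cells, total_cells,
                           cell_area, flag = NA_character_) {
  data.frame(month = month, scope = scope,
             overlap_area_km2 = overlap_cells * cell_area,
             total_area_km2 = total_cells * cell_area,
             ratio = if (total_cells > 0) overlap_cells / total_cells
                     else NA_real_,
             flag = flag)
}

#' Inter-colony overlap index for one month
#'
#' Overlap area is the area of cells whose presence set contains
#' individuals from at least two distinct colonies; total area is the area
#' of all occupied cells of the month.
#'
#' @param hud an [assign_cells()] result.
#' @param month month key `"YYYY-MM"`.
#' @return one-row data.frame with `overlap_area_km2`, `total_area_km2`,
#'   `ratio` in `[0, 1]` (NA with an empty-month flag when absent).
#' @export
intercolony_overlap <- function(hud, month) {
  ca <- attr(hud, "cell_area")
  h <- hud[hud$month == month, , drop = FALSE]
  if (!nrow(h))
    return(overlap_record(month, "inter", 0, 0, ca, "month absent"))
  key <- paste(h$q, h$r)
  ncol_by_cell <- tapply(h$colony, key, function(cc) length(unique(cc)))
  overlap_record(month, "inter",
                 sum(ncol_by_cell >= 2), length(ncol_by_cell), ca)
}

#' Intra-colony overlap index for one month
#'
#' Overlap area is the area of cells holding at least two distinct
#' individuals of the colony; total area is the area of the colony's
#' occupied cells.
#'
#' @param hud an [assign_cells()] result.
#' @param colony colony name.
#' @param month month key `"YYYY-MM"`.
#' @return one-row data.frame as in [intercolony_overlap()]; a
#'   single-individual colony-month yields ratio 0 with a flag.
#' @export
intracolony_overlap <- function(hud, colony, month) {
  ca <- attr(hud, "cell_area")
  h <- hud[hud$month == month & hud$colony == colony, , drop = FALSE]
  if (!nrow(h))
    return(overlap_record(month, paste0("intra:", colony), 0, 0, ca,
                          "colony-month absent"))
  flag <- if (length(unique(h$deployment_id)) < 2) "single individual"
          else NA_character_
  key <- paste(h$q, h$r)
  nind <- tapply(h$deployment_id, key, function(ii) length(unique(ii)))
  overlap_record(month, paste0("intra:", colony),
                 sum(nind >= 2), length(nind), ca, flag)
}

#' Monthly overlap table across all months and colonies
#'
#' @param hud an [assign_cells()] result.
#' @return data.frame with one inter-colony row per month plus one
#'   intra-colony row per colony-month, ratios also as percentages.
#' @export
overlap_table <- function(hud) {
  months <- sort(unique(hud$month))
  colonies <- sort(unique(hud$colony))
  rows <- list()
  for (m in months) {
    rows[[length(rows) + 1]] <- intercolony_overlap(hud, m)
    for (cc in colonies)
      if (any(hud$month == m & hud$colony == cc))
        rows[[length(rows) + 1]] <- intracolony_overlap(hud, cc, m)
  }
  out <- do.call(rbind, rows)
  out$percent <- 100 * out$ratio
  rownames(out) <- NULL
  out
}

#' Write a HUD as GeoJSON cell polygons
#'
#' One feature per (month, cell) with individual counts and colony
#' presence; coordinates are the cell polygon in lon/lat.
#'
#' @param hud an [assign_cells()] result.
#' @param grid the [build_hexgrid()] used to build it.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hud_geojson <- function(hud, grid, path) {
  cells <- unique(hud[, c("month", "q", "r")])
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    ce <- cells[i, ]
    sub <- hud[hud$month == ce$month & hud$q == ce$q & hud$r == ce$r, ]
    poly <- hex_polygon(grid, ce$q, ce$r)
    ll <- unproject_laea(poly$x, poly$y)
    ring <- lapply(c(seq_len(nrow(ll)), 1L), function(k) unname(ll[k, ]))
    list(type = "Feature",
         properties = list(month = ce$month, q = ce$q, r = ce$r,
                           n_individuals = length(unique(sub$deployment_id)),
                           colonies = paste(sort(unique(sub$colony)),
                                            collapse = ";")),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
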