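#' Default study-region bounding box
#'
#' The south-eastern Tibetan Plateau analysis window:
#' 27deg45'-37deg45'N, 90deg15'-101deg15'E.
#'
#' @return Named numeric vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @export
default_bbox <- function() {
  c(lat_min = 27.75, lat_max = 37.75, lon_min = 90.25, lon_max = 101.25)
}

# Sutherland-Hodgman clip of a convex polygon (matrix with lon/lat columns)
# against the half-plane a*lon + b*lat <= c
clip_halfplane <- function(poly, a, b, cc) {
  if (is.null(poly) || nrow(poly) == 0L) return(poly)
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2L,
                dimnames = list(NULL, c("lon", "lat")))
  g <- a * poly[, 1L] + b * poly[, 2L] - cc
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p1 <- poly[i, ]; p2 <- poly[j, ]
    in1 <- g[i] <= 0; in2 <- g[j] <= 0
    if (in1) out <- rbind(out, p1)
    if (xor(in1, in2)) {
      t <- g[i] / (g[i] - g[j])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  rownames(out) <- NULL
  out
}

#' Thiessen (Voronoi) polygons of sites clipped to a bounding box
#'
#' Builds each site's Voronoi cell as the intersection of the bounding box
#' with the half-planes bounded by the perpendicular bisectors towards every
#' other site, treating longitude/latitude as planar coordinates
#' (plate-carree), the usual GIS practice at this regional extent. The cells
#' tile the box exactly (shared boundaries only) and every interior point's
#' nearest site in the same planar metric is its cell's site. Collinear site
#' configurations are handled naturally by the bounded construction.
#'
#' @param sites List of [site_location()] (>= 1 inside the box, no duplicate
#'   coordinates).
#' @param bbox Named vector `c(lat_min, lat_max, lon_min, lon_max)`
#'   (default [default_bbox()]).
#' @return An object of class `thiessen_map`: list with `bbox`, `sites`
#'   (data.frame of site_id, lon, lat), `polygons` (named list of vertex
#'   matrices with `lon`, `lat` columns) and an empty `values` table to be
#'   filled by [attach_site_values()].
#' @export
thiessen_polygons <- function(sites, bbox = default_bbox()) {
  if (length(sites) == 0L) stop("no sites supplied")
  lon <- vapply(sites, `[[`, 0, "longitude")
  lat <- vapply(sites, `[[`, 0, "latitude")
  ids <- vapply(sites, `[[`, "", "site_id")
  if (anyDuplicated(cbind(lon, lat))) stop("duplicate site coordinates")
  if (anyDuplicated(ids)) stop("duplicate site_id")
  inside <- lat >= bbox[["lat_min"]] & lat <= bbox[["lat_max"]] &
    lon >= bbox[["lon_min"]] & lon <= bbox[["lon_max"]]
  if (!any(inside)) stop("no site inside bbox")
  box <- matrix(c(bbox[["lon_min"]], bbox[["lat_min"]],
                  bbox[["lon_max"]], bbox[["lat_min"]],
                  bbox[["lon_max"]], bbox[["lat_max"]],
                  bbox[["lon_min"]], bbox[["lat_max"]]),
                ncol = 2L, byrow = TRUE,
                dimnames = list(NULL, c("lon", "lat")))
  polys <- lapply(seq_along(sites), function(i) {
    cell <- box
    for (j in seq_along(sites)) {
      if (j == i || nrow(cell) == 0L) next
      # keep d(p, site_i) <= d(p, site_j)
      a <- 2 * (lon[j] - lon[i]); b <- 2 * (lat[j] - lat[i])
      cc <- lon[j]^2 + lat[j]^2 - lon[i]^2 - lat[i]^2
      cell <- clip_halfplane(cell, a, b, cc)
    }
    cell
  })
  names(polys) <- ids
  empty <- vapply(polys, function(p) is.null(p) || nrow(p) < 3L, TRUE)
  if (any(empty))
    warning("site(s) with empty cell inside bbox: ",
            paste(ids[empty], collapse = ", "))
  structure(list(bbox = bbox,
                 sites = data.frame(site_id = ids, lon = lon, lat = lat),
                 polygons = polys[!empty],
                 values = NULL, event_year = NA_integer_),
            class = "thiessen_map")
}

#' @export
print.thiessen_map <- function(x, ...) {
  cat(sprintf("<thiessen_map> %d cells, bbox %s-%sN %s-%sE%s\n",
              length(x$polygons), x$bbox[["lat_min"]], x$bbox[["lat_max"]],
              x$bbox[["lon_min"]], x$bbox[["lon_max"]],
              if (is.null(x$values)) " (no values attached)" else
                sprintf(", event %s", x$event_year)))
  invisible(x)
}

#' Attach per-site metric values to a Thiessen map
#'
#' @param map A [thiessen_polygons()] object.
#' @param summaries [summarize_sites()] rows.
#' @param event_year Event to attach.
#' @return The map with its `values` table filled for that event.
#' @export
attach_site_values <- function(map, summaries, event_year) {
  s <- summaries[summaries$event_year == event_year, , drop = FALSE]
  m <- match(names(map$polygons), s$site_id)
  map$values <- data.frame(site_id = names(map$polygons),
                           P_high_Rt = s$P_high_Rt[m],
                           P_high_Rc = s$P_high_Rc[m])
  map$event_year <- as.integer(event_year)
  map
}

#' Polygon areas of a Thiessen map
#'
#' Shoelace areas on a local equal-area approximation: degrees are scaled to
#' kilometres with the meridian degree length and the parallel degree length
#' at the mid-latitude of the box. The same linear scaling applies to every
#' cell, so cell areas sum exactly to the box area.
#'
#' @param map A `thiessen_map`.
#' @return Named numeric vector of cell areas in km^2.
#' @export
polygon_areas <- function(map) {
  km_lat <- 111.195
  km_lon <- km_lat * cos(mean(map$bbox[c("lat_min", "lat_max")]) * pi / 180)
  vapply(map$polygons, function(p) {
    x <- p[, "lon"] * km_lon
    y <- p[, "lat"] * km_lat
    abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  }, 0)
}

#' Area fractions above/below a metric cut
#'
#' Fraction of the bounding-box area whose Thiessen cell carries a metric
#' value strictly above (`high`) or at/below (`low`) the cut.
#'
#' @param map A `thiessen_map` with values attached.
#' @param metric `"P_high_Rt"` or `"P_high_Rc"`.
#' @param cut Threshold on the proportion (default 0.5).
#' @return Named numeric vector `c(high = ..., low = ...)`, summing to 1
#'   over cells with non-missing values.
#' @export
classify_area <- function(map, metric = c("P_high_Rt", "P_high_Rc"),
                          cut = 0.5) {
  metric <- match.arg(metric)
  if (is.null(map$values)) stop("map has no metric values attached")
  v <- map$values[[metric]][match(names(map$polygons), map$values$site_id)]
  if (all(is.na(v))) stop("metric '", metric, "' is unpopulated")
  a <- polygon_areas(map)
  tot <- sum(a[!is.na(v)])
  c(high = sum(a[!is.na(v) & v > cut]) / tot,
    low = sum(a[!is.na(v) & v <= cut]) / tot)
}

#' Export a Thiessen map as GeoJSON
#'
#' Writes a standard `FeatureCollection` of polygon features; properties
#' carry `site_id`, `event_year` and the metric values (written as `null`,
#' with a warning, when no values are attached).
#'
#' @param map A `thiessen_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_geojson <- function(map, path) {
  if (is.null(map$values))
    warning("map has no metric values: writing null properties")
  feats <- lapply(names(map$polygons), function(id) {
    p <- map$polygons[[id]]
    ring <- lapply(seq_len(nrow(p)), function(i) unname(p[i, ]))
    ring[[length(ring) + 1L]] <- ring[[1L]]  # close the ring
    val <- function(metric) {
      if (is.null(map$values)) return(NULL)
      v <- map$values[[metric]][map$values$site_id == id]
      if (length(v) == 0L || is.na(v)) NULL else v
    }
    list(type = "Feature",
         properties = list(site_id = id,
                           event_year = if (is.na(map$event_year)) NULL else
                             map$event_year,
                           P_high_Rt = val("P_high_Rt"),
                           P_high_Rc = val("P_high_Rc")),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
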