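#' Ring-width series
#'
#' Container for one tree's dated annual ring widths. Widths are stored in
#' millimetres; a width of exactly 0 encodes a locally absent (missing) ring,
#' following the Tucson convention.
#'
#' @param tree_id Series identifier (one physical tree or core).
#' @param site_id Site code the tree belongs to.
#' @param first_year Calendar year of the first ring (integer).
#' @param widths Numeric vector of annual widths in mm, one per consecutive
#'   year. Must be non-negative with at least one positive value.
#' @return An object of class `rw_series`.
#' @examples
#' rw_series("T01", "SIT", 1950, c(0.5, 0.62, 0, 0.48))
#' @export
rw_series <- function(tree_id, site_id, first_year, widths) {
  widths <- as.numeric(widths)
  first_year <- as.integer(first_year)
  if (length(widths) < 1L) stop("widths must have length >= 1")
  if (anyNA(widths) || any(!is.finite(widths))) stop("widths must be finite")
  if (any(widths < 0)) stop("widths must be non-negative (0 = missing ring)")
  if (all(widths == 0)) stop("series must contain at least one positive width")
  structure(
    list(tree_id = as.character(tree_id), site_id = as.character(site_id),
         first_year = first_year, widths = widths),
    class = "rw_series")
}

#' @export
print.rw_series <- function(x, ...) {
  cat(sprintf("<rw_series> %s (site %s), %d-%d, %d rings, %d missing\n",
              x$tree_id, x$site_id, x$first_year, last_year(x),
              length(x$widths), sum(x$widths == 0)))
  invisible(x)
}

#' Calendar years covered by a series
#'
#' @param x An `rw_series`, `rwi_series` or `site_chronology` object.
#' @return Integer vector of consecutive calendar years.
#' @export
series_years <- function(x) x$first_year + seq_along(series_values(x)) - 1L

last_year <- function(x) x$first_year + length(series_values(x)) - 1L

series_values <- function(x) {
  if (!is.null(x$widths)) x$widths
  else if (!is.null(x$indices)) x$indices
  else x$values
}

#' Ring-width index series
#'
#' Dimensionless ring-width indices for one tree: measured width divided by
#' the fitted growth trend. The index is exactly 0 where the width is 0
#' (missing ring) and the mean index over a series without missing rings is
#' close to 1.
#'
#' @param tree_id,site_id,first_year As in [rw_series()].
#' @param indices Annual dimensionless indices (>= 0).
#' @param trend Fitted trend values in mm (same length, > 0).
#' @return An object of class `rwi_series`.
#' @export
rwi_series <- function(tree_id, site_id, first_year, indices, trend) {
  indices <- as.numeric(indices)
  trend <- as.numeric(trend)
  if (length(indices) != length(trend)) stop("indices and trend lengths differ")
  if (any(indices < 0)) stop("indices must be non-negative")
  structure(
    list(tree_id = as.character(tree_id), site_id = as.character(site_id),
         first_year = as.integer(first_year), indices = indices, trend = trend),
    class = "rwi_series")
}

#' @export
print.rwi_series <- function(x, ...) {
  cat(sprintf("<rwi_series> %s (site %s), %d-%d, mean index %.3f\n",
              x$tree_id, x$site_id, x$first_year, last_year(x),
              mean(x$indices[x$indices > 0])))
  invisible(x)
}

#' Extract index values for a span of calendar years
#'
#' @param x An `rwi_series`.
#' @param years Integer vector of calendar years.
#' @return Numeric vector, `NA` for years outside the series span.
#' @export
index_at <- function(x, years) {
  pos <- years - x$first_year + 1L
  out <- rep(NA_real_, length(years))
  ok <- pos >= 1L & pos <= length(x$indices)
  out[ok] <- x$indices[pos[ok]]
  out
}

#' Site location record
#'
#' @param site_id Site (or grid point) code.
#' @param latitude Decimal degrees north.
#' @param longitude Decimal degrees east.
#' @param elevation Elevation in m a.s.l. (optional).
#' @return An object of class `site_location`.
#' @export
site_location <- function(site_id, latitude, longitude, elevation = NA_real_) {
  if (!is.finite(latitude) || !is.finite(longitude))
    stop("latitude/longitude must be finite")
  structure(
    list(site_id = as.character(site_id), latitude = as.numeric(latitude),
         longitude = as.numeric(longitude), elevation = as.numeric(elevation)),
    class = "site_location")
}

#' Monthly climate series for one location and variable
#'
#' Values are held as a year-by-12 matrix; missing entries are `NA`, never a
#' silent zero.
#'
#' @param location_id Location (grid point) code.
#' @param variable One of `"scPDSI"`, `"DTR"`, `"T_mean"`, `"T_max"`,
#'   `"T_min"`, `"precipitation"`.
#' @param first_year First calendar year covered.
#' @param monthly_values Numeric matrix, one row per year, 12 columns.
#' @param units Unit string (e.g. `"degC"`, `"mm"`, `"index"`).
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(location_id, variable, first_year, monthly_values,
                           units = "") {
  variable <- match.arg(variable, climate_variables())
  monthly_values <- as.matrix(monthly_values)
  if (ncol(monthly_values) != 12L) stop("monthly_values needs 12 columns")
  structure(
    list(location_id = as.character(location_id), variable = variable,
         first_year = as.integer(first_year),
         monthly_values = unname(monthly_values), units = as.character(units)),
    class = "climate_series")
}

climate_variables <- function() {
  c("scPDSI", "DTR", "T_mean", "T_max", "T_min", "precipitation")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> %s %s, %d-%d (%d missing cells)\n",
              x$location_id, x$variable, x$first_year,
              x$first_year + nrow(x$monthly_values) - 1L,
              sum(is.na(x$monthly_values))))
  invisible(x)
}

climate_years <- function(x) x$first_year + seq_len(nrow(x$monthly_values)) - 1L
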