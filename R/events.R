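#' Seasonal mean of a monthly climate series
#'
#' Per calendar year, the arithmetic mean of the requested months. A year is
#' flagged missing (`NA`) if any constituent month is missing.
#'
#' @param climate A [climate_series()].
#' @param months Non-empty integer vector of months in 1-12.
#' @return A `seasonal_series` object: list with `location_id`, `variable`,
#'   `months`, `first_year` and annual `values` (`NA` where incomplete).
#' @export
seasonal_mean <- function(climate, months) {
  months <- as.integer(months)
  if (length(months) == 0L) stop("empty month set")
  if (any(months < 1L | months > 12L)) stop("months must be in 1-12")
  vals <- rowMeans(climate$monthly_values[, months, drop = FALSE])
  structure(list(location_id = climate$location_id,
                 variable = climate$variable, months = sort(unique(months)),
                 first_year = climate$first_year, values = vals),
            class = "seasonal_series")
}

#' @export
print.seasonal_series <- function(x, ...) {
  cat(sprintf("<seasonal_series> %s %s months %s, %d-%d\n", x$location_id,
              x$variable, paste(x$months, collapse = ","), x$first_year,
              last_year(x)))
  invisible(x)
}

#' Regional (multi-location) mean of seasonal series
#'
#' Unweighted mean across locations per year, restricted to locations whose
#' coordinates fall inside a lat/lon bounding box.
#'
#' @param series List of `seasonal_series` (one per location), all of the
#'   same variable and month set.
#' @param locations List of [site_location()] matching `series` by
#'   `location_id`.
#' @param bbox Named numeric vector `c(lat_min, lat_max, lon_min, lon_max)`;
#'   `NULL` keeps every location.
#' @return A `seasonal_series` with `location_id = "regional"`.
#' @export
regional_mean <- function(series, locations = NULL, bbox = NULL) {
  if (length(series) == 0L) stop("no seasonal series supplied")
  if (!is.null(bbox)) {
    if (is.null(locations))
      stop("locations must be supplied when bbox is used")
    locs <- locations[match(vapply(series, `[[`, "", "location_id"),
                            vapply(locations, `[[`, "", "site_id"))]
    keep <- vapply(locs, function(l) {
      !is.null(l) && l$latitude >= bbox[["lat_min"]] &&
        l$latitude <= bbox[["lat_max"]] && l$longitude >= bbox[["lon_min"]] &&
        l$longitude <= bbox[["lon_max"]]
    }, TRUE)
    series <- series[keep]
    if (length(series) == 0L) stop("no locations inside bbox")
  }
  y0 <- min(vapply(series, `[[`, 0L, "first_year"))
  y1 <- max(vapply(series, last_year, 0L))
  yrs <- y0:y1
  mat <- vapply(series, function(s) {
    pos <- yrs - s$first_year + 1L
    out <- rep(NA_real_, length(yrs))
    ok <- pos >= 1L & pos <= length(s$values)
    out[ok] <- s$values[pos[ok]]
    out
  }, numeric(length(yrs)))
  mat <- matrix(mat, nrow = length(yrs))
  structure(list(location_id = "regional", variable = series[[1L]]$variable,
                 months = series[[1L]]$months, first_year = y0,
                 values = rowMeans(mat)),
            class = "seasonal_series")
}

#' Detect extreme drought years from first differences
#'
#' Computes first-order differences `d_t = x_t - x_{t-1}` of an annual
#' seasonal series (typically May-June scPDSI) and flags every year whose
#' difference falls more than `k` sample standard deviations below the mean
#' of all differences (`d_t < mu - k * sigma`, sd with denominator n-1). The
#' event is stamped with the later year of the differenced pair — the year
#' the drop occurs. Consecutive qualifying years are reported as separate
#' events.
#'
#' @param series A `seasonal_series` with at least 10 consecutive non-missing
#'   years and no internal gaps.
#' @param k Threshold in standard-deviation units (default 1.5). Lowering
#'   `k` can only add events, never remove one.
#' @return A data.frame with columns `year`, `delta` (the triggering first
#'   difference) and `threshold` (the cutoff used), in chronological order;
#'   zero rows if nothing qualifies. A constant series yields zero rows with
#'   a warning.
#' @export
detect_extreme_droughts <- function(series, k = 1.5) {
  x <- series$values
  if (anyNA(x)) {
    if (any(diff(which(!is.na(x))) > 1L)) stop("gaps in seasonal series")
    x <- x[!is.na(x)]
    first_year <- series$first_year + which(!is.na(series$values))[1L] - 1L
  } else first_year <- series$first_year
  if (length(x) < 10L) stop("need >= 10 years of consecutive values")
  d <- diff(x)
  mu <- mean(d)
  sigma <- stats::sd(d)
  empty <- data.frame(year = integer(), delta = numeric(),
                      threshold = numeric())
  if (sigma == 0) {
    warning("constant series: no variability, no events")
    return(empty)
  }
  thr <- mu - k * sigma
  hit <- which(d < thr)
  if (length(hit) == 0L) return(empty)
  data.frame(year = first_year + hit, delta = d[hit], threshold = thr)
}
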