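#' Read a Tucson (RWL) decadal ring-width file
#'
#' Parses the standard Tucson decadal layout: each line carries a series ID,
#' the calendar year of its first value, and up to ten annual width fields in
#' 0.001 mm units; a series ends with a terminal sentinel (`999` or `-9999`).
#' The first line of a series may start mid-decade. Width fields of `0`
#' encode locally absent (missing) rings and are kept as width 0.
#'
#' @param path Path to an RWL file.
#' @param site_id Site code to attach to all series; defaults to the file
#'   name without extension.
#' @return A list of [rw_series()] objects (empty, with a warning, for an
#'   empty file).
#' @seealso [write_rwl()]
#' @export
read_rwl <- function(path, site_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(site_id))
    site_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty RWL file: ", path)
    return(list())
  }
  parsed <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    # fixed-column files run an 8-character ID straight into the year field
    if (nchar(tok[[1L]]) > 8L && grepl("[0-9]{4}$", tok[[1L]])) {
      nc <- nchar(tok[[1L]])
      tok <- c(substr(tok[[1L]], 1L, nc - 4L),
               substr(tok[[1L]], nc - 3L, nc), tok[-1L])
    }
    if (length(tok) < 3L)
      stop("malformed decade line ", i, " in ", path, ": too few fields")
    year <- suppressWarnings(as.integer(tok[[2L]]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(year) || anyNA(vals))
      stop("malformed decade line ", i, " in ", path, ": non-numeric field")
    if (length(vals) > 11L)   # 10 widths + possibly a sentinel
      stop("malformed decade line ", i, " in ", path, ": too many values")
    list(id = tok[[1L]], year = year, vals = vals, line = i)
  })
  ids <- vapply(parsed, `[[`, "", "id")
  # series are contiguous line blocks; a block whose ID already closed is a
  # duplicate series
  block <- cumsum(c(TRUE, ids[-1L] != ids[-length(ids)]))
  block_ids <- ids[!duplicated(block)]
  if (anyDuplicated(block_ids)) {
    dup <- block_ids[duplicated(block_ids)][1L]
    at <- parsed[[which(block == which(block_ids == dup)[2L])[1L]]]$line
    stop("duplicate series ID '", dup, "' at line ", at, " in ", path)
  }
  acc <- list()
  for (b in seq_along(block_ids)) {
    chunk <- parsed[block == b]
    id <- block_ids[b]
    vals <- numeric(); first_year <- chunk[[1L]]$year; prev <- -Inf
    for (li in seq_along(chunk)) {
      ln <- chunk[[li]]
      v <- ln$vals
      # a sentinel is only meaningful on the last line of the series block:
      # -9999 anywhere there, or a terminal 999 (the 0.01-mm-dialect stop)
      if (li == length(chunk)) {
        is_last_val <- length(v) > 0 &&
          (v[length(v)] == -9999 || v[length(v)] == 999)
        if (any(v == -9999) && (!is_last_val || sum(v == -9999) > 1L))
          stop("malformed decade line ", ln$line, " in ", path,
               ": sentinel not terminal")
        if (is_last_val) v <- v[-length(v)] else
          warning("series without terminal sentinel in ", path, ": ", id)
      } else if (any(v == -9999)) {
        stop("malformed decade line ", ln$line, " in ", path,
             ": sentinel not terminal")
      }
      if (length(v) > 10L)
        stop("malformed decade line ", ln$line, " in ", path,
             ": more than 10 values")
      if (any(v < 0))
        stop("malformed decade line ", ln$line, " in ", path,
             ": negative width")
      if (li > 1L) {
        if (ln$year <= prev)
          stop("non-monotone decades in series '", id, "' at line ", ln$line)
        expected <- first_year + length(vals)
        if (ln$year != expected)
          stop("series '", id, "' line ", ln$line, " starts at ", ln$year,
               " but previous coverage ends at ", expected - 1L)
      }
      vals <- c(vals, v)
      prev <- ln$year
    }
    acc[[id]] <- list(first_year = first_year, values = vals)
  }
  out <- lapply(names(acc), function(id) {
    rw_series(id, site_id, acc[[id]]$first_year, acc[[id]]$values / 1000)
  })
  names(out) <- names(acc)
  out
}

#' Write ring-width series to a Tucson (RWL) decadal file
#'
#' Widths are rounded to integer 0.001 mm units; missing rings (width 0) are
#' written as `0` fields and each series is closed with a `-9999` sentinel.
#' A series starting mid-decade gets a short first line covering only the
#' years up to the next decade boundary.
#'
#' @param series A list of [rw_series()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rwl <- function(series, path) {
  ids <- vapply(series, `[[`, "", "tree_id")
  if (anyDuplicated(ids)) stop("duplicate tree_id in collection")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    units <- round(s$widths * 1000)
    if (any(units > 9998))
      stop("width overflow in series '", s$tree_id,
           "': widths above 9.998 mm cannot be encoded")
    yrs <- series_years(s)
    fields <- c(sprintf("%6.0f", units), sprintf("%6d", -9999L))
    fyrs <- c(yrs, yrs[length(yrs)] + 1L)  # sentinel sits in the next slot
    while (length(fields)) {
      y0 <- fyrs[1L]
      n_take <- min(10L - y0 %% 10L, length(fields))
      line <- paste0(sprintf("%-8s", s$tree_id), sprintf("%4d", y0),
                     paste(fields[seq_len(n_take)], collapse = ""))
      writeLines(line, con)
      fields <- fields[-seq_len(n_take)]
      fyrs <- fyrs[-seq_len(n_take)]
    }
  }
  invisible(path)
}

#' Read a long-format monthly climate CSV
#'
#' Expects columns `location_id`, `variable`, `year`, `month`, `value`.
#' One [climate_series()] is built per (location, variable) pair, spanning
#' the years present for that pair; cells absent from the file or equal to
#' `missing_code` become `NA`.
#'
#' @param path CSV path.
#' @param missing_code Numeric value encoding missing data (default `-9999`);
#'   empty/NA cells are always treated as missing.
#' @return A list of [climate_series()] objects named `location.variable`.
#' @seealso [write_climate_csv()]
#' @export
read_climate_csv <- function(path, missing_code = -9999) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location_id", "variable", "year", "month", "value")
  if (!all(need %in% names(d)))
    stop("climate CSV must have columns: ", paste(need, collapse = ", "))
  if (any(d$month < 1 | d$month > 12))
    stop("month outside 1-12 in ", path)
  key <- paste(d$location_id, d$variable, d$year, d$month)
  if (anyDuplicated(key))
    stop("duplicate (location, variable, year, month) entries in ", path)
  d$value[!is.na(d$value) & d$value == missing_code] <- NA_real_
  out <- list()
  for (grp in split(d, paste(d$location_id, d$variable, sep = "."))) {
    y0 <- min(grp$year); y1 <- max(grp$year)
    m <- matrix(NA_real_, nrow = y1 - y0 + 1L, ncol = 12L)
    m[cbind(grp$year - y0 + 1L, grp$month)] <- grp$value
    cs <- climate_series(grp$location_id[1L], grp$variable[1L], y0, m)
    out[[paste(cs$location_id, cs$variable, sep = ".")]] <- cs
  }
  out
}

#' Write climate series to a long-format CSV
#'
#' Companion writer for [read_climate_csv()]; missing cells are written as
#' `missing_code`.
#'
#' @param climate A list of [climate_series()] objects.
#' @param path Output CSV path.
#' @param missing_code Numeric missing-value code (default `-9999`).
#' @return Invisibly, `path`.
#' @export
write_climate_csv <- function(climate, path, missing_code = -9999) {
  rows <- lapply(climate, function(cs) {
    yrs <- climate_years(cs)
    data.frame(location_id = cs$location_id, variable = cs$variable,
               year = rep(yrs, times = 12L),
               month = rep(1:12, each = length(yrs)),
               value = as.vector(cs$monthly_values))
  })
  d <- do.call(rbind, rows)
  d <- d[order(d$location_id, d$variable, d$year, d$month), ]
  d$value[is.na(d$value)] <- missing_code
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site table CSV
#'
#' Expects columns `site_id`, `lat`, `lon` and optionally `elev_m`.
#'
#' @param path CSV path.
#' @return A list of [site_location()] objects named by site code.
#' @export
read_site_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "lat", "lon") %in% names(d)))
    stop("site table must have columns site_id, lat, lon")
  if (anyDuplicated(d$site_id)) stop("duplicate site_id in ", path)
  out <- lapply(seq_len(nrow(d)), function(i) {
    site_location(d$site_id[i], d$lat[i], d$lon[i],
                  if ("elev_m" %in% names(d)) d$elev_m[i] else NA_real_)
  })
  names(out) <- d$site_id
  out
}

#' Write a site table CSV
#'
#' @param sites A list of [site_location()] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(sites, path) {
  d <- data.frame(site_id = vapply(sites, `[[`, "", "site_id"),
                  lat = vapply(sites, `[[`, 0, "latitude"),
                  lon = vapply(sites, `[[`, 0, "longitude"),
                  elev_m = vapply(sites, `[[`, 0, "elevation"))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Nearest climate grid point to a site
#'
#' Returns the grid location minimizing great-circle (haversine) distance to
#' the site. Exact ties are broken by the lexicographically smaller
#' location ID so runs are reproducible.
#'
#' @param site A [site_location()].
#' @param grid_locations Non-empty list of [site_location()] grid points.
#' @return The `location_id` (site_id field) of the nearest grid point.
#' @export
nearest_gridpoint <- function(site, grid_locations) {
  if (length(grid_locations) == 0L) stop("empty grid")
  ids <- vapply(grid_locations, `[[`, "", "site_id")
  pts <- cbind(vapply(grid_locations, `[[`, 0, "longitude"),
               vapply(grid_locations, `[[`, 0, "latitude"))
  d <- geosphere::distHaversine(c(site$longitude, site$latitude), pts)
  # geometric ties differ by floating-point rounding only
  best <- which(d <= min(d) + 1e-6 * (1 + min(d)))
  ids[best][order(ids[best])][1L]
}
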