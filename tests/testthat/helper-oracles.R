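# Independent brute-force oracles, deliberately written with naive loops and
# no shared code with the package implementation.

# haversine distance in metres, written from the formula
oracle_haversine <- function(lat1, lon1, lat2, lon2, r = 6378137) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# GLK by explicit interval-by-interval scan
oracle_glk <- function(a, b) {
  s <- 0
  n <- length(a)
  for (i in 2:n) {
    da <- a[i] - a[i - 1]
    db <- b[i] - b[i - 1]
    s <- s + if (da == 0 || db == 0) 0.5 else if (sign(da) == sign(db)) 1 else 0
  }
  s / (n - 1)
}

# Kruskal-Wallis H with tie correction, straight from the rank formula
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Tukey biweight location by an independently-coded fixed-point iteration
# (different update structure: recompute until two successive medians of the
# weighted residuals agree)
oracle_biweight <- function(x, c_tune = 9) {
  t0 <- median(x)
  s <- median(abs(x - median(x))) * 1.4826
  if (s == 0) return(median(x))
  for (it in 1:200) {
    u <- (x - t0) / (c_tune * s)
    w <- rep(0, length(x))
    inside <- abs(u) < 1
    w[inside] <- ((1 - u[inside]^2))^2
    t1 <- sum(w * x) / sum(w)
    if (is.nan(t1) || abs(t1 - t0) < 1e-10) break
    t0 <- t1
  }
  t0
}

# least-squares sinusoid amplitude of a fitted curve at a given wavelength
measure_amplitude <- function(trend, wavelength) {
  t <- seq_along(trend)
  X <- cbind(1, sin(2 * pi * t / wavelength), cos(2 * pi * t / wavelength))
  b <- qr.solve(X, trend)
  sqrt(b[2]^2 + b[3]^2)
}

# quick constructors for synthetic series
make_rw <- function(widths, first_year = 1950, id = "T1", site = "S1") {
  rw_series(id, site, first_year, widths)
}

make_rwi <- function(indices, first_year = 1950, id = "T1", site = "S1") {
  rwi_series(id, site, first_year, indices, rep(1, length(indices)))
}

make_seasonal <- function(values, first_year = 1957, loc = "L1") {
  structure(list(location_id = loc, variable = "scPDSI", months = c(5L, 6L),
                 first_year = as.integer(first_year), values = values),
            class = "seasonal_series")
}

# monthly climate matrix whose May/June rows average to the given annual
# values (other months zero)
make_pdsi_climate <- function(annual, first_year = 1957, loc = "L1") {
  m <- matrix(0, length(annual), 12)
  m[, 5] <- annual
  m[, 6] <- annual
  climate_series(loc, "scPDSI", first_year, m, "index")
}

# point-in-convex-polygon with tolerance (cross-product signs)
oracle_in_convex <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  sgn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    if (abs(cr) < eps) next
    if (sgn == 0) sgn <- sign(cr)
    else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}
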