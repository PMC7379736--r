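#' Fit a frequency-cutoff cubic smoothing spline growth trend
#'
#' Fits the cubic smoothing spline conventionally used for tree-ring
#' detrending: the penalty is chosen in closed form so the spline's amplitude
#' response to a sinusoid of wavelength `cutoff_fraction * length(series)`
#' is `fresp` (50% by default). For the discrete natural spline on unit
#' spacing the filter symbol gives
#' `lambda = (1/fresp - 1) * (2 + cos w) / (12 * (1 - cos w)^2)` with
#' `w = 2*pi/wavelength`. The series is extended at both ends by point
#' reflection (odd extension) over one cutoff wavelength before smoothing,
#' which keeps the stated frequency response valid up to the series ends and
#' preserves exact reproduction of constants and straight lines.
#'
#' Missing-ring years (width 0) are excluded from the least-squares objective
#' (weight 0) but receive interpolated trend values. Trend values are floored
#' at 0.001 mm so downstream indices stay finite and non-negative.
#'
#' @param series An [rw_series()] of length >= 10.
#' @param cutoff_fraction Wavelength of the 50% frequency-response cutoff as
#'   a fraction of the series length, in (0, 1]; default 0.5 (half the series
#'   length).
#' @param fresp Amplitude response at the cutoff wavelength (default 0.5).
#' @return Numeric vector of fitted trend values in mm, same length as the
#'   series, strictly positive.
#' @export
fit_spline_trend <- function(series, cutoff_fraction = 0.5, fresp = 0.5) {
  stopifnot(inherits(series, "rw_series"))
  y <- series$widths
  n <- length(y)
  if (n < 10L) stop("series too short to detrend (< 10 years)")
  if (cutoff_fraction <= 0 || cutoff_fraction > 1)
    stop("cutoff_fraction must be in (0, 1]")
  wavelength <- cutoff_fraction * n
  w <- as.numeric(y > 0)
  if (sum(w) < 4L) stop("too few measured (non-missing) rings to detrend")
  # fill missing-ring years by linear interpolation so the reflected padding
  # is built from plausible values; the fill itself carries weight 0
  yf <- y
  if (any(w == 0))
    yf[w == 0] <- stats::approx(which(w > 0), y[w > 0], xout = which(w == 0),
                                rule = 2)$y
  m <- min(n - 1L, as.integer(ceiling(wavelength)))
  yp <- c(2 * yf[1L] - yf[(m + 1L):2L], yf, 2 * yf[n] - yf[(n - 1L):(n - m)])
  wp <- c(w[(m + 1L):2L], w, w[(n - 1L):(n - m)])
  g <- solve_smoothing_spline(yp, wp, wavelength, fresp)
  pmax(g[(m + 1L):(m + n)], 0.001)
}

# natural cubic smoothing spline on unit spacing (Reinsch form):
# minimize sum w_i (y_i - g_i)^2 + lambda * int g''^2,  g = (W + lambda K)^-1 W y
solve_smoothing_spline <- function(y, w, wavelength, fresp) {
  n <- length(y)
  om <- 2 * pi / wavelength
  lam <- (1 / fresp - 1) * (2 + cos(om)) / (12 * (1 - cos(om))^2)
  Q <- matrix(0, n, n - 2L)
  idx <- seq_len(n - 2L)
  Q[cbind(idx, idx)] <- 1
  Q[cbind(idx + 1L, idx)] <- -2
  Q[cbind(idx + 2L, idx)] <- 1
  R <- diag(2 / 3, n - 2L)
  if (n > 3L) {
    off <- cbind(idx[-length(idx)], idx[-1L])
    R[off] <- 1 / 6
    R[off[, 2:1, drop = FALSE]] <- 1 / 6
  }
  K <- Q %*% solve(R, t(Q))
  as.numeric(solve(diag(w, n) + lam * K, w * y))
}

#' Detrend a ring-width series into ring-width indices
#'
#' Divides each annual width by the fitted smoothing-spline trend
#' ([fit_spline_trend()]). Missing-ring years (width 0) get index 0 by rule,
#' never as a division artifact. Indices are scale-free: multiplying all
#' widths by a positive constant leaves them unchanged.
#'
#' @inheritParams fit_spline_trend
#' @return An [rwi_series()].
#' @export
detrend <- function(series, cutoff_fraction = 0.5) {
  trend <- fit_spline_trend(series, cutoff_fraction)
  idx <- ifelse(series$widths > 0, series$widths / trend, 0)
  rwi_series(series$tree_id, series$site_id, series$first_year, idx, trend)
}

#' Tukey biweight robust mean
#'
#' Iterated biweight location estimate: starting from the median, residuals
#' are scaled by `c * MAD` (tuning constant `c = 9`) and observations receive
#' weights `(1 - u^2)^2` inside the window, 0 outside; the weighted mean is
#' re-centred until it moves less than `tol` or `max_iter` is reached. With
#' one or two values the arithmetic mean is returned; when the MAD is 0 the
#' biweight window degenerates and the median is returned.
#'
#' @param values Numeric vector with at least one finite value.
#' @param c_tuning Biweight tuning constant (default 9).
#' @param tol Convergence tolerance on the location (default 1e-8).
#' @param max_iter Iteration cap (default 50).
#' @return The robust location estimate (a single number).
#' @export
biweight_mean <- function(values, c_tuning = 9, tol = 1e-8, max_iter = 50L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("biweight_mean: no finite values")
  if (length(values) <= 2L) return(mean(values))
  s <- stats::mad(values)
  # MAD 0 means > half the sample sits at the median: the biweight window
  # degenerates and its limit is the median itself
  if (s == 0) return(stats::median(values))
  t0 <- stats::median(values)
  for (i in seq_len(max_iter)) {
    u <- (values - t0) / (c_tuning * s)
    wt <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(wt) == 0) return(t0)
    t1 <- sum(wt * values) / sum(wt)
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Build a site chronology by biweight robust mean
#'
#' For each calendar year covered by at least one tree, the chronology value
#' is the [biweight_mean()] of all trees' ring-width indices in that year
#' (missing rings contribute their index of 0); `sample_depth` records how
#' many trees cover each year.
#'
#' @param indices A non-empty list of [rwi_series()] from a single site.
#' @return A `site_chronology` object: list with `site_id`, `first_year`,
#'   `values` and `sample_depth`.
#' @export
build_chronology <- function(indices) {
  if (length(indices) == 0L) stop("no index series supplied")
  sites <- unique(vapply(indices, `[[`, "", "site_id"))
  if (length(sites) > 1L)
    stop("mixed site_ids in chronology input: ", paste(sites, collapse = ", "))
  y0 <- min(vapply(indices, `[[`, 0L, "first_year"))
  y1 <- max(vapply(indices, last_year, 0L))
  yrs <- y0:y1
  mat <- vapply(indices, index_at, numeric(length(yrs)), years = yrs)
  mat <- matrix(mat, nrow = length(yrs))
  depth <- rowSums(!is.na(mat))
  vals <- rep(NA_real_, length(yrs))
  for (i in which(depth > 0))
    vals[i] <- biweight_mean(mat[i, !is.na(mat[i, ])])
  structure(list(site_id = sites, first_year = y0, values = vals,
                 sample_depth = as.integer(depth)),
            class = "site_chronology")
}

#' @export
print.site_chronology <- function(x, ...) {
  cat(sprintf("<site_chronology> %s, %d-%d, max depth %d\n", x$site_id,
              x$first_year, last_year(x), max(x$sample_depth)))
  invisible(x)
}

#' Correlate a site chronology with seasonal climate
#'
#' Pearson correlation between chronology values and the mean of the stated
#' months' climate values per year, restricted to `interval`. Used to verify
#' the moisture sensitivity of a site (e.g. May-June scPDSI).
#'
#' @param chronology A `site_chronology`.
#' @param climate A [climate_series()].
#' @param months Integer months (1-12) to average, e.g. `c(5, 6)`.
#' @param interval Length-2 integer vector of first and last calendar year.
#' @return Pearson correlation coefficient.
#' @export
correlate_chronology_climate <- function(chronology, climate,
                                         months = c(5L, 6L),
                                         interval = c(1957L, 2000L)) {
  seas <- seasonal_mean(climate, months)
  yrs <- interval[1L]:interval[2L]
  cpos <- yrs - chronology$first_year + 1L
  spos <- yrs - seas$first_year + 1L
  ok <- cpos >= 1L & cpos <= length(chronology$values) &
    spos >= 1L & spos <= length(seas$values)
  cv <- rep(NA_real_, length(yrs)); sv <- rep(NA_real_, length(yrs))
  cv[ok] <- chronology$values[cpos[ok]]
  sv[ok] <- seas$values[spos[ok]]
  use <- !is.na(cv) & !is.na(sv)
  if (sum(use) < 10L)
    stop("chronology/climate overlap < 10 years within interval")
  stats::cor(cv[use], sv[use])
}
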