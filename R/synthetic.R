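#' Configuration for the synthetic region generator
#'
#' Defines the study conditions the generator emulates: a juniper network of
#' `n_sites` stands (28 by default, 849 trees in total) on the south-eastern
#' Tibetan Plateau, moisture-coupled growth (site chronologies correlating
#' about `climate_coupling` with May-June scPDSI), three region-wide extreme
#' drought years planted as May-June scPDSI drops, per-tree heterogeneous
#' resistance/recovery with site-level spatial gradients, and drought-
#' inflated missing-ring probability.
#'
#' @param n_sites Number of sites.
#' @param total_trees Total trees across sites (distributed as evenly as
#'   possible).
#' @param trees_per_site Optional explicit integer vector (length `n_sites`);
#'   overrides `total_trees`.
#' @param span Length-2 first/last calendar year of tree growth and climate.
#' @param site_bbox Sampling window for site coordinates
#'   (`lat_min, lat_max, lon_min, lon_max`).
#' @param drought_years Planted region-wide extreme drought years.
#' @param drought_magnitude Drop magnitude per event, in SD units of the
#'   regional May-June scPDSI first differences. The defaults (7, 8, 9) give
#'   three droughts of distinct severity, all large enough that the 1.5-SD
#'   first-difference rule recovers them near-surely even though the planted
#'   drops themselves inflate the detection threshold.
#' @param climate_coupling Target correlation between a site chronology and
#'   May-June scPDSI.
#' @param glk_weight_range Range of the per-site common-signal weight (share
#'   of growth variance common to all trees of a site); drives the spread of
#'   site GLK values.
#' @param resistance_field List with per-event `p_high` (target proportion
#'   of high-resistance trees), `lat_slope` (change of that proportion from
#'   the southern to the northern edge), and the per-event means `high_mu`,
#'   `low_mu` and half-widths `high_hw`, `low_hw` of the uniform
#'   distributions the per-tree true resistance multipliers are drawn from.
#' @param recovery_field Same structure for recovery.
#' @param missing_ring_base_prob Per-year probability of a missing ring in a
#'   non-event year.
#' @param missing_ring_drought_mult Multiplier applied at event years (to
#'   low-resistance trees only: a missing ring is itself the extreme
#'   low-resistance outcome, so planted high-resistance trees never draw
#'   one).
#' @param noise_sd SD of per-tree log growth variability.
#' @param climate_local_sd SD of per-grid-point annual scPDSI deviations
#'   from the regional signal.
#' @param response_mode `"field"` plants the resistance/recovery fields
#'   directly; `"equation"` derives per-site target proportions from the
#'   fitted driver equations (see [generate_region()]).
#' @param equation_rt,equation_rc Coefficients (intercept, delta, glk) used
#'   in `"equation"` mode.
#' @param equation_r2 Target R-squared of the equation-mode responses
#'   (length 2: resistance, recovery models).
#' @param analysis_interval Years used for chronology-climate correlation
#'   and event detection.
#' @param seed Integer master seed of the hierarchical generator stream.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_sites = 28L, total_trees = 849L,
                             trees_per_site = NULL,
                             span = c(1800L, 2005L),
                             site_bbox = c(lat_min = 28.12, lat_max = 37.38,
                                           lon_min = 90.43, lon_max = 100.82),
                             drought_years = c(1969L, 1979L, 1995L),
                             drought_magnitude = c(7, 8, 9),
                             climate_coupling = 0.47,
                             glk_weight_range = c(0.45, 0.75),
                             resistance_field = list(
                               p_high = c(0.719, 0.552, 0.397),
                               lat_slope = c(0.10, -0.20, -0.35),
                               high_mu = c(1.05, 1.00, 0.95), high_hw = 0.12,
                               low_mu = c(0.52, 0.51, 0.45), low_hw = 0.15),
                             recovery_field = list(
                               p_high = c(0.283, 0.522, 0.642),
                               lat_slope = c(-0.10, 0.10, 0.20),
                               high_mu = c(2.5, 2.5, 2.5), high_hw = 1.0,
                               low_mu = c(0.82, 0.82, 0.82), low_hw = 0.27),
                             missing_ring_base_prob = 0.002,
                             missing_ring_drought_mult = 15,
                             noise_sd = 0.3,
                             climate_local_sd = 0.7,
                             response_mode = c("field", "equation"),
                             equation_rt = c(1.887, -0.052, -1.97),
                             equation_rc = c(-0.5413, 0.154, 1.45),
                             equation_r2 = c(0.35, 0.32),
                             analysis_interval = c(1957L, 2000L),
                             seed = 1L) {
  response_mode <- match.arg(response_mode)
  if (is.null(trees_per_site)) {
    base <- total_trees %/% n_sites
    extra <- total_trees %% n_sites
    trees_per_site <- rep(base, n_sites) + c(rep(1L, extra),
                                             rep(0L, n_sites - extra))
  }
  if (length(trees_per_site) != n_sites)
    stop("trees_per_site must have length n_sites")
  if (any(trees_per_site < 2L)) stop("each site needs >= 2 trees (GLK)")
  if (length(drought_magnitude) == 1L)
    drought_magnitude <- rep(drought_magnitude, length(drought_years))
  if (any(drought_years < span[1L] + 5L | drought_years > span[2L] - 5L))
    stop("drought years must sit >= 5 years inside the span")
  probs <- c(resistance_field$p_high, recovery_field$p_high,
             missing_ring_base_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(
    list(n_sites = as.integer(n_sites),
         trees_per_site = as.integer(trees_per_site),
         span = as.integer(span), site_bbox = site_bbox,
         drought_years = as.integer(drought_years),
         drought_magnitude = drought_magnitude,
         climate_coupling = climate_coupling,
         glk_weight_range = glk_weight_range,
         resistance_field = resistance_field,
         recovery_field = recovery_field,
         missing_ring_base_prob = missing_ring_base_prob,
         missing_ring_drought_mult = missing_ring_drought_mult,
         noise_sd = noise_sd, climate_local_sd = climate_local_sd,
         response_mode = response_mode, equation_rt = equation_rt,
         equation_rc = equation_rc, equation_r2 = equation_r2,
         analysis_interval = as.integer(analysis_interval),
         seed = as.integer(seed)),
    class = "generator_config")
}

# hierarchical counter-based seeding: one master seed plus a path of integer
# counters gives every region/site/tree its own reproducible substream, so
# adding a site never perturbs other sites' draws
stream_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (k in c(...)) h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  set.seed(as.integer(h))
  invisible(as.integer(h))
}

ar1_series <- function(n, phi, sd_marginal = 1) {
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, sd = sd_marginal)
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1L] + stats::rnorm(1L, sd = innov_sd)
  x
}

#' Generate synthetic site and grid-point locations
#'
#' Sites are scattered uniformly over the sampling window; each site's
#' climate grid point is its coordinates snapped to the half-degree grid.
#'
#' @param config A [generator_config()].
#' @return List with `sites` and `gridpoints` (lists of [site_location()])
#'   and `site_to_location` (named character vector).
#' @export
generate_locations <- function(config) {
  stream_seed(config$seed, 0L)
  bb <- config$site_bbox
  n <- config$n_sites
  lat <- stats::runif(n, bb[["lat_min"]], bb[["lat_max"]])
  lon <- stats::runif(n, bb[["lon_min"]], bb[["lon_max"]])
  elev <- round(stats::runif(n, 3300, 4700))
  ids <- sprintf("S%02d", seq_len(n))
  sites <- mapply(site_location, ids, lat, lon, elev, SIMPLIFY = FALSE)
  glat <- round(lat * 2) / 2
  glon <- round(lon * 2) / 2
  gids <- sprintf("GP_%04.1fN_%05.1fE", glat, glon)
  uniq <- !duplicated(gids)
  gridpoints <- mapply(site_location, gids[uniq], glat[uniq], glon[uniq],
                       SIMPLIFY = FALSE)
  list(sites = sites, gridpoints = gridpoints,
       site_to_location = stats::setNames(gids, ids))
}

#' Generate synthetic monthly climate for a set of grid points
#'
#' scPDSI is built from a standardized regional AR(1) annual signal
#' (autocorrelation 0.3) plus independent per-grid-point deviations, with
#' the configured drought drops subtracted from May and June of the event
#' years (magnitudes in SD units of the regional first differences). DTR,
#' temperatures and precipitation are seasonal climatologies plus noise;
#' May-July DTR gets a planted increase in the year following each drought.
#' Deterministic under the config seed.
#'
#' @param config A [generator_config()].
#' @param gridpoints List of [site_location()] grid points.
#' @return List of [climate_series()] named `location.variable`.
#' @export
generate_climate <- function(config, gridpoints) {
  yrs <- config$span[1L]:config$span[2L]
  ny <- length(yrs)
  ev_pos <- match(config$drought_years, yrs)
  stream_seed(config$seed, 1L)
  g <- ar1_series(ny, phi = 0.3)          # regional annual scPDSI signal
  sigma_diff <- sqrt(2 * (1 - 0.3))       # theoretical SD of its differences
  g[ev_pos] <- g[ev_pos] - config$drought_magnitude * sigma_diff
  # post-drought May-July DTR rises; magnitudes unrelated to drought
  # severity (cloud-cover recovery, not moisture, sets the DTR response)
  dtr_bump <- rep_len(c(1.0, 0.4, 1.2), length(ev_pos))
  out <- list()
  for (i in seq_along(gridpoints)) {
    gp <- gridpoints[[i]]
    stream_seed(config$seed, 1L, i)
    loc_pdsi <- g + stats::rnorm(ny, sd = config$climate_local_sd)
    m_pdsi <- matrix(loc_pdsi, ny, 12L) +
      matrix(stats::rnorm(ny * 12L, sd = 0.15), ny, 12L)
    months <- matrix(1:12, ny, 12L, byrow = TRUE)
    dtr_clim <- 13 + 2 * cos(2 * pi * (months - 1) / 12)   # widest in winter
    dtr_anom <- stats::rnorm(ny, sd = 0.4)
    m_dtr <- dtr_clim + matrix(dtr_anom, ny, 12L) +
      matrix(stats::rnorm(ny * 12L, sd = 0.3), ny, 12L)
    for (e in seq_along(ev_pos)) {
      row <- ev_pos[e] + 1L
      if (row <= ny) m_dtr[row, 5:7] <- m_dtr[row, 5:7] + dtr_bump[e]
    }
    t_clim <- 1 + 11 * cos(2 * pi * (months - 7) / 12)
    t_anom <- stats::rnorm(ny, sd = 0.8)
    m_tmean <- t_clim + matrix(t_anom, ny, 12L) +
      matrix(stats::rnorm(ny * 12L, sd = 0.5), ny, 12L)
    m_tmax <- m_tmean + m_dtr / 2
    m_tmin <- m_tmean - m_dtr / 2
    p_clim <- 5 + 60 * exp(-((months - 7) / 2)^2)          # monsoon peak
    m_prec <- pmax(0, p_clim * exp(stats::rnorm(ny * 12L, sd = 0.4)))
    add <- function(var, m, units) {
      out[[paste(gp$site_id, var, sep = ".")]] <<-
        climate_series(gp$site_id, var, yrs[1L], m, units)
    }
    add("scPDSI", m_pdsi, "index")
    add("DTR", m_dtr, "degC")
    add("T_mean", m_tmean, "degC")
    add("T_max", m_tmax, "degC")
    add("T_min", m_tmin, "degC")
    add("precipitation", matrix(m_prec, ny, 12L), "mm")
  }
  out
}

# exact-count assignment of n trees to the "high" group with probability p
assign_high <- function(n, p) {
  n_high <- round(p * n)
  sample(c(rep(TRUE, n_high), rep(FALSE, n - n_high)))
}

# expected pairwise GLK for two trees sharing a fraction w^2 of the variance
# of their (approximately independent) annual log-growth increments
expected_glk <- function(w) 0.5 + asin(w^2) / pi

#' Generate the trees of one synthetic site
#'
#' Annual widths follow a multiplicative lognormal model around a modified
#' negative-exponential age trend, the standard generative assumption
#' compatible with ratio detrending: `width_t = (a e^{-b t} + k) * index_t`
#' with `log index_t` mixing a site common signal (weight
#' `glk_signal_weight`) with tree-level noise. The common signal is itself a
#' mix of the site's standardized May-June scPDSI and non-climatic site
#' variability, calibrated so the site chronology correlates
#' `climate_coupling` with May-June scPDSI. Event-year suppression and the
#' 4-year post-event ramp are imposed on the index scale, so each tree's
#' true resistance and recovery multipliers are controlled exactly; an
#' exact count `round(p * n)` of trees is planted in each event's
#' high-resistance (high-recovery) group. Missing rings (width 0) are drawn
#' with the base probability in non-event years and, for low-resistance
#' trees only, with the inflated probability at event years. Widths are
#' quantized to 0.001 mm.
#'
#' @param config A [generator_config()].
#' @param site A [site_location()].
#' @param site_index Index of the site in the region (seeds its substream).
#' @param pdsi May-June scPDSI `seasonal_series` at the site's grid point.
#' @param targets List with per-event `p_rt`, `p_rc` target proportions and
#'   scalar `w` (common-signal weight); see [generate_region()].
#' @return List with `trees` (list of [rw_series()]) and `truth` (data.frame
#'   of per-tree, per-event planted multipliers and flags).
#' @export
generate_site_trees <- function(config, site, site_index, pdsi, targets) {
  n <- config$trees_per_site[site_index]
  yrs <- config$span[1L]:config$span[2L]
  ny <- length(yrs)
  w <- targets$w
  rf <- config$resistance_field
  cf <- config$recovery_field

  # site-level draws: common signal and event group assignments
  stream_seed(config$seed, 2L, site_index)
  pz <- (pdsi$values - mean(pdsi$values)) / stats::sd(pdsi$values)
  # attenuation correction: tree noise only averages down as 1/sqrt(n), and
  # the event-window index overwrites decouple ~1/4 of the correlation
  # interval from climate (empirical factor 1.37, fixed by calibration)
  alpha <- min(0.98, 1.37 * config$climate_coupling *
                 sqrt(w^2 + (1 - w^2) / n) / w)
  eta <- stats::rnorm(ny)
  common <- alpha * pz + sqrt(1 - alpha^2) * eta
  # stand establishment period: sites differ in age by up to ~130 years,
  # trees within a site by up to 20
  latest_start <- min(config$drought_years) - 20L
  site_base <- config$span[1L] +
    sample.int(max(1L, latest_start - 19L - config$span[1L] + 1L), 1L) - 1L
  high_rt <- vapply(targets$p_rt, assign_high, logical(n), n = n)
  high_rc <- vapply(targets$p_rc, assign_high, logical(n), n = n)
  high_rt <- matrix(high_rt, nrow = n)
  high_rc <- matrix(high_rc, nrow = n)

  trees <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    stream_seed(config$seed, 3L, site_index, i)
    first_year <- site_base + sample.int(20L, 1L) - 1L
    len <- ny - (first_year - config$span[1L])
    rows <- (first_year - config$span[1L] + 1L):ny
    xi <- stats::rnorm(len)
    l <- config$noise_sd * (w * common[rows] + sqrt(1 - w^2) * xi)
    idx <- exp(l - config$noise_sd^2 / 2)
    # age trend (modified negative exponential)
    a <- stats::runif(1L, 0.5, 1.5)
    b <- stats::runif(1L, 0.01, 0.04)
    k <- stats::runif(1L, 0.2, 0.6)
    age <- seq_len(len)
    trend <- a * exp(-b * age) + k
    # missing rings: base draws everywhere except event years
    miss <- stats::runif(len) < config$missing_ring_base_prob
    ev_local <- config$drought_years - first_year + 1L
    miss[ev_local[ev_local >= 1L & ev_local <= len]] <- FALSE
    tt <- data.frame(tree_id = sprintf("%s_T%03d", site$site_id, i),
                     site_id = site$site_id,
                     event_year = config$drought_years,
                     rt_star = NA_real_, rc_star = NA_real_,
                     high_rt = high_rt[i, ], high_rc = high_rc[i, ],
                     missing_event_ring = FALSE, window_inside = FALSE)
    for (e in seq_along(config$drought_years)) {
      pos <- ev_local[e]
      if (pos - 4L < 1L || pos + 4L > len) next
      tt$window_inside[e] <- TRUE
      rt_mu <- if (high_rt[i, e]) rf$high_mu[e] else rf$low_mu[e]
      rt_hw <- if (high_rt[i, e]) rf$high_hw else rf$low_hw
      rc_mu <- if (high_rc[i, e]) cf$high_mu[e] else cf$low_mu[e]
      rc_hw <- if (high_rc[i, e]) cf$high_hw else cf$low_hw
      rt_star <- stats::runif(1L, rt_mu - rt_hw, rt_mu + rt_hw)
      rc_star <- stats::runif(1L, rc_mu - rc_hw, rc_mu + rc_hw)
      drought_miss <- !high_rt[i, e] &&
        stats::runif(1L) < min(1, config$missing_ring_base_prob *
                                 config$missing_ring_drought_mult)
      idx_masked <- ifelse(miss, 0, idx)
      pre <- mean(idx_masked[(pos - 4L):(pos - 1L)])
      if (pre <= 0) next
      dr <- rt_star * pre
      idx[pos] <- dr
      post <- (pos + 1L):(pos + 4L)
      cur <- mean(ifelse(miss[post], 0, idx[post]))
      if (cur > 0) idx[post] <- idx[post] * (rc_star * dr) / cur
      if (drought_miss) {
        miss[pos] <- TRUE
        tt$missing_event_ring[e] <- TRUE
      }
      tt$rt_star[e] <- rt_star
      tt$rc_star[e] <- rc_star
    }
    widths <- pmax(round(trend * idx * 1000) / 1000, 0.001)
    widths[miss] <- 0
    if (all(widths == 0)) widths[which.max(idx)] <- 0.001
    trees[[i]] <- rw_series(tt$tree_id[1L], site$site_id, first_year, widths)
    truth[[i]] <- tt
  }
  list(trees = trees, truth = do.call(rbind, truth))
}

#' Generate a complete synthetic region with ground truth
#'
#' Produces the full input bundle the pipeline consumes — RWL ring-width
#' files (one per site), a long-format climate CSV, a site table — plus a
#' `ground_truth.json` with the planted per-site target proportions and the
#' per-tree multipliers they derive from. In `"field"` response mode the
#' per-site, per-event target proportions follow the configured resistance
#' and recovery fields (regional level per event plus a north-south
#' gradient), so the high-resistance area shrinks and the high-recovery area
#' grows across the events. In `"equation"` mode the targets are computed
#' from the configured driver equations applied to each site's realized
#' climate deltas and expected GLK, plus Gaussian noise scaled to the target
#' R-squared, making the driver regression recoverable end to end.
#'
#' @param config A [generator_config()].
#' @param dir Output directory for the bundle (created if needed); `NULL`
#'   skips writing and returns objects only.
#' @return Invisibly, a list with `sites`, `gridpoints`, `site_to_location`,
#'   `climate`, `trees` (flat list of [rw_series()]), `truth` (per-tree
#'   data.frame), `site_targets` (per site x event), `config` and `paths`.
#' @export
generate_region <- function(config = generator_config(), dir = NULL) {
  loc <- generate_locations(config)
  climate <- generate_climate(config, loc$gridpoints)
  bb <- config$site_bbox
  lat <- vapply(loc$sites, `[[`, 0, "latitude")
  lat_z <- (lat - bb[["lat_min"]]) / (bb[["lat_max"]] - bb[["lat_min"]])
  n_ev <- length(config$drought_years)
  stream_seed(config$seed, 4L)
  w_site <- stats::runif(config$n_sites, config$glk_weight_range[1L],
                         config$glk_weight_range[2L])

  tgt <- vector("list", config$n_sites)
  for (s in seq_len(config$n_sites)) {
    site_id <- loc$sites[[s]]$site_id
    gp <- loc$site_to_location[[site_id]]
    if (config$response_mode == "field") {
      p_rt <- config$resistance_field$p_high +
        config$resistance_field$lat_slope * (lat_z[s] - 0.5)
      p_rc <- config$recovery_field$p_high +
        config$recovery_field$lat_slope * (lat_z[s] - 0.5)
    } else {
      pdsi_s <- seasonal_mean(climate[[paste(gp, "scPDSI", sep = ".")]],
                              c(5L, 6L))
      dtr_s <- seasonal_mean(climate[[paste(gp, "DTR", sep = ".")]],
                             c(5L, 6L, 7L))
      at <- function(ss, y) ss$values[y - ss$first_year + 1L]
      dp <- at(pdsi_s, config$drought_years) -
        at(pdsi_s, config$drought_years - 1L)
      dd <- at(dtr_s, config$drought_years + 1L) -
        at(dtr_s, config$drought_years)
      eg <- expected_glk(w_site[s])
      p_rt <- config$equation_rt[1L] + config$equation_rt[2L] * dp +
        config$equation_rt[3L] * eg
      p_rc <- config$equation_rc[1L] + config$equation_rc[2L] * dd +
        config$equation_rc[3L] * eg
    }
    tgt[[s]] <- data.frame(site_id = site_id,
                           event_year = config$drought_years,
                           target_P_high_Rt = p_rt, target_P_high_Rc = p_rc,
                           glk_weight = w_site[s])
  }
  site_targets <- do.call(rbind, tgt)
  if (config$response_mode == "equation") {
    # add noise scaled to the target R2 of each driver equation
    stream_seed(config$seed, 5L)
    for (col in c("target_P_high_Rt", "target_P_high_Rc")) {
      r2 <- config$equation_r2[[match(col, c("target_P_high_Rt",
                                             "target_P_high_Rc"))]]
      v <- stats::var(site_targets[[col]])
      site_targets[[col]] <- site_targets[[col]] +
        stats::rnorm(nrow(site_targets), sd = sqrt(v * (1 - r2) / r2))
    }
  }
  site_targets$target_P_high_Rt <- pmin(pmax(site_targets$target_P_high_Rt,
                                             0.03), 0.97)
  site_targets$target_P_high_Rc <- pmin(pmax(site_targets$target_P_high_Rc,
                                             0.03), 0.97)

  trees <- list()
  truth <- vector("list", config$n_sites)
  for (s in seq_len(config$n_sites)) {
    site_id <- loc$sites[[s]]$site_id
    gp <- loc$site_to_location[[site_id]]
    pdsi_s <- seasonal_mean(climate[[paste(gp, "scPDSI", sep = ".")]],
                            c(5L, 6L))
    rows <- site_targets$site_id == site_id
    res <- generate_site_trees(
      config, loc$sites[[s]], s, pdsi_s,
      targets = list(p_rt = site_targets$target_P_high_Rt[rows],
                     p_rc = site_targets$target_P_high_Rc[rows],
                     w = w_site[s]))
    trees <- c(trees, res$trees)
    truth[[s]] <- res$truth
  }
  truth <- do.call(rbind, truth)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(file.path(dir, "rwl"), recursive = TRUE, showWarnings = FALSE)
    site_ids <- vapply(loc$sites, `[[`, "", "site_id")
    rwl_paths <- file.path(dir, "rwl", paste0(site_ids, ".rwl"))
    tree_sites <- vapply(trees, `[[`, "", "site_id")
    for (s in seq_along(site_ids))
      write_rwl(trees[tree_sites == site_ids[s]], rwl_paths[s])
    climate_path <- file.path(dir, "climate.csv")
    write_climate_csv(climate, climate_path)
    sites_path <- file.path(dir, "sites.csv")
    write_site_table(loc$sites, sites_path)
    grid_path <- file.path(dir, "gridpoints.csv")
    write_site_table(loc$gridpoints, grid_path)
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(event_years = config$drought_years,
           response_mode = config$response_mode,
           equation_rt = config$equation_rt,
           equation_rc = config$equation_rc,
           site_targets = site_targets, tree_truth = truth,
           seed = config$seed),
      truth_path, digits = NA, pretty = TRUE)
    paths <- list(rwl_dir = file.path(dir, "rwl"), climate = climate_path,
                  sites = sites_path, gridpoints = grid_path,
                  ground_truth = truth_path)
  }
  invisible(list(sites = loc$sites, gridpoints = loc$gridpoints,
                 site_to_location = loc$site_to_location, climate = climate,
                 trees = trees, truth = truth, site_targets = site_targets,
                 config = config, paths = paths))
}

#' Simulate a driver-regression design table
#'
#' Draws site-by-event predictor values with the spreads the full region
#' generator produces (three droughts of distinct severity, site-level
#' climate deviations, GLK and stand-structure variation), for studies of
#' the stepwise selection procedure at the design-matrix level.
#'
#' @param n_sites Number of sites (rows = `n_sites * 3` events).
#' @param seed Integer seed.
#' @return Data.frame with `site_id`, `event_year`, `delta_pdsi`,
#'   `delta_dtr`, `glk`, `mean_age`, `sd_indices`.
#' @export
simulate_design <- function(n_sites = 28L, seed = 1L) {
  stream_seed(seed, 9L)
  events <- c(1969L, 1979L, 1995L)
  d <- expand.grid(site_id = sprintf("S%02d", seq_len(n_sites)),
                   event_year = events, stringsAsFactors = FALSE)
  ev <- match(d$event_year, events)
  n <- nrow(d)
  d$delta_pdsi <- c(-2.0, -3.5, -5.0)[ev] + stats::rnorm(n, sd = 1.0)
  d$delta_dtr <- c(1.0, 0.4, 1.2)[ev] + stats::rnorm(n, sd = 0.25)
  d$glk <- stats::runif(n, 0.63, 0.80)
  d$mean_age <- stats::rnorm(n, 60, 12)
  d$sd_indices <- stats::runif(n, 0.15, 0.35)
  d
}

#' Simulate responses from a linear driver equation
#'
#' Computes `intercept + sum(coef * column)` over a design table and adds
#' Gaussian noise scaled so the population R-squared equals `r_squared`
#' (no noise when `r_squared = 1`).
#'
#' @param design Data.frame containing the named predictor columns.
#' @param coefficients Named numeric vector: first element the intercept
#'   (name ignored), remaining elements named after design columns.
#' @param r_squared Target R-squared in (0, 1].
#' @param seed Integer seed for the noise draw.
#' @return Numeric response vector.
#' @export
simulate_responses <- function(design, coefficients, r_squared = 1,
                               seed = 1L) {
  terms <- names(coefficients)[-1L]
  lin <- coefficients[[1L]]
  for (tm in terms) lin <- lin + coefficients[[tm]] * design[[tm]]
  if (r_squared >= 1) return(lin)
  stream_seed(seed, 10L)
  noise_sd <- sqrt(stats::var(lin) * (1 - r_squared) / r_squared)
  lin + stats::rnorm(nrow(design), sd = noise_sd)
}
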