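small_cfg <- function(seed = 1, ...) {
  generator_config(n_sites = 3L, total_trees = 12L, seed = seed, ...)
}

test_that("identical config and seed give a byte-identical bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_region(small_cfg(seed = 5), d1)
  generate_region(small_cfg(seed = 5), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_region(small_cfg(seed = 6), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "climate.csv"))),
    unname(tools::md5sum(file.path(d3, "climate.csv")))))
})

test_that("default configuration reproduces the study cardinality", {
  cfg <- generator_config()
  expect_equal(cfg$n_sites, 28L)
  expect_equal(sum(cfg$trees_per_site), 849L)
  expect_equal(cfg$drought_years, c(1969L, 1979L, 1995L))
  loc <- generate_locations(cfg)
  expect_length(loc$sites, 28L)
  lats <- vapply(loc$sites, `[[`, 0, "latitude")
  expect_true(all(lats >= 28.12 & lats <= 37.38))
  expect_true(all(loc$site_to_location %in%
                    vapply(loc$gridpoints, `[[`, "", "site_id")))
})

test_that("config validation rejects impossible settings", {
  expect_error(generator_config(drought_years = c(1802, 1979, 1995)),
               "inside the span")
  expect_error(generator_config(n_sites = 3, trees_per_site = c(5, 5)),
               "length n_sites")
  expect_error(generator_config(n_sites = 2, trees_per_site = c(1, 5)),
               ">= 2 trees")
  expect_error(generator_config(
    resistance_field = list(p_high = c(1.2, 0.5, 0.4),
                            lat_slope = c(0, 0, 0), high_mu = rep(1, 3),
                            high_hw = 0.1, low_mu = rep(0.5, 3),
                            low_hw = 0.1)), "probabilities")
})

test_that("planted group fractions are recoverable exactly from the truth", {
  reg <- generate_region(generator_config(n_sites = 4L, total_trees = 80L,
                                          seed = 9))
  for (s in unique(reg$truth$site_id)) {
    n_s <- sum(reg$truth$site_id == s & reg$truth$event_year == 1969)
    for (ev in c(1969, 1979, 1995)) {
      tt <- reg$truth[reg$truth$site_id == s & reg$truth$event_year == ev, ]
      tg <- reg$site_targets[reg$site_targets$site_id == s &
                               reg$site_targets$event_year == ev, ]
      expect_equal(mean(tt$high_rt), round(tg$target_P_high_Rt * n_s) / n_s)
      expect_equal(mean(tt$high_rc), round(tg$target_P_high_Rc * n_s) / n_s)
    }
  }
  # missing event rings only ever hit low-resistance trees
  expect_true(all(!reg$truth$high_rt[reg$truth$missing_event_ring]))
})

test_that("planted events are exactly recovered by the detection rule", {
  hits <- vapply(1:25, function(s) {
    cfg <- generator_config(span = c(1957L, 2000L), seed = s)
    loc <- generate_locations(cfg)
    cl <- generate_climate(cfg, loc$gridpoints)
    pdsi <- cl[vapply(cl, `[[`, "", "variable") == "scPDSI"]
    seas <- lapply(pdsi, seasonal_mean, months = c(5L, 6L))
    ev <- detect_extreme_droughts(regional_mean(seas), k = 1.5)
    identical(ev$year, c(1969L, 1979L, 1995L))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("without planted drops the planted years are not singled out", {
  hits <- vapply(1:20, function(s) {
    cfg <- generator_config(span = c(1957L, 2000L), drought_magnitude = 0,
                            seed = s)
    loc <- generate_locations(cfg)
    cl <- generate_climate(cfg, loc$gridpoints)
    pdsi <- cl[vapply(cl, `[[`, "", "variable") == "scPDSI"]
    seas <- lapply(pdsi, seasonal_mean, months = c(5L, 6L))
    ev <- detect_extreme_droughts(regional_mean(seas), k = 1.5)
    identical(ev$year, c(1969L, 1979L, 1995L))
  }, TRUE)
  expect_lt(mean(hits), 0.2)
})

test_that("suppression is planted on the index scale: realized Rt matches", {
  cfg <- generator_config(n_sites = 2L, total_trees = 30L, seed = 13,
                          missing_ring_base_prob = 0)
  reg <- generate_region(cfg)
  idx <- lapply(reg$trees, detrend)
  rec <- resilience_records(idx, cfg$drought_years)
  tr <- reg$truth[!reg$truth$missing_event_ring & reg$truth$window_inside, ]
  merged <- merge(rec, tr, by = c("tree_id", "event_year"))
  ok <- merged[merged$window_complete, ]
  expect_gt(nrow(ok), 50)
  # spline re-estimation jitters realized Rt only slightly around the truth
  expect_lt(median(abs(ok$Rt - ok$rt_star) / ok$rt_star), 0.03)
  expect_equal(mean(ok$high_resistance == (ok$rt_star > 0.75)), 1,
               tolerance = 0.03)
})

test_that("raising drought magnitude never raises realized resistance", {
  mean_rt <- vapply(c(3, 6, 9), function(mag) {
    cfg <- generator_config(n_sites = 2L, total_trees = 24L,
                            drought_magnitude = mag, seed = 31)
    reg <- generate_region(cfg)
    idx <- lapply(reg$trees, detrend)
    rec <- resilience_records(idx, cfg$drought_years)
    mean(rec$Rt[rec$window_complete])
  }, 0)
  expect_true(all(diff(mean_rt) < 0.03))
})

test_that("equation-mode targets carry the configured driver structure", {
  # moderate drops: at the published coefficients, the proportions the
  # equations predict stay inside [0, 1] for drought-year scPDSI swings of
  # a few index units, not the near-certain-detection magnitudes
  cfg <- generator_config(n_sites = 16L, trees_per_site = rep(2L, 16L),
                          response_mode = "equation",
                          drought_magnitude = c(2, 3, 4), seed = 3)
  reg <- generate_region(cfg)
  st <- reg$site_targets
  # recompute the realized predictors the targets were built from
  dp <- vapply(seq_len(nrow(st)), function(i) {
    gp <- reg$site_to_location[[st$site_id[i]]]
    s <- seasonal_mean(reg$climate[[paste0(gp, ".scPDSI")]], c(5, 6))
    at <- function(y) s$values[y - s$first_year + 1]
    at(st$event_year[i]) - at(st$event_year[i] - 1)
  }, 0)
  glk_e <- 0.5 + asin(st$glk_weight^2) / pi
  fit_rt <- lm(st$target_P_high_Rt ~ dp + glk_e)
  expect_lt(coef(fit_rt)[["dp"]], 0)
  expect_lt(coef(fit_rt)[["glk_e"]], 0)
  expect_gt(summary(fit_rt)$r.squared, 0.15)
})

test_that("glk weight controls realized growth coherence", {
  glk_at <- function(w) {
    cfg <- generator_config(n_sites = 1L, total_trees = 10L, seed = 17,
                            glk_weight_range = c(w, w),
                            missing_ring_base_prob = 0)
    reg <- generate_region(cfg)
    idx <- lapply(reg$trees, detrend)
    site_glk(idx, 1940L)   # window clear of any planted event
  }
  g <- vapply(c(0.1, 0.5, 1.0), glk_at, 0)
  expect_true(all(diff(g) > 0))
  expect_gt(g[3], 0.9)   # pure common signal: near-perfect coherence
})
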