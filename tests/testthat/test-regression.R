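# minimal site/climate scaffolding for build_design
make_design_inputs <- function() {
  pdsi <- matrix(0, 5, 12)                  # 1967-1971
  pdsi[, 5:6] <- c(0.5, 1.0, -2.0, 0.3, 0.1)  # May = June = annual value
  dtr <- matrix(14, 5, 12)
  dtr[3, 5:7] <- 14.0; dtr[4, 5:7] <- 15.5
  climate <- list(
    "G1.scPDSI" = climate_series("G1", "scPDSI", 1967, pdsi, "index"),
    "G1.DTR" = climate_series("G1", "DTR", 1967, dtr, "degC"),
    "G1.T_mean" = climate_series("G1", "T_mean", 1967, matrix(8, 5, 12)),
    "G1.T_max" = climate_series("G1", "T_max", 1967, matrix(15, 5, 12)),
    "G1.T_min" = climate_series("G1", "T_min", 1967, matrix(1, 5, 12)),
    "G1.precipitation" = climate_series("G1", "precipitation", 1967,
                                        matrix(40, 5, 12), "mm"))
  summaries <- data.frame(site_id = "S1", event_year = 1969L,
                          n_trees_evaluated = 30L, P_high_Rt = 0.7,
                          P_high_Rc = 0.3, mean_Rt = 0.9, mean_Rc = 1.2,
                          n_floored = 0L, mean_Rc_floored = NA_real_)
  factors <- data.frame(site_id = "S1", event_year = 1969L, glk = 0.7,
                        sd_indices = 0.25, mean_age = 80, n_trees = 30L)
  list(climate = climate, summaries = summaries, factors = factors,
       map = c(S1 = "G1"))
}

test_that("build_design computes the published delta definitions", {
  inp <- make_design_inputs()
  d <- build_design(inp$summaries, inp$factors, inp$climate, inp$map)
  expect_equal(nrow(d), 1L)
  # delta_pdsi: scPDSI(1969) - scPDSI(1968) = -2.0 - 1.0
  expect_equal(d$delta_pdsi, -3.0)
  # delta_dtr: DTR(1970) - DTR(1969) = 15.5 - 14.0
  expect_equal(d$delta_dtr, 1.5)
  expect_equal(d$glk, 0.7)
  expect_true(all(c("t_mean_mj", "prec_mj", "scpdsi_mj", "dtr_mjj")
                  %in% names(d)))
})

test_that("build_design excludes rows with missing climate", {
  inp <- make_design_inputs()
  inp$summaries <- rbind(inp$summaries,
                         within(inp$summaries, site_id <- "S2"))
  inp$factors <- rbind(inp$factors, within(inp$factors, site_id <- "S2"))
  inp$map <- c(inp$map, S2 = "G_MISSING")
  expect_message(
    d <- build_design(inp$summaries, inp$factors, inp$climate, inp$map),
    "excluded")
  expect_equal(nrow(d), 1L)
  expect_equal(attr(d, "excluded")$site_id, "S2")
})

test_that("stepwise_ols finds an exact linear signal and ignores noise", {
  set.seed(8)
  x1 <- rnorm(60); x2 <- rnorm(60)
  y <- 2 + 3 * x1
  m <- suppressWarnings(stepwise_ols(y, data.frame(x1 = x1, x2 = x2)))
  expect_equal(m$terms, "x1")
  expect_gt(m$r_squared, 0.999)
  expect_equal(unname(m$coefficients), c(2, 3), tolerance = 1e-8)

  y_noisy <- y + rnorm(60, sd = 0.3)
  expect_error(stepwise_ols(y_noisy, data.frame()), "non-empty")
  expect_warning(stepwise_ols(y_noisy, data.frame(x1 = x1, z = rep(1, 60))),
                 "zero-variance")
})

test_that("with thresholds at 1 stepwise reduces to full OLS", {
  set.seed(12)
  d <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- 1 + 0.5 * d$a - 0.2 * d$b + rnorm(50, sd = 0.5)
  m <- stepwise_ols(y, d, p_enter = 1, p_remove = 1)
  full <- lm(y ~ a + b + c, data = d)
  expect_setequal(m$terms, c("a", "b", "c"))
  expect_equal(sort(m$coefficients), sort(coef(full)), tolerance = 1e-10)
  expect_equal(m$r_squared, summary(full)$r.squared, tolerance = 1e-12)
})

test_that("reported R2 equals 1 - RSS/TSS recomputed from residuals", {
  set.seed(14)
  d <- data.frame(a = rnorm(70), b = rnorm(70))
  y <- 0.3 + 0.8 * d$a + rnorm(70, sd = 0.6)
  m <- stepwise_ols(y, d)
  r <- residuals(m)
  expect_equal(m$r_squared, 1 - sum(r^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(predict(m), y - r, ignore_attr = TRUE)
})

test_that("selection is invariant to affine rescaling of candidates", {
  set.seed(19)
  d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- 1 + 0.6 * d$a - 0.4 * d$b + rnorm(60, sd = 0.4)
  m1 <- stepwise_ols(y, d)
  d2 <- transform(d, a = 100 * a - 7, b = b / 1000 + 2)
  m2 <- stepwise_ols(y, d2)
  expect_equal(m1$terms, m2$terms)
  expect_equal(unname(m1$p_values), unname(m2$p_values), tolerance = 1e-9)
})

test_that("null responses enter candidates at roughly the entry rate", {
  set.seed(77)
  entered <- matrix(FALSE, 500, 5,
                    dimnames = list(NULL, paste0("x", 1:5)))
  for (r in 1:500) {
    d <- as.data.frame(matrix(rnorm(84 * 5), 84, 5))
    names(d) <- paste0("x", 1:5)
    m <- stepwise_ols(rnorm(84), d)
    entered[r, m$terms] <- TRUE
  }
  rate <- colMeans(entered)
  expect_true(all(rate >= 0.05 & rate <= 0.15))
})

test_that("noise-free driver equations are recovered to four decimals", {
  d <- simulate_design(28, seed = 2)
  cand <- d[, c("delta_pdsi", "delta_dtr", "glk", "mean_age", "sd_indices")]
  y_rt <- simulate_responses(d, c(b0 = 1.887, delta_pdsi = -0.052,
                                  glk = -1.97), r_squared = 1)
  m_rt <- suppressWarnings(stepwise_ols(y_rt, cand))
  expect_setequal(m_rt$terms, c("delta_pdsi", "glk"))
  expect_equal(m_rt$coefficients[["(Intercept)"]], 1.887, tolerance = 1e-4)
  expect_equal(m_rt$coefficients[["delta_pdsi"]], -0.052, tolerance = 1e-4)
  expect_equal(m_rt$coefficients[["glk"]], -1.97, tolerance = 1e-4)

  y_rc <- simulate_responses(d, c(b0 = -0.5413, delta_dtr = 0.154,
                                  glk = 1.45), r_squared = 1)
  m_rc <- suppressWarnings(stepwise_ols(y_rc, cand))
  expect_setequal(m_rc$terms, c("delta_dtr", "glk"))
  expect_equal(m_rc$coefficients[["(Intercept)"]], -0.5413, tolerance = 1e-4)
  expect_equal(m_rc$coefficients[["delta_dtr"]], 0.154, tolerance = 1e-4)
  expect_equal(m_rc$coefficients[["glk"]], 1.45, tolerance = 1e-4)
})

test_that("fit_driver_models wires both responses through the same pool", {
  d <- simulate_design(20, seed = 4)
  d$P_high_Rt <- simulate_responses(d, c(b0 = 1.887, delta_pdsi = -0.052,
                                         glk = -1.97), r_squared = 1)
  d$P_high_Rc <- simulate_responses(d, c(b0 = -0.5413, delta_dtr = 0.154,
                                         glk = 1.45), r_squared = 1)
  m <- suppressWarnings(fit_driver_models(d))
  expect_setequal(m$model_rt$terms, c("delta_pdsi", "glk"))
  expect_setequal(m$model_rc$terms, c("delta_dtr", "glk"))
  expect_lt(m$model_rt$coefficients[["glk"]], 0)
  expect_gt(m$model_rc$coefficients[["glk"]], 0)
})
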