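#' Assemble the driver-regression design matrix
#'
#' One row per site x event, combining the site-level responses
#' (`P_high_Rt`, `P_high_Rc` from [summarize_sites()]), the stand-internal
#' factors ([internal_factors()]), and climate predictors from each site's
#' nearest-grid-point series:
#' \describe{
#'   \item{delta_pdsi}{May-June scPDSI(event year) - scPDSI(year before).}
#'   \item{delta_dtr}{May-July DTR(year after) - DTR(event year), degC.}
#'   \item{seasonal levels}{Event-year May-June means of T_mean, T_max,
#'     T_min, precipitation and scPDSI, and the May-July DTR mean.}
#' }
#' With `full_monthly = TRUE` every monthly value of every variable is also
#' offered as a candidate (a much wider pool than the default seasonal
#' aggregates; a warning reminds that n should stay well above p).
#' Rows with any missing predictor are excluded and reported via the
#' `"excluded"` attribute.
#'
#' @param summaries Output of [summarize_sites()].
#' @param factors Data.frame of [internal_factors()] rows (site x event).
#' @param climate List of [climate_series()] named `location.variable` as
#'   returned by [read_climate_csv()].
#' @param site_to_location Named character vector mapping site_id to climate
#'   location_id (e.g. from [nearest_gridpoint()]).
#' @param pdsi_months Months for the scPDSI season (default May-June).
#' @param dtr_months Months for the DTR season (default May-July).
#' @param full_monthly Offer all 12 months x 6 variables as candidates.
#' @return A data.frame of class `design_rows`; responses are in [0, 1].
#' @export
build_design <- function(summaries, factors, climate, site_to_location,
                         pdsi_months = c(5L, 6L), dtr_months = c(5L, 6L, 7L),
                         full_monthly = FALSE) {
  if (full_monthly)
    warning("full monthly candidate pool requested: ",
            "keep the number of rows well above the number of candidates")
  key <- function(loc, var) paste(loc, var, sep = ".")
  seas_at <- function(loc, var, months, year) {
    cs <- climate[[key(loc, var)]]
    if (is.null(cs)) return(NA_real_)
    s <- seasonal_mean(cs, months)
    pos <- year - s$first_year + 1L
    if (pos < 1L || pos > length(s$values)) NA_real_ else s$values[pos]
  }
  rows <- lapply(seq_len(nrow(summaries)), function(i) {
    site <- summaries$site_id[i]
    ev <- summaries$event_year[i]
    loc <- site_to_location[[site]]
    fac <- factors[factors$site_id == site & factors$event_year == ev, ]
    if (nrow(fac) != 1L) return(NULL)
    row <- data.frame(
      site_id = site, event_year = ev,
      P_high_Rt = summaries$P_high_Rt[i], P_high_Rc = summaries$P_high_Rc[i],
      delta_pdsi = seas_at(loc, "scPDSI", pdsi_months, ev) -
        seas_at(loc, "scPDSI", pdsi_months, ev - 1L),
      delta_dtr = seas_at(loc, "DTR", dtr_months, ev + 1L) -
        seas_at(loc, "DTR", dtr_months, ev),
      t_mean_mj = seas_at(loc, "T_mean", pdsi_months, ev),
      t_max_mj = seas_at(loc, "T_max", pdsi_months, ev),
      t_min_mj = seas_at(loc, "T_min", pdsi_months, ev),
      prec_mj = seas_at(loc, "precipitation", pdsi_months, ev),
      scpdsi_mj = seas_at(loc, "scPDSI", pdsi_months, ev),
      dtr_mjj = seas_at(loc, "DTR", dtr_months, ev),
      glk = fac$glk, mean_age = fac$mean_age, sd_indices = fac$sd_indices)
    if (full_monthly) {
      for (v in climate_variables()) for (m in 1:12)
        row[[sprintf("%s_m%02d", tolower(v), m)]] <- seas_at(loc, v, m, ev)
    }
    row
  })
  d <- do.call(rbind, rows)
  pred <- setdiff(names(d), c("site_id", "event_year", "P_high_Rt",
                              "P_high_Rc"))
  complete <- stats::complete.cases(d[, pred, drop = FALSE])
  excluded <- d[!complete, c("site_id", "event_year")]
  if (nrow(excluded))
    message(nrow(excluded), " design row(s) excluded for missing predictors")
  d <- d[complete, , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "excluded") <- excluded
  class(d) <- c("design_rows", "data.frame")
  d
}

#' Forward-backward stepwise least squares with p-value thresholds
#'
#' Classic threshold-driven stepwise selection. At each forward step the
#' candidate with the smallest partial-F p-value (equivalently the squared-t
#' p-value of its coefficient given the current model) is added if that
#' p-value is below `p_enter`; ties are broken by lexicographic term name.
#' After every addition, retained terms whose p-value exceeds `p_remove` are
#' dropped iteratively, worst first. Selection stops when no candidate
#' qualifies for entry. The final model is refit by ordinary least squares.
#'
#' With `p_enter = p_remove = 1` the procedure reduces to the full-model
#' ordinary least squares on all candidates. Selection is invariant to
#' affine rescaling of any candidate column.
#'
#' @param y Numeric response vector.
#' @param candidates Data.frame of named candidate predictor columns.
#' @param p_enter Entry threshold (default 0.1).
#' @param p_remove Removal threshold (default 0.15).
#' @return An object of class `stepwise_ols`: list with `terms`,
#'   `coefficients` (intercept first), `p_values`, `r_squared`, `sigma`,
#'   `n`, `p_enter`, `p_remove`, `trace` (ordered add/drop log) and the
#'   final `fit` (an `lm`).
#' @export
stepwise_ols <- function(y, candidates, p_enter = 0.1, p_remove = 0.15) {
  if (!is.data.frame(candidates) || ncol(candidates) == 0L)
    stop("candidates must be a non-empty data.frame")
  if (nrow(candidates) != length(y)) stop("y and candidates lengths differ")
  keep <- vapply(candidates, function(x) stats::sd(x) > 0, TRUE)
  if (any(!keep)) {
    warning("dropping zero-variance candidate(s): ",
            paste(names(candidates)[!keep], collapse = ", "))
    candidates <- candidates[, keep, drop = FALSE]
    if (ncol(candidates) == 0L) stop("no usable candidates left")
  }
  dat <- cbind(.y = y, candidates)
  n <- length(y)
  term_p <- function(terms) {
    # p-values of each coefficient in the model with the given terms
    f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    sm <- summary(stats::lm(f, data = dat))
    cf <- stats::coef(sm)
    stats::setNames(cf[-1L, 4L], rownames(cf)[-1L])
  }
  selected <- character()
  trace <- character()
  resid_sd <- function(terms) {
    if (length(terms) == 0L) return(stats::sd(y))
    f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    summary(stats::lm(f, data = dat))$sigma
  }
  repeat {
    pool <- setdiff(names(candidates), selected)
    if (length(pool) == 0L || n < length(selected) + 3L) break
    # an (essentially) perfect fit leaves nothing for further candidates:
    # p-values on zero residuals are numerical noise
    if (resid_sd(selected) < 1e-8 * max(stats::sd(y), 1e-300)) break
    entry_p <- vapply(pool, function(cand) {
      ps <- tryCatch(term_p(c(selected, cand)), error = function(e) NULL)
      if (is.null(ps) || !(cand %in% names(ps)) || is.na(ps[[cand]])) {
        warning("candidate '", cand, "' skipped (collinear or unfittable)")
        Inf
      } else ps[[cand]]
    }, 0)
    best <- pool[order(entry_p, pool)][1L]
    if (!is.finite(entry_p[[best]]) || entry_p[[best]] >= p_enter) break
    selected <- c(selected, best)
    trace <- c(trace, paste0("+", best))
    repeat {
      ps <- term_p(selected)
      ps <- ps[!is.na(ps)]
      worst <- names(ps)[order(-ps, names(ps))][1L]
      if (length(ps) == 0L || ps[[worst]] <= p_remove) break
      selected <- setdiff(selected, worst)
      trace <- c(trace, paste0("-", worst))
      if (length(selected) == 0L) break
    }
    if (length(trace) > 4L * ncol(candidates)) break  # cycle guard
  }
  if (length(selected) == 0L) {
    fit <- stats::lm(.y ~ 1, data = dat)
    pv <- numeric(0)
  } else {
    fit <- stats::lm(stats::as.formula(
      paste(".y ~", paste(selected, collapse = " + "))), data = dat)
    pv <- term_p(selected)[selected]
  }
  sm <- summary(fit)
  structure(
    list(terms = selected, coefficients = stats::coef(fit), p_values = pv,
         r_squared = if (length(selected)) sm$r.squared else 0,
         sigma = sm$sigma, n = n, p_enter = p_enter, p_remove = p_remove,
         trace = trace, fit = fit),
    class = "stepwise_ols")
}

#' @export
print.stepwise_ols <- function(x, digits = 4, ...) {
  cat("Stepwise least-squares model (p_enter =", x$p_enter,
      ", p_remove =", x$p_remove, ")\n")
  if (length(x$terms) == 0L) {
    cat("  no terms selected (intercept-only model)\n")
  } else {
    b <- x$coefficients
    eq <- paste0(format(b[1L], digits = digits),
                 paste0(ifelse(b[-1L] >= 0, " + ", " - "),
                        format(abs(b[-1L]), digits = digits), "*",
                        names(b)[-1L], collapse = ""))
    cat("  y =", eq, "\n")
    cat("  R^2 =", format(x$r_squared, digits = digits), " n =", x$n, "\n")
  }
  invisible(x)
}

#' @export
summary.stepwise_ols <- function(object, ...) {
  print(object)
  if (length(object$terms)) {
    cat("  term p-values:\n")
    print(round(object$p_values, 5))
    cat("  trace:", paste(object$trace, collapse = " "), "\n")
  }
  invisible(object)
}

#' @export
coef.stepwise_ols <- function(object, ...) object$coefficients

#' @export
predict.stepwise_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.stepwise_ols <- function(object, ...) stats::residuals(object$fit)

#' Fit the high-resistance and high-recovery driver models
#'
#' Runs [stepwise_ols()] for both responses over the candidate columns of a
#' [build_design()] table: `P_high_Rt` (proportion of high-resistance trees)
#' and `P_high_Rc` (proportion of high-recovery trees). All events are
#' pooled into one regression (n = sites x events) unless `per_event = TRUE`.
#'
#' @param design A [build_design()] data.frame.
#' @param p_enter,p_remove Stepwise thresholds (defaults 0.1 / 0.15).
#' @param candidates Optional character vector restricting the candidate
#'   columns; default is every non-id, non-response column.
#' @param per_event Fit separate models per event (default FALSE).
#' @return A list with elements `model_rt` and `model_rc` (each a
#'   [stepwise_ols()] object), or a list of such pairs per event when
#'   `per_event = TRUE`.
#' @export
fit_driver_models <- function(design, p_enter = 0.1, p_remove = 0.15,
                              candidates = NULL, per_event = FALSE) {
  resp <- c("P_high_Rt", "P_high_Rc")
  if (is.null(candidates))
    candidates <- setdiff(names(design), c("site_id", "event_year", resp))
  if (per_event) {
    return(lapply(split(design, design$event_year), fit_driver_models,
                  p_enter = p_enter, p_remove = p_remove,
                  candidates = candidates, per_event = FALSE))
  }
  cand <- design[, candidates, drop = FALSE]
  list(model_rt = stepwise_ols(design$P_high_Rt, cand, p_enter, p_remove),
       model_rc = stepwise_ols(design$P_high_Rc, cand, p_enter, p_remove))
}
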