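#' Pipeline configuration
#'
#' Single declarative configuration for the full analysis. The defaults are
#' the `"juniper"` profile: spline cutoff at half the series length, May-June
#' scPDSI with the 1.5-SD first-difference rule for event detection, 4-year
#' resistance/recovery windows with thresholds 0.75 / 1.25, an 11-year GLK
#' window, and stepwise thresholds p_enter 0.1 / p_remove 0.15.
#'
#' Exactly one of `generator` or `input` must be supplied: either a
#' [generator_config()] (a synthetic bundle is generated into
#' `<out_dir>/inputs` and read back through the standard readers) or a list
#' with paths `rwl_dir`, `climate_csv`, `site_csv` and optionally
#' `gridpoint_csv` (grid-point coordinates for nearest-grid-point matching;
#' without it climate locations are matched to sites by identical IDs).
#'
#' @param out_dir Output directory for all stage tables and the manifest.
#' @param generator Optional [generator_config()].
#' @param input Optional list of input paths (see above).
#' @param cutoff_fraction Spline frequency-response cutoff as fraction of
#'   series length.
#' @param pdsi_months,dtr_months Seasonal windows for scPDSI and DTR.
#' @param k Event-detection threshold in SD units.
#' @param window Resistance/recovery window in years.
#' @param rt_threshold,rc_threshold High-resistance / high-recovery cutoffs.
#' @param dr_floor Event-year index floor for recovery.
#' @param half_window GLK half-window in years.
#' @param p_enter,p_remove Stepwise selection thresholds.
#' @param full_monthly Offer the full monthly candidate pool to the
#'   regression.
#' @param bbox Analysis bounding box (regional mean, Thiessen clipping).
#' @param analysis_interval Years of the drought-detection / correlation
#'   window.
#' @param area_cut Proportion cut for high/low area summaries.
#' @param seed Integer seed (used by the generator; the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            generator = NULL, input = NULL,
                            cutoff_fraction = 0.5,
                            pdsi_months = c(5L, 6L),
                            dtr_months = c(5L, 6L, 7L),
                            k = 1.5, window = 4L,
                            rt_threshold = 0.75, rc_threshold = 1.25,
                            dr_floor = 0.01, half_window = 5L,
                            p_enter = 0.1, p_remove = 0.15,
                            full_monthly = FALSE,
                            bbox = default_bbox(),
                            analysis_interval = c(1957L, 2000L),
                            area_cut = 0.5, seed = 1L) {
  if (is.null(generator) == is.null(input))
    stop("supply exactly one of 'generator' or 'input'")
  structure(
    list(out_dir = out_dir, generator = generator, input = input,
         cutoff_fraction = cutoff_fraction, pdsi_months = pdsi_months,
         dtr_months = dtr_months, k = k, window = window,
         rt_threshold = rt_threshold, rc_threshold = rc_threshold,
         dr_floor = dr_floor, half_window = half_window,
         p_enter = p_enter, p_remove = p_remove,
         full_monthly = full_monthly, bbox = bbox,
         analysis_interval = analysis_interval, area_cut = area_cut,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$bbox)) y$bbox <- unlist(y$bbox)
  if (!is.null(y$generator)) {
    if (!is.null(y$generator$site_bbox))
      y$generator$site_bbox <- unlist(y$generator$site_bbox)
    y$generator <- do.call(generator_config, y$generator)
  }
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$bbox <- as.list(y$bbox)   # keep names through YAML
  if (!is.null(y$generator)) {
    y$generator <- unclass(y$generator)
    y$generator$site_bbox <- as.list(y$generator$site_bbox)
  }
  yaml::write_yaml(y[!vapply(y, is.null, TRUE)], path)
  invisible(path)
}

#' Run the full resilience analysis pipeline
#'
#' Executes the stages in order — input (read or generate), detrending +
#' chronologies, drought-event detection, per-tree resistance/recovery,
#' growth coherence, driver regression, Thiessen mapping — writing one or
#' more CSV/JSON/GeoJSON files per stage into `config$out_dir` plus a run
#' manifest (`manifest.json`: config hash, package version, seed, per-stage
#' row counts). Outputs contain no timestamps, so re-running with an
#' identical config and seed reproduces byte-identical files.
#'
#' If no drought event is detected, the resilience and downstream stages
#' are skipped with an explicit warning and the manifest records status
#' `"no_events"`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest (list of class `pipeline_manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "dendrores",
                   version = as.character(utils::packageVersion("dendrores")),
                   seed = config$seed, status = "running", stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    res
  }
  note <- function(name, rows) {
    manifest$stages[[name]] <<- list(rows = as.integer(rows))
  }
  cfg_path <- file.path(out, "config.json")
  cfg_echo <- unclass(config)
  cfg_echo$out_dir <- NULL   # analysis parameters only, not the run location
  jsonlite::write_json(cfg_echo, cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  ## stage 1: input -------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(config$generator)) {
      gen <- generate_region(config$generator, file.path(out, "inputs"))
      list(rwl_dir = gen$paths$rwl_dir, climate_csv = gen$paths$climate,
           site_csv = gen$paths$sites, gridpoint_csv = gen$paths$gridpoints)
    } else config$input
  })
  trees <- stage("input", {
    files <- sort(list.files(inp$rwl_dir, pattern = "\\.rwl$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no .rwl files in ", inp$rwl_dir)
    unlist(lapply(files, read_rwl), recursive = FALSE)
  })
  climate <- stage("input", read_climate_csv(inp$climate_csv))
  sites <- stage("input", read_site_table(inp$site_csv))
  gridpoints <- if (!is.null(inp$gridpoint_csv))
    read_site_table(inp$gridpoint_csv) else NULL
  site_to_location <- stage("input", {
    if (is.null(gridpoints)) {
      stats::setNames(names(sites), names(sites))
    } else {
      vapply(sites, nearest_gridpoint, "", grid_locations = gridpoints)
    }
  })
  note("input", length(trees))

  ## stage 2: detrend + chronologies --------------------------------------
  indices <- stage("detrend", lapply(trees, detrend,
                                     cutoff_fraction = config$cutoff_fraction))
  tree_sites <- vapply(indices, `[[`, "", "site_id")
  by_site <- split(indices, tree_sites)
  chron <- stage("detrend", lapply(by_site, build_chronology))
  idx_tab <- do.call(rbind, lapply(indices, function(s)
    data.frame(year = series_years(s), site_id = s$site_id,
               tree_id = s$tree_id, value = s$indices)))
  utils::write.csv(idx_tab, file.path(out, "indices.csv"),
                   row.names = FALSE, quote = FALSE)
  chron_tab <- do.call(rbind, lapply(chron, function(ch)
    data.frame(year = series_years(ch), site_id = ch$site_id,
               value = ch$values, sample_depth = ch$sample_depth)))
  utils::write.csv(chron_tab, file.path(out, "chronologies.csv"),
                   row.names = FALSE, quote = FALSE)
  note("detrend", nrow(chron_tab))

  ## chronology-climate correlations per site
  cors <- stage("detrend", vapply(names(chron), function(sid) {
    cs <- climate[[paste(site_to_location[[sid]], "scPDSI", sep = ".")]]
    if (is.null(cs)) return(NA_real_)
    tryCatch(correlate_chronology_climate(chron[[sid]], cs,
                                          config$pdsi_months,
                                          config$analysis_interval),
             error = function(e) NA_real_)
  }, 0))
  utils::write.csv(data.frame(site_id = names(cors), r_pdsi = unname(cors)),
                   file.path(out, "site_correlations.csv"),
                   row.names = FALSE, quote = FALSE)

  ## stage 3: events ------------------------------------------------------
  events <- stage("events", {
    pdsi <- climate[vapply(climate, `[[`, "", "variable") == "scPDSI"]
    if (length(pdsi) == 0L) stop("no scPDSI series in climate input")
    seas <- lapply(pdsi, seasonal_mean, months = config$pdsi_months)
    reg <- regional_mean(seas, locations = gridpoints,
                         bbox = if (is.null(gridpoints)) NULL else config$bbox)
    iv <- config$analysis_interval
    pos <- (iv[1L]:iv[2L]) - reg$first_year + 1L
    pos <- pos[pos >= 1L & pos <= length(reg$values)]
    reg$values <- reg$values[pos]
    reg$first_year <- reg$first_year + pos[1L] - 1L
    detect_extreme_droughts(reg, k = config$k)
  })
  utils::write.csv(events, file.path(out, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  note("events", nrow(events))

  if (nrow(events) == 0L) {
    warning("no extreme drought events detected: ",
            "resilience stages skipped")
    manifest$status <- "no_events"
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    class(manifest) <- "pipeline_manifest"
    attr(manifest, "out_dir") <- out
    return(invisible(manifest))
  }

  ## stage 4: resilience --------------------------------------------------
  records <- stage("resilience",
                   resilience_records(indices, events$year, config$window,
                                      config$dr_floor, config$rt_threshold,
                                      config$rc_threshold))
  utils::write.csv(records, file.path(out, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  summaries <- stage("resilience", summarize_sites(records))
  utils::write.csv(summaries, file.path(out, "site_summaries.csv"),
                   row.names = FALSE, quote = FALSE)
  note("resilience", nrow(records))

  ## stage 5: coherence ---------------------------------------------------
  factors <- stage("coherence", {
    do.call(rbind, lapply(events$year, function(ev) {
      do.call(rbind, lapply(by_site, function(trees_s) {
        tryCatch(internal_factors(trees_s, ev, config$half_window),
                 error = function(e) NULL)
      }))
    }))
  })
  utils::write.csv(factors, file.path(out, "internal_factors.csv"),
                   row.names = FALSE, quote = FALSE)
  note("coherence", nrow(factors))

  ## stage 6: regression --------------------------------------------------
  design <- stage("regression",
                  build_design(summaries, factors, climate, site_to_location,
                               config$pdsi_months, config$dtr_months,
                               config$full_monthly))
  utils::write.csv(as.data.frame(design), file.path(out, "design.csv"),
                   row.names = FALSE, quote = FALSE)
  models <- stage("regression",
                  fit_driver_models(design, config$p_enter, config$p_remove))
  model_json <- lapply(models, function(m)
    list(terms = m$terms, coefficients = as.list(m$coefficients),
         p_values = as.list(m$p_values), r_squared = m$r_squared,
         n = m$n, trace = m$trace))
  jsonlite::write_json(model_json, file.path(out, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("regression", nrow(design))

  ## stage 7: spatial -----------------------------------------------------
  spatial_rows <- stage("spatial", {
    map <- thiessen_polygons(sites, config$bbox)
    areas <- lapply(events$year, function(ev) {
      m <- attach_site_values(map, summaries, ev)
      export_geojson(m, file.path(out, sprintf("map_%d.geojson", ev)))
      data.frame(event_year = ev,
                 high_rt_area = classify_area(m, "P_high_Rt",
                                              config$area_cut)[["high"]],
                 high_rc_area = classify_area(m, "P_high_Rc",
                                              config$area_cut)[["high"]])
    })
    at <- do.call(rbind, areas)
    utils::write.csv(at, file.path(out, "area_fractions.csv"),
                     row.names = FALSE, quote = FALSE)
    nrow(at)
  })
  note("spatial", spatial_rows)

  manifest$status <- "complete"
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "pipeline_manifest"
  attr(manifest, "out_dir") <- out
  invisible(manifest)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest>", x$package, x$version, "status:", x$status, "\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %d rows\n", nm, x$stages[[nm]]$rows))
  invisible(x)
}

#' Summarize a completed pipeline run
#'
#' Rebuilds the regional results from the stage tables on disk: one row per
#' event with regional mean resistance and recovery (floored recoveries
#' excluded from the mean, counted separately), the regional proportions of
#' high-resistance and high-recovery trees, plus Kruskal-Wallis comparisons
#' of the per-tree distributions across events, the mean chronology-scPDSI
#' correlation, and the fitted driver-model equations.
#'
#' @param x A `pipeline_manifest` or the output directory of a run.
#' @return A list of class `resilience_report` with elements `events`
#'   (per-event table), `kruskal_rt`, `kruskal_rc`, `mean_r_pdsi`,
#'   `models` and `area` (high-area fractions per event).
#' @export
summarize_run <- function(x) {
  out <- if (inherits(x, "pipeline_manifest")) attr(x, "out_dir") else x
  man_path <- file.path(out, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", out)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (!identical(man$status, "complete"))
    stop("run is not complete (status: ", man$status, ")")
  records <- utils::read.csv(file.path(out, "records.csv"))
  cors <- utils::read.csv(file.path(out, "site_correlations.csv"))
  models <- jsonlite::read_json(file.path(out, "models.json"),
                                simplifyVector = TRUE)
  area <- utils::read.csv(file.path(out, "area_fractions.csv"))
  ok <- records[records$window_complete, ]
  ev_tab <- do.call(rbind, lapply(split(ok, ok$event_year), function(r) {
    unfl <- r[!r$dr_floored, ]
    data.frame(event_year = r$event_year[1L], n_trees = nrow(r),
               mean_Rt = mean(r$Rt), mean_Rc = mean(unfl$Rc),
               P_high_Rt = mean(r$high_resistance),
               P_high_Rc = mean(r$high_recovery),
               n_floored = sum(r$dr_floored))
  }))
  rownames(ev_tab) <- NULL
  n_ev <- nrow(ev_tab)
  kru_rt <- kru_rc <- NULL
  if (n_ev >= 2L) {
    kru_rt <- compare_events(split(ok$Rt, ok$event_year))
    kru_rc <- compare_events(split(ok$Rc, ok$event_year))
  }
  structure(list(events = ev_tab, kruskal_rt = kru_rt, kruskal_rc = kru_rc,
                 mean_r_pdsi = mean(cors$r_pdsi, na.rm = TRUE),
                 models = models, area = area),
            class = "resilience_report")
}

#' @export
print.resilience_report <- function(x, digits = 3, ...) {
  cat("Regional tree resilience summary\n")
  cat("--------------------------------\n")
  print(format(x$events, digits = digits), row.names = FALSE)
  cat(sprintf("mean chronology ~ May-June scPDSI r: %.2f\n", x$mean_r_pdsi))
  if (!is.null(x$kruskal_rt)) {
    cat(sprintf("Kruskal-Wallis across events: Rt H = %.2f (p = %.2g), ",
                x$kruskal_rt$H, x$kruskal_rt$p_value))
    cat(sprintf("Rc H = %.2f (p = %.2g)\n", x$kruskal_rc$H,
                x$kruskal_rc$p_value))
  } else cat("single event: Kruskal-Wallis comparison omitted\n")
  eq <- function(m, resp) {
    b <- unlist(m$coefficients)
    if (length(b) <= 1L) return(sprintf("%s: no terms selected", resp))
    rhs <- paste0(format(b[1L], digits = digits),
                  paste0(ifelse(b[-1L] >= 0, " + ", " - "),
                         format(abs(b[-1L]), digits = digits), "*",
                         names(b)[-1L], collapse = ""))
    sprintf("%s = %s (R2 = %.2f)", resp, rhs, m$r_squared)
  }
  cat(eq(x$models$model_rt, "P_high_Rt"), "\n")
  cat(eq(x$models$model_rc, "P_high_Rc"), "\n")
  if (!is.null(x$area)) {
    cat("high-area fractions (share of bbox):\n")
    print(format(x$area, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
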