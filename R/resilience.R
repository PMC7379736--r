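#' Tree resistance to a drought event
#'
#' Lloret resistance: `Rt = Dr / PreDr`, where `Dr` is the ring-width index
#' in the event year and `PreDr` the mean index over the `window` preceding
#' years. A missing ring in the event year (`Dr = 0`) gives `Rt = 0` exactly.
#'
#' @param indices An [rwi_series()].
#' @param event_year Calendar year of the drought event.
#' @param window Number of preceding years averaged (default 4).
#' @return A list with `Rt`, `Dr`, `PreDr` and `window_complete`. An
#'   incomplete pre-window (or `PreDr = 0`) sets `window_complete = FALSE`
#'   and `Rt = NA` rather than raising an error, so such trees can be
#'   excluded from aggregation.
#' @export
resistance <- function(indices, event_year, window = 4L) {
  dr <- index_at(indices, event_year)
  pre <- index_at(indices, (event_year - window):(event_year - 1L))
  if (anyNA(c(dr, pre)) || mean(pre) == 0)
    return(list(Rt = NA_real_, Dr = dr, PreDr = mean(pre),
                window_complete = FALSE))
  list(Rt = dr / mean(pre), Dr = dr, PreDr = mean(pre), window_complete = TRUE)
}

#' Tree recovery from a drought event
#'
#' Lloret recovery: `Rc = PostDr / Dr`, where `PostDr` is the mean index over
#' the `window` years following the event. A missing or near-zero event-year
#' ring would make `Rc` infinite, so `Dr` is floored at `dr_floor` before
#' division; records where the floor engaged are flagged `dr_floored` (they
#' yield large finite recoveries and are excluded from mean recovery by
#' default downstream).
#'
#' @inheritParams resistance
#' @param dr_floor Lower bound applied to `Dr` (default 0.01 index units).
#' @return A list with `Rc`, `Dr`, `PostDr`, `dr_floored` and
#'   `window_complete` (FALSE, with `Rc = NA`, if the post-window is
#'   incomplete).
#' @export
recovery <- function(indices, event_year, window = 4L, dr_floor = 0.01) {
  dr <- index_at(indices, event_year)
  post <- index_at(indices, (event_year + 1L):(event_year + window))
  if (anyNA(c(dr, post)))
    return(list(Rc = NA_real_, Dr = dr, PostDr = mean(post),
                dr_floored = FALSE, window_complete = FALSE))
  floored <- dr < dr_floor
  list(Rc = mean(post) / max(dr, dr_floor), Dr = dr, PostDr = mean(post),
       dr_floored = floored, window_complete = TRUE)
}

#' Classify a tree as high-resistance / high-recovery
#'
#' Strict thresholds: high resistance iff `Rt > rt_threshold` (0.75), high
#' recovery iff `Rc > rc_threshold` (1.25). Values exactly at a threshold do
#' not qualify.
#'
#' @param record A one-row data.frame (or list) with finite `Rt` and `Rc`.
#' @param rt_threshold,rc_threshold Classification cutoffs.
#' @return The record with logical `high_resistance` and `high_recovery`
#'   added.
#' @export
classify <- function(record, rt_threshold = 0.75, rc_threshold = 1.25) {
  record$high_resistance <- !is.na(record$Rt) & record$Rt > rt_threshold
  record$high_recovery <- !is.na(record$Rc) & record$Rc > rc_threshold
  record
}

#' Per-tree resilience records for a set of events
#'
#' Computes [resistance()] and [recovery()] for every tree and event and
#' applies [classify()].
#'
#' @param indices List of [rwi_series()].
#' @param event_years Integer vector of drought event years.
#' @param window Pre/post window length in years (default 4).
#' @param dr_floor Event-year index floor for recovery (default 0.01).
#' @param rt_threshold,rc_threshold Classification cutoffs (0.75 / 1.25).
#' @return A data.frame of class `resilience_records` with one row per
#'   tree x event: `tree_id`, `site_id`, `event_year`, `Rt`, `Rc`, `Dr`,
#'   `PreDr`, `PostDr`, `high_resistance`, `high_recovery`,
#'   `window_complete`, `dr_floored`.
#' @export
resilience_records <- function(indices, event_years, window = 4L,
                               dr_floor = 0.01, rt_threshold = 0.75,
                               rc_threshold = 1.25) {
  rows <- lapply(indices, function(s) {
    do.call(rbind, lapply(event_years, function(e) {
      rt <- resistance(s, e, window)
      rc <- recovery(s, e, window, dr_floor)
      data.frame(tree_id = s$tree_id, site_id = s$site_id, event_year = e,
                 Rt = rt$Rt, Rc = rc$Rc, Dr = rt$Dr, PreDr = rt$PreDr,
                 PostDr = rc$PostDr,
                 window_complete = rt$window_complete && rc$window_complete,
                 dr_floored = rc$dr_floored)
    }))
  })
  out <- classify(do.call(rbind, rows), rt_threshold, rc_threshold)
  rownames(out) <- NULL
  class(out) <- c("resilience_records", "data.frame")
  out
}

#' @export
print.resilience_records <- function(x, ...) {
  cat(sprintf("<resilience_records> %d records, %d trees, events: %s\n",
              nrow(x), length(unique(x$tree_id)),
              paste(sort(unique(x$event_year)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Site-level summary of one event
#'
#' Aggregates per-tree records of a single site and event into the
#' proportions of high-resistance and high-recovery trees and mean Rt / Rc.
#' Only records with a complete pre- and post-window enter; records whose
#' recovery was floored still count in the proportions but are excluded from
#' `mean_Rc` (reported separately as `mean_Rc_floored` and `n_floored`).
#'
#' @param records Rows of [resilience_records()] for one site and one event.
#' @return A one-row data.frame: `site_id`, `event_year`, `n_trees_evaluated`,
#'   `P_high_Rt`, `P_high_Rc`, `mean_Rt`, `mean_Rc`, `n_floored`,
#'   `mean_Rc_floored`.
#' @export
site_event_summary <- function(records) {
  if (length(unique(records$site_id)) != 1L ||
      length(unique(records$event_year)) != 1L)
    stop("records must belong to a single site and event")
  ok <- records[records$window_complete, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("no complete records for site ", records$site_id[1L], ", event ",
         records$event_year[1L])
  unfloored <- ok[!ok$dr_floored, , drop = FALSE]
  data.frame(
    site_id = ok$site_id[1L], event_year = ok$event_year[1L],
    n_trees_evaluated = nrow(ok),
    P_high_Rt = mean(ok$high_resistance),
    P_high_Rc = mean(ok$high_recovery),
    mean_Rt = mean(ok$Rt),
    mean_Rc = if (nrow(unfloored)) mean(unfloored$Rc) else NA_real_,
    n_floored = sum(ok$dr_floored),
    mean_Rc_floored = if (any(ok$dr_floored))
      mean(ok$Rc[ok$dr_floored]) else NA_real_)
}

#' Summarize all sites and events
#'
#' @param records A [resilience_records()] table.
#' @return A data.frame with one [site_event_summary()] row per site x event
#'   that has at least one complete record.
#' @export
summarize_sites <- function(records) {
  parts <- split(records, list(records$site_id, records$event_year),
                 drop = TRUE)
  parts <- parts[vapply(parts, function(p) any(p$window_complete), TRUE)]
  if (length(parts) == 0L) stop("no complete records in table")
  out <- do.call(rbind, lapply(parts, site_event_summary))
  out <- out[order(out$event_year, out$site_id), ]
  rownames(out) <- NULL
  out
}

#' Compare per-tree indices across drought events
#'
#' Kruskal-Wallis rank test (with tie correction) of whether the
#' distribution of a resilience index differs between events.
#'
#' @param values_by_event Named list of numeric vectors, one per event, each
#'   with at least 2 values.
#' @return A list with `H` (the chi-square statistic), `df` and `p_value`.
#' @export
compare_events <- function(values_by_event) {
  if (length(values_by_event) < 2L) stop("need >= 2 groups")
  n_per <- vapply(values_by_event, length, 0L)
  if (any(n_per < 2L)) stop("every group needs >= 2 values")
  kt <- stats::kruskal.test(values_by_event)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
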