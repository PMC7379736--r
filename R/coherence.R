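#' Gleichlaeufigkeit (GLK) of two index series
#'
#' Sign agreement of year-to-year growth changes over the common window of
#' two trees: each of the n-1 first-difference intervals scores 1 when both
#' series move in the same direction, 0 when they move oppositely and 0.5
#' when either difference is zero (the classical tie convention; quantized
#' ring widths produce exact ties). The GLK is the mean score, in [0, 1].
#'
#' @param a,b [rwi_series()] objects (any series object with consecutive
#'   annual values works).
#' @param years Optional integer vector restricting the comparison window;
#'   default is the full overlap of the two series.
#' @return GLK in [0, 1], or `NA` if the common window has fewer than 2
#'   years.
#' @export
glk_pair <- function(a, b, years = NULL) {
  if (is.null(years))
    years <- max(a$first_year, b$first_year):min(last_year(a), last_year(b))
  if (length(years) < 2L) return(NA_real_)
  va <- index_at(a, years)
  vb <- index_at(b, years)
  if (anyNA(va) || anyNA(vb)) return(NA_real_)
  da <- sign(diff(va))
  db <- sign(diff(vb))
  score <- ifelse(da == 0 | db == 0, 0.5, (da == db) * 1)
  mean(score)
}

#' Site-level GLK around an event
#'
#' Arithmetic mean of [glk_pair()] over all unordered pairs of trees that
#' fully cover the window `[event_year - half_window, event_year +
#' half_window]` (11 years by default: the event year plus 5 years on each
#' side). Pairs without full coverage are dropped rather than partially
#' scored, so the window is identical for every pair.
#'
#' @param trees List of [rwi_series()] from one site.
#' @param event_year Central (event) calendar year.
#' @param half_window Years on each side of the event (default 5).
#' @return Mean pairwise GLK in [0, 1].
#' @export
site_glk <- function(trees, event_year, half_window = 5L) {
  years <- (event_year - half_window):(event_year + half_window)
  covers <- vapply(trees, function(s) !anyNA(index_at(s, years)), TRUE)
  trees <- trees[covers]
  if (length(trees) < 2L)
    stop("fewer than 2 trees cover the ", length(years), "-year window at ",
         event_year)
  pairs <- utils::combn(length(trees), 2L)
  g <- apply(pairs, 2L, function(p)
    glk_pair(trees[[p[1L]]], trees[[p[2L]]], years))
  mean(g)
}

#' Forest internal factors for one site and event
#'
#' Computes the stand-internal covariates used as resilience drivers:
#' \describe{
#'   \item{glk}{[site_glk()] over the 11-year event window.}
#'   \item{sd_indices}{Sample SD of all trees' ring-width indices within the
#'     same window.}
#'   \item{mean_age}{Mean ring count from each tree's first ring to the
#'     event year, inclusive. Cores rarely hit the pith, so this
#'     underestimates true tree age; it is a relative age measure.}
#' }
#'
#' @param trees List of [rwi_series()] from one site (>= 2 trees).
#' @param event_year Event calendar year.
#' @param half_window Years on each side of the event (default 5).
#' @return A one-row data.frame: `site_id`, `event_year`, `glk`,
#'   `sd_indices`, `mean_age`, `n_trees`.
#' @export
internal_factors <- function(trees, event_year, half_window = 5L) {
  if (length(trees) < 2L) stop("site needs >= 2 trees")
  glk <- site_glk(trees, event_year, half_window)
  years <- (event_year - half_window):(event_year + half_window)
  vals <- unlist(lapply(trees, function(s) {
    v <- index_at(s, years)
    v[!is.na(v)]
  }))
  ages <- vapply(trees, function(s) as.numeric(event_year) - s$first_year + 1,
                 0)
  ages <- ages[ages > 0L]
  data.frame(site_id = trees[[1L]]$site_id, event_year = event_year,
             glk = glk, sd_indices = stats::sd(vals), mean_age = mean(ages),
             n_trees = length(trees))
}
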