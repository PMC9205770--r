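#' Study timeline for a segmented interrupted time series
#'
#' Defines the month indexing of the three analysis regimes: the pre-pandemic
#' baseline, the acute shock window during which both a level and a slope
#' change apply, and the resumption quarter at the end of the study period.
#' Months are abstract indices \code{1..total_months}; with the defaults,
#' index 1 corresponds to January 2019, months 1-15 are baseline
#' (January 2019 - March 2020), months 16-21 are the 6-month shock window
#' (April - September 2020) and months 22-24 are the resumption quarter
#' (October - December 2020).
#'
#' The Nepali calendar variant (14 baseline months, 10 pandemic months) is
#' obtained with \code{baseline_months = 14}.
#'
#' @param total_months total number of monthly observations (default 24).
#' @param baseline_months number of pre-pandemic months (default 15).
#' @param shock_months length of the acute shock window (default 6).
#' @return An object of class \code{study_timeline}: a list with fields
#'   \code{total_months}, \code{baseline_months}, \code{shock_months} and
#'   \code{resumption_start} (first month of the resumption period,
#'   \code{baseline_months + shock_months + 1}).
#' @examples
#' tl <- study_timeline()
#' tl$resumption_start  # 22
#' month_regime(22, tl) # "resumption"
#' @export
study_timeline <- function(total_months = 24L, baseline_months = 15L,
                           shock_months = 6L) {
  total_months <- as.integer(total_months)
  baseline_months <- as.integer(baseline_months)
  shock_months <- as.integer(shock_months)
  if (total_months < 3L) stop("total_months must be at least 3")
  if (baseline_months < 1L) stop("baseline_months must be positive")
  if (shock_months < 1L) stop("shock_months must be positive")
  if (baseline_months + shock_months >= total_months) {
    stop("baseline_months + shock_months must be < total_months ",
         "(the resumption period needs at least one month)")
  }
  structure(
    list(total_months = total_months,
         baseline_months = baseline_months,
         shock_months = shock_months,
         resumption_start = baseline_months + shock_months + 1L),
    class = "study_timeline"
  )
}

#' @export
print.study_timeline <- function(x, ...) {
  cat("Study timeline (", x$total_months, " months)\n", sep = "")
  cat("  baseline:   months 1-", x$baseline_months, "\n", sep = "")
  cat("  shock:      months ", x$baseline_months + 1L, "-",
      x$baseline_months + x$shock_months, "\n", sep = "")
  cat("  resumption: months ", x$resumption_start, "-", x$total_months,
      "\n", sep = "")
  invisible(x)
}

#' Regime of a study month
#'
#' @param month integer month index (vectorized).
#' @param timeline a [study_timeline()].
#' @return Character vector: \code{"baseline"}, \code{"shock"} or
#'   \code{"resumption"}.
#' @export
month_regime <- function(month, timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  month <- as.integer(month)
  if (any(month < 1L | month > timeline$total_months)) {
    stop("month index outside 1..total_months")
  }
  shock_end <- timeline$baseline_months + timeline$shock_months
  ifelse(month <= timeline$baseline_months, "baseline",
         ifelse(month <= shock_end, "shock", "resumption"))
}

#' Months of the pandemic window
#'
#' All months after the baseline period (shock window plus resumption
#' quarter); with the default timeline, months 16-24, i.e. April-December
#' 2020.
#'
#' @param timeline a [study_timeline()].
#' @return Integer vector of month indices.
#' @export
pandemic_months <- function(timeline) {
  stopifnot(inherits(timeline, "study_timeline"))
  seq.int(timeline$baseline_months + 1L, timeline$total_months)
}

#' Default month-to-season mapping
#'
#' Maps abstract month indices to the four meteorological seasons assuming
#' index 1 is January (Northern-Hemisphere convention): December-February
#' winter, March-May spring, June-August summer, September-November fall.
#' Southern-Hemisphere studies should supply their own mapping; the season
#' assignment is configuration, not fixed code.
#'
#' @param total_months number of months to map (default 24).
#' @param anchor_month calendar month (1-12) of study month 1 (default 1,
#'   January).
#' @return Character vector of length \code{total_months} with values in
#'   \code{c("winter", "spring", "summer", "fall")}, named by month index.
#' @examples
#' default_season_map()[c(1, 4, 7, 10)]
#' @export
default_season_map <- function(total_months = 24L, anchor_month = 1L) {
  total_months <- as.integer(total_months)
  anchor_month <- as.integer(anchor_month)
  stopifnot(total_months >= 1L, anchor_month >= 1L, anchor_month <= 12L)
  cal <- ((anchor_month - 1L + seq_len(total_months) - 1L) %% 12L) + 1L
  seasons <- c("winter", "winter", "spring", "spring", "spring",
               "summer", "summer", "summer", "fall", "fall", "fall",
               "winter")
  out <- seasons[cal]
  names(out) <- seq_len(total_months)
  out
}

check_season_map <- function(season_map, total_months) {
  if (length(season_map) < total_months) {
    stop("season_map must cover months 1..", total_months)
  }
  bad <- setdiff(unique(season_map), c("winter", "spring", "summer", "fall"))
  if (length(bad)) {
    stop("unknown season label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
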