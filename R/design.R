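#' Build the segmented interrupted time series design matrix
#'
#' Encodes the impact model
#' \deqn{Y_{it} = \beta_0 + \beta_1 T + \beta_2 X_t + \beta_3 Z + \beta_4 W
#'   + \beta_5 S + \beta_6 R + \epsilon_{it}}
#' for a single indicator's unit-month panel: \code{T} the month index,
#' \code{X} an indicator of the acute shock window, \code{Z} months since
#' the shock began (1..shock_months inside the window, 0 elsewhere),
#' \code{W} an indicator of the resumption quarter, \code{S} season dummies
#' and \code{R} sub-national-unit dummies.
#'
#' Coding choice for the resumption quarter: \code{X = Z = 0} once
#' \code{W = 1}, so the resumption-level coefficient alone measures the
#' full remaining gap relative to the continued pre-pandemic trend — the
#' quantity the resumption percent-change effect divides by the baseline
#' mean. Reference levels (first season and first unit alphabetically) are
#' dropped for full rank; coefficient values for the dummy blocks, but not
#' fits or effect estimates, depend on that choice.
#'
#' @param panel a [unit_panel()] holding exactly one indicator (or pass
#'   \code{indicator} to select one).
#' @param timeline a [study_timeline()].
#' @param season_map month-to-season mapping covering
#'   \code{1..total_months}; default [default_season_map()].
#' @param indicator indicator to select when the panel has several.
#' @return An object of class \code{its_design}: list with the model
#'   \code{matrix} (columns \code{intercept, trend, covid_level,
#'   covid_slope, resumption_level, season_*, unit_*}), the response
#'   \code{y}, \code{cluster} (unit id per row), \code{month},
#'   \code{coef_group} (which model block each column belongs to), the
#'   panel rows used, the timeline and the season map.
#' @examples
#' m <- generating_model(n_units = 3, facilities_per_unit = 2,
#'                       dispersion = 0)
#' up <- aggregate_to_units(simulate_panel(m))
#' d <- build_design(up, study_timeline())
#' colnames(d$matrix)
#' @export
build_design <- function(panel, timeline = study_timeline(),
                         season_map = NULL, indicator = NULL) {
  panel <- unit_panel(panel)
  stopifnot(inherits(timeline, "study_timeline"))
  if (!is.null(indicator)) panel <- subset_indicator(panel, indicator)
  inds <- unique(panel$indicator)
  if (length(inds) != 1L) {
    stop("panel must hold exactly one indicator (got ",
         length(inds), "); pass `indicator` to select one")
  }
  if (is.null(season_map)) {
    season_map <- default_season_map(timeline$total_months)
  }
  check_season_map(season_map, timeline$total_months)
  if (any(panel$month > timeline$total_months)) {
    stop("panel months exceed timeline$total_months")
  }
  units <- sort(unique(panel$unit_id))
  if (length(units) < 2L) {
    stop("at least 2 sub-national units are required: cluster-robust ",
         "inference uses G-2 degrees of freedom")
  }

  tl <- timeline
  T_ <- panel$month
  X <- as.integer(T_ > tl$baseline_months &
                    T_ <= tl$baseline_months + tl$shock_months)
  Z <- ifelse(X == 1L, T_ - tl$baseline_months, 0L)
  W <- as.integer(T_ >= tl$resumption_start)
  season <- factor(season_map[T_],
                   levels = sort(unique(season_map[seq_len(
                     tl$total_months)])))
  season <- droplevels(season)
  unit <- factor(panel$unit_id, levels = units)

  n <- nrow(panel)
  mat <- cbind(intercept = rep(1, n), trend = as.numeric(T_),
               covid_level = as.numeric(X), covid_slope = as.numeric(Z),
               resumption_level = as.numeric(W))
  group <- c(intercept = "intercept", trend = "trend",
             covid_level = "covid_level", covid_slope = "covid_slope",
             resumption_level = "resumption_level")
  if (nlevels(season) > 1L) {
    sd_ <- stats::model.matrix(~season)[, -1L, drop = FALSE]
    colnames(sd_) <- paste0("season_", levels(season)[-1L])
    mat <- cbind(mat, sd_)
    group <- c(group, stats::setNames(rep("season", ncol(sd_)),
                                      colnames(sd_)))
  }
  ud <- stats::model.matrix(~unit)[, -1L, drop = FALSE]
  colnames(ud) <- paste0("unit_", levels(unit)[-1L])
  mat <- cbind(mat, ud)
  group <- c(group, stats::setNames(rep("unit", ncol(ud)), colnames(ud)))

  qr_ <- qr(mat)
  if (qr_$rank < ncol(mat)) {
    dep <- colnames(mat)[qr_$pivot[seq.int(qr_$rank + 1L, ncol(mat))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }

  structure(list(matrix = mat, y = panel$count,
                 cluster = panel$unit_id, month = T_,
                 coef_group = group, indicator = inds,
                 panel = panel, timeline = tl, season_map = season_map),
            class = "its_design")
}

#' @export
print.its_design <- function(x, ...) {
  cat("ITS design for indicator '", x$indicator, "': ",
      nrow(x$matrix), " unit-month rows, ", ncol(x$matrix),
      " columns, G = ", length(unique(x$cluster)), " units\n", sep = "")
  invisible(x)
}

#' Export a design matrix (plus response and cluster ids) to CSV
#'
#' @param design an [build_design()] result.
#' @param path output CSV path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "its_design"))
  out <- data.frame(unit_id = design$cluster, month = design$month,
                    y = design$y, design$matrix, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
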