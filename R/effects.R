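#' Pre-pandemic baseline mean of unit-month counts
#'
#' Denominator of all percent-change effects: the average unit-month count
#' over the baseline period. The default (\code{mode = "unit_month"}) is
#' the observation-weighted mean over the baseline unit-month records —
#' the same scale on which the regression coefficients are estimated, so
#' numerator and denominator share units. \code{mode = "national_per_unit"}
#' instead averages the national monthly total divided by the number of
#' units; the two coincide on balanced panels and the alternative is kept
#' for display alongside national trend plots.
#'
#' @param panel a [unit_panel()] holding one indicator.
#' @param timeline a [study_timeline()].
#' @param mode denominator convention (see above).
#' @return Positive scalar.
#' @examples
#' up <- unit_panel(data.frame(unit_id = rep(c("a", "b"), each = 3),
#'   indicator = "x", month = rep(1:3, 2), count = c(100, 100, 100,
#'   300, 300, 300), n_facilities = 1L))
#' baseline_mean(up, study_timeline(total_months = 24))  # 200
#' @export
baseline_mean <- function(panel, timeline = study_timeline(),
                          mode = c("unit_month", "national_per_unit")) {
  panel <- unit_panel(panel)
  stopifnot(inherits(timeline, "study_timeline"))
  mode <- match.arg(mode)
  base <- panel[panel$month <= timeline$baseline_months, , drop = FALSE]
  if (!nrow(base)) stop("no baseline observations (months 1..",
                        timeline$baseline_months, ")")
  bm <- if (mode == "unit_month") {
    mean(base$count)
  } else {
    totals <- tapply(base$count, base$month, sum)
    mean(totals) / length(unique(panel$unit_id))
  }
  if (bm <= 0) stop("baseline mean is not positive; percent-change ",
                    "effects are undefined")
  bm
}

#' Percent-change effect estimates relative to the baseline mean
#'
#' The headline quantities of the analysis: the immediate pandemic effect
#' (shock-window level change) and the resumption effect (remaining level
#' change in the final quarter), each expressed as a percentage of the
#' pre-pandemic mean unit-month count. The coefficient and both confidence
#' limits are divided by the (fixed) baseline mean — the baseline mean's
#' own sampling error is ignored — and the p value is carried over from
#' the coefficient's cluster-robust t test unchanged.
#'
#' @param fit an [its_fit()].
#' @param which \code{"immediate"} (shock-window level, beta2) or
#'   \code{"resumption"} (final-quarter level, beta4); coefficient names
#'   \code{"covid_level"} / \code{"resumption_level"} are also accepted.
#' @param baseline_mean positive denominator from [baseline_mean()].
#' @param alpha two-sided level for the transformed CI (default 0.05).
#' @return A one-row data frame of class \code{effect_estimate}: columns
#'   \code{indicator, effect_kind, coefficient, percent_change,
#'   ci_low_pct, ci_high_pct, p_value, baseline_mean}.
#' @examples
#' m <- generating_model(n_units = 4, facilities_per_unit = 5,
#'                       dispersion = 0)
#' up <- aggregate_to_units(simulate_panel(m))
#' fit <- its_fit(up)
#' percent_change(fit, "immediate", baseline_mean(up))
#' @export
percent_change <- function(fit, which = c("immediate", "resumption"),
                           baseline_mean, alpha = 0.05) {
  stopifnot(inherits(fit, "its_fit"))
  which <- match.arg(which[1],
                     c("immediate", "resumption", "covid_level",
                       "resumption_level"))
  term <- switch(which, immediate = , covid_level = "covid_level",
                 resumption = , resumption_level = "resumption_level")
  kind <- if (term == "covid_level") "immediate" else "resumption"
  if (!is.numeric(baseline_mean) || length(baseline_mean) != 1L ||
      baseline_mean <= 0) {
    stop("baseline_mean must be a positive scalar")
  }
  tab <- summary(fit, alpha = alpha)$coefficients
  row <- tab[tab$term == term, ]
  out <- data.frame(indicator = fit$design$indicator, effect_kind = kind,
                    coefficient = row$estimate,
                    percent_change = 100 * row$estimate / baseline_mean,
                    ci_low_pct = 100 * row$ci_low / baseline_mean,
                    ci_high_pct = 100 * row$ci_high / baseline_mean,
                    p_value = row$p_value, baseline_mean = baseline_mean)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Both percent-change effects of a fit, forest-table ready
#'
#' @param fit an [its_fit()].
#' @param baseline_mean denominator from [baseline_mean()].
#' @param alpha two-sided level (default 0.05).
#' @param label optional country/configuration label column.
#' @return Two-row \code{effect_estimate} data frame (immediate and
#'   resumption), the machine-readable twin of a forest plot.
#' @export
effect_table <- function(fit, baseline_mean, alpha = 0.05, label = NA) {
  out <- rbind(percent_change(fit, "immediate", baseline_mean, alpha),
               percent_change(fit, "resumption", baseline_mean, alpha))
  out <- cbind(label = label, out)
  class(out) <- c("effect_estimate", "data.frame")
  out
}
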