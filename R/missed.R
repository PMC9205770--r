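#' Counterfactual unit-month series over the pandemic window
#'
#' For every observed unit-month in the requested months, the prediction
#' of the fitted model with the pandemic terms forced to zero: what
#' service delivery would have been had the pre-pandemic trend continued,
#' adjusted for seasonality and unit composition. Predictions are only
#' produced for unit-months with an observed value (no extrapolation over
#' missing cells), so observed and predicted sums are always
#' like-for-like. Counterfactual predictions are not floored at zero; a
#' negative prediction (possible under a strong negative trend) triggers a
#' warning but is kept, since flooring would bias deficits downward.
#'
#' @param fit an [its_fit()].
#' @param months month indices to predict for; default the full pandemic
#'   window of the fit's timeline. Must lie within the timeline.
#' @return Data frame with columns \code{unit_id, indicator, month,
#'   observed, predicted, deficit} (\code{predicted - observed}).
#' @export
counterfactual_series <- function(fit, months = NULL) {
  stopifnot(inherits(fit, "its_fit"))
  design <- fit$design
  tl <- design$timeline
  if (is.null(months)) months <- pandemic_months(tl)
  months <- as.integer(months)
  if (any(months < 1L | months > tl$total_months)) {
    stop("requested months outside the study timeline (1..",
         tl$total_months, ")")
  }
  keep <- design$month %in% months
  pred <- predict(fit, counterfactual = TRUE)[keep]
  if (any(pred < 0)) {
    warning(sum(pred < 0),
            " negative counterfactual prediction(s); kept unfloored")
  }
  out <- data.frame(unit_id = design$cluster[keep],
                    indicator = design$indicator,
                    month = design$month[keep],
                    observed = design$y[keep], predicted = pred)
  out$deficit <- out$predicted - out$observed
  out <- out[order(out$unit_id, out$month), ]
  rownames(out) <- NULL
  out
}

#' Cumulative missed care over the pandemic window
#'
#' Sums monthly deficits (counterfactual prediction minus observed count,
#' totalled across units) over the window. Negative totals are permitted
#' and meaningful: more care was delivered than the pre-pandemic trend
#' predicted.
#'
#' @param counterfactual output of [counterfactual_series()].
#' @param window month indices to sum over; default all months present in
#'   \code{counterfactual}. Must be a subset of them.
#' @return An object of class \code{missed_care}: list with
#'   \code{indicator}, \code{monthly} (per-month observed, predicted,
#'   deficit totals), \code{total} (cumulative deficit), \code{window},
#'   and \code{excluded = FALSE}.
#' @examples
#' cf <- data.frame(unit_id = "u1", indicator = "anc", month = 16:24,
#'                  observed = 80, predicted = 100, deficit = 20)
#' cumulative_missed(cf)$total  # 180
#' @export
cumulative_missed <- function(counterfactual, window = NULL) {
  need <- c("unit_id", "indicator", "month", "observed", "predicted")
  if (!all(need %in% names(counterfactual))) {
    stop("counterfactual must have columns ",
         paste(need, collapse = ", "))
  }
  if (is.null(window)) window <- sort(unique(counterfactual$month))
  window <- as.integer(window)
  if (!length(window)) stop("window must be non-empty")
  extra <- setdiff(window, counterfactual$month)
  if (length(extra)) {
    stop("window months absent from the counterfactual series: ",
         paste(extra, collapse = ", "))
  }
  cf <- counterfactual[counterfactual$month %in% window, , drop = FALSE]
  monthly <- data.frame(
    month = sort(unique(cf$month)),
    observed = as.numeric(tapply(cf$observed, cf$month, sum)),
    predicted = as.numeric(tapply(cf$predicted, cf$month, sum)))
  monthly$deficit <- monthly$predicted - monthly$observed
  rownames(monthly) <- NULL
  structure(list(indicator = unique(cf$indicator)[1], monthly = monthly,
                 total = sum(monthly$deficit), window = window,
                 excluded = FALSE, rate_per_1000 = NULL,
                 denominator = NULL),
            class = "missed_care")
}

#' @export
print.missed_care <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat("Missed care for '", x$indicator, "': EXCLUDED (",
        x$exclusion_reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Missed care for '", x$indicator, "' over months ",
      min(x$window), "-", max(x$window), ": ",
      format(round(x$total, 1), big.mark = ","), " visits", sep = "")
  if (!is.null(x$rate_per_1000)) {
    cat(" (", round(x$rate_per_1000, 2), " per 1,000 ",
        x$denominator$basis, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Denominator for per-1,000 normalization of missed care
#'
#' Births basis: annual births are estimated as population times crude
#' birth rate per 1,000; maternal/newborn/child deficits are divided by
#' births in thousands. Population basis divides by population in
#' thousands (used for chronic-disease care).
#'
#' @param population total population of the country (or province).
#' @param crude_birth_rate annual births per 1,000 population (required
#'   for the births basis).
#' @param basis \code{"births"} or \code{"population"}.
#' @return An object of class \code{denominator_spec}.
#' @examples
#' denominator_spec(100000, crude_birth_rate = 20)  # 2,000 annual births
#' @export
denominator_spec <- function(population, crude_birth_rate = NULL,
                             basis = c("births", "population")) {
  basis <- match.arg(basis)
  if (!is.numeric(population) || population <= 0) {
    stop("population must be positive")
  }
  if (basis == "births") {
    if (is.null(crude_birth_rate) || crude_birth_rate <= 0) {
      stop("crude_birth_rate must be positive for the births basis")
    }
  }
  structure(list(population = population,
                 crude_birth_rate = crude_birth_rate, basis = basis),
            class = "denominator_spec")
}

#' Normalize a missed-care total per 1,000 births or population
#'
#' @param result a [cumulative_missed()] object (or a grouped result from
#'   [group_services()]).
#' @param denom a [denominator_spec()].
#' @return The result with \code{rate_per_1000} and \code{denominator}
#'   filled in: missed visits per 1,000 annual births
#'   (\code{population * crude_birth_rate / 1000} births) or per 1,000
#'   population.
#' @examples
#' cf <- data.frame(unit_id = "u", indicator = "anc", month = 16,
#'                  observed = 0, predicted = 500, deficit = 500)
#' r <- normalize_missed(cumulative_missed(cf),
#'                       denominator_spec(100000, 20))
#' r$rate_per_1000  # 250
#' @export
normalize_missed <- function(result, denom) {
  stopifnot(inherits(result, "missed_care"),
            inherits(denom, "denominator_spec"))
  if (isTRUE(result$excluded)) return(result)
  thousands <- if (denom$basis == "births") {
    denom$population * denom$crude_birth_rate / 1000 / 1000
  } else {
    denom$population / 1000
  }
  if (thousands <= 0) stop("denominator is zero")
  result$rate_per_1000 <- result$total / thousands
  result$denominator <- denom
  result
}

#' Sum per-indicator missed care into service groups
#'
#' Grouped deficits (for example maternal and newborn care = antenatal +
#' delivery + postnatal) are the sum of member deficits before
#' normalization. A group whose member indicator has no result — for
#' example because cleaning removed the indicator — is marked excluded
#' rather than silently summed over a partial set. A group referencing an
#' indicator outside the known universe is an error.
#'
#' @param results named list of [cumulative_missed()] objects, keyed by
#'   indicator.
#' @param groups named list of character vectors of member indicators.
#' @param universe all indicators that could legitimately appear; default
#'   \code{names(results)}.
#' @return Named list of \code{missed_care} objects, one per group;
#'   excluded groups carry \code{excluded = TRUE} and an
#'   \code{exclusion_reason}.
#' @export
group_services <- function(results, groups, universe = names(results)) {
  if (!length(groups)) stop("groups must be non-empty")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list")
  }
  out <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    if (!length(members)) stop("group '", g, "' is empty")
    unknown <- setdiff(members, universe)
    if (length(unknown)) {
      stop("group '", g, "' references unknown indicator(s): ",
           paste(unknown, collapse = ", "))
    }
    absent <- setdiff(members, names(results))
    if (length(absent)) {
      return(structure(list(indicator = g, monthly = NULL, total = NA_real_,
                            window = NULL, excluded = TRUE,
                            exclusion_reason = paste("missing indicator(s):",
                              paste(absent, collapse = ", ")),
                            rate_per_1000 = NULL, denominator = NULL),
                       class = "missed_care"))
    }
    parts <- results[members]
    months <- sort(unique(unlist(lapply(parts, function(p)
      p$monthly$month))))
    monthly <- data.frame(month = months, observed = 0, predicted = 0)
    for (p in parts) {
      i <- match(p$monthly$month, monthly$month)
      monthly$observed[i] <- monthly$observed[i] + p$monthly$observed
      monthly$predicted[i] <- monthly$predicted[i] + p$monthly$predicted
    }
    monthly$deficit <- monthly$predicted - monthly$observed
    structure(list(indicator = g, members = members, monthly = monthly,
                   total = sum(vapply(parts, `[[`, numeric(1), "total")),
                   window = sort(unique(unlist(lapply(parts, `[[`,
                                                      "window")))),
                   excluded = FALSE, rate_per_1000 = NULL,
                   denominator = NULL),
              class = "missed_care")
  })
  stats::setNames(out, names(groups))
}

missed_summary_row <- function(x, label) {
  data.frame(group = label,
             total_missed = x$total,
             rate_per_1000 = if (is.null(x$rate_per_1000)) NA_real_ else
               x$rate_per_1000,
             basis = if (is.null(x$denominator)) NA_character_ else
               x$denominator$basis,
             excluded = isTRUE(x$excluded))
}
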