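#' Generating model for synthetic facility-month count panels
#'
#' Describes a ground-truth segmented time-series process at facility level.
#' The expected count of a facility in unit \eqn{i} at month \eqn{t} is the
#' linear predictor
#' \deqn{\mu_{it} = \beta_0 + \beta_1 T + \beta_2 X_t + \beta_3 Z + \beta_4 W
#'   + season(t) + unit_i}
#' where \eqn{T} is the month index, \eqn{X_t} indicates the acute shock
#' window, \eqn{Z} counts months since the shock began (0 outside the
#' window), and \eqn{W} indicates the resumption quarter — exactly the
#' design encoded by [build_design()], so the generator and the fitted
#' model share one estimand. Counts are drawn with negative-binomial (NB2)
#' noise, \eqn{Var = \mu + \phi\mu^2}; \code{dispersion = 0} switches the
#' noise off entirely (counts are the rounded linear predictor), which is
#' what every exact-recovery test uses.
#'
#' Defaults describe a realistic mid-sized country panel: 10 sub-national
#' units of 20 facilities each averaging 100 visits/month, a slight upward
#' pre-pandemic trend, a 30-visit (30\%) immediate pandemic drop with
#' partial within-window recovery, a 10-visit remaining deficit in the
#' resumption quarter, a modest seasonal cycle, and unit-level
#' heterogeneity.
#'
#' @param n_units number of sub-national units.
#' @param facilities_per_unit facilities per unit.
#' @param timeline a [study_timeline()].
#' @param beta0 baseline expected count per facility-month.
#' @param beta1 pre-pandemic monthly trend per facility.
#' @param beta2 pandemic level change per facility (shock window).
#' @param beta3 monthly slope change during the shock window.
#' @param beta4 remaining level change in the resumption quarter.
#' @param season_effects additive offsets named
#'   \code{winter, spring, summer, fall}.
#' @param unit_effects additive per-unit offsets, length \code{n_units}.
#' @param dispersion NB2 overdispersion \eqn{\phi} (\code{0} = noiseless).
#' @param family noise family when \code{dispersion > 0}:
#'   \code{"nbinom"} (default) or \code{"poisson"} (ignores
#'   \code{dispersion}'s magnitude beyond being positive).
#' @param indicator indicator label stamped on every record.
#' @param season_map month-to-season mapping (default
#'   [default_season_map()]).
#' @param seed integer RNG seed; identical models give byte-identical
#'   panels.
#' @return An object of class \code{generating_model}.
#' @seealso [simulate_panel()], [corrupt_panel()]
#' @export
generating_model <- function(n_units = 10L, facilities_per_unit = 20L,
                             timeline = study_timeline(),
                             beta0 = 100, beta1 = 0.5, beta2 = -30,
                             beta3 = 3, beta4 = -10,
                             season_effects = c(winter = -8, spring = 0,
                                                summer = 8, fall = 0),
                             unit_effects = NULL,
                             dispersion = 0.05,
                             family = c("nbinom", "poisson"),
                             indicator = "service",
                             season_map = NULL,
                             seed = 1L) {
  stopifnot(inherits(timeline, "study_timeline"))
  n_units <- as.integer(n_units)
  facilities_per_unit <- as.integer(facilities_per_unit)
  if (n_units < 1L) stop("n_units must be positive")
  if (facilities_per_unit < 1L) stop("facilities_per_unit must be positive")
  family <- match.arg(family)
  if (length(season_effects) != 4L) {
    stop("season_effects must have exactly 4 entries")
  }
  if (is.null(names(season_effects))) {
    names(season_effects) <- c("winter", "spring", "summer", "fall")
  }
  if (!setequal(names(season_effects),
                c("winter", "spring", "summer", "fall"))) {
    stop("season_effects must be named winter, spring, summer, fall")
  }
  if (is.null(unit_effects)) {
    unit_effects <- if (n_units == 1L) 0 else
      seq(-0.2 * beta0, 0.2 * beta0, length.out = n_units)
  }
  if (length(unit_effects) != n_units) {
    stop("unit_effects must have length n_units")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (is.null(season_map)) {
    season_map <- default_season_map(timeline$total_months)
  }
  check_season_map(season_map, timeline$total_months)
  model <- structure(
    list(n_units = n_units, facilities_per_unit = facilities_per_unit,
         timeline = timeline, beta0 = beta0, beta1 = beta1, beta2 = beta2,
         beta3 = beta3, beta4 = beta4,
         season_effects = season_effects,
         unit_effects = as.numeric(unit_effects),
         dispersion = dispersion, family = family,
         indicator = indicator, season_map = season_map,
         seed = as.integer(seed)),
    class = "generating_model")
  # every unit-season cell must start with a positive expected count
  m1 <- min(outer(model$unit_effects, model$season_effects, `+`)) +
    beta0 + beta1
  if (m1 <= 0) {
    stop("expected count at month 1 is non-positive for some unit-season ",
         "combination; adjust beta0 / season_effects / unit_effects")
  }
  model
}

#' @export
print.generating_model <- function(x, ...) {
  cat("Generating model: ", x$n_units, " units x ", x$facilities_per_unit,
      " facilities x ", x$timeline$total_months, " months (indicator '",
      x$indicator, "')\n", sep = "")
  cat(sprintf("  beta0=%g beta1=%g beta2=%g beta3=%g beta4=%g\n",
              x$beta0, x$beta1, x$beta2, x$beta3, x$beta4))
  cat(sprintf("  dispersion=%g (%s), seed=%d\n", x$dispersion,
              if (x$dispersion == 0) "noiseless" else x$family, x$seed))
  invisible(x)
}

# run `code` under `seed`, leaving the caller's RNG stream untouched
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# linear predictor per facility-month for a generating model; returns the
# complete grid with mu
model_grid <- function(model) {
  tl <- model$timeline
  months <- seq_len(tl$total_months)
  X <- as.integer(months > tl$baseline_months &
                    months <= tl$baseline_months + tl$shock_months)
  Z <- ifelse(X == 1L, months - tl$baseline_months, 0L)
  W <- as.integer(months >= tl$resumption_start)
  season <- model$season_map[months]
  month_part <- model$beta0 + model$beta1 * months + model$beta2 * X +
    model$beta3 * Z + model$beta4 * W +
    unname(model$season_effects[season])

  unit_ids <- sprintf("unit%02d", seq_len(model$n_units))
  n_fac <- model$n_units * model$facilities_per_unit
  facility_id <- sprintf("fac%04d", seq_len(n_fac))
  unit_of_fac <- rep(unit_ids, each = model$facilities_per_unit)
  eff_of_fac <- rep(model$unit_effects, each = model$facilities_per_unit)

  grid <- data.frame(
    facility_id = rep(facility_id, each = tl$total_months),
    unit_id = rep(unit_of_fac, each = tl$total_months),
    indicator = model$indicator,
    month = rep(months, times = n_fac),
    mu = rep(eff_of_fac, each = tl$total_months) +
      rep(month_part, times = n_fac),
    stringsAsFactors = FALSE
  )
  grid
}

#' Simulate a facility-month count panel from a generating model
#'
#' Runs the segmented impact model forward with overdispersed count noise:
#' one record per facility per month \code{1..total_months}. A negative
#' linear predictor at any cell is a configuration error (named in the
#' message), never silently clipped; the count draws themselves are
#' non-negative by construction.
#'
#' @param model a [generating_model()].
#' @return A [facility_panel()] with an attribute \code{"model"} holding
#'   the generating parameters.
#' @examples
#' m <- generating_model(n_units = 2, facilities_per_unit = 3,
#'                       dispersion = 0, beta1 = 0, beta2 = 0, beta3 = 0,
#'                       beta4 = 0, season_effects = c(winter = 0,
#'                       spring = 0, summer = 0, fall = 0),
#'                       unit_effects = c(0, 0))
#' unique(simulate_panel(m)$count)  # all 100
#' @export
simulate_panel <- function(model) {
  stopifnot(inherits(model, "generating_model"))
  grid <- model_grid(model)
  if (any(grid$mu < 0)) {
    bad <- grid[which.min(grid$mu), ]
    stop(sprintf(
      "negative expected count (%.3f) at facility %s, month %d; %s",
      bad$mu, bad$facility_id, bad$month,
      "the generating parameters are inconsistent"))
  }
  n <- nrow(grid)
  counts <- if (model$dispersion == 0) {
    round(grid$mu)
  } else if (model$family == "poisson") {
    with_preserved_seed(model$seed, stats::rpois(n, lambda = grid$mu))
  } else {
    with_preserved_seed(model$seed,
      stats::rnbinom(n, mu = grid$mu, size = 1 / model$dispersion))
  }
  out <- facility_panel(data.frame(
    facility_id = grid$facility_id, unit_id = grid$unit_id,
    indicator = grid$indicator, month = grid$month,
    count = as.numeric(counts)))
  attr(out, "model") <- model
  out
}

#' Corruption process emulating RHIS reporting-quality threats
#'
#' Two threats the cleaning step must correct: facility-months that are
#' never reported (dropout, optionally intensified during the pandemic,
#' when reporting effort competes with the response), and reported values
#' replaced by implausibly high entries (data-entry errors).
#'
#' @param dropout_rate probability a facility-month report is missing.
#' @param pandemic_dropout_multiplier factor (>= 1) applied to the dropout
#'   probability in pandemic months; the product is capped at 1.
#' @param outlier_rate probability a surviving report is replaced by an
#'   extreme high value.
#' @param outlier_scale multiplier of the facility mean defining "extreme".
#' @param seed integer RNG seed.
#' @return An object of class \code{corruption_spec}.
#' @export
corruption_spec <- function(dropout_rate = 0.08,
                            pandemic_dropout_multiplier = 1.5,
                            outlier_rate = 0.01, outlier_scale = 5,
                            seed = 1L) {
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("dropout_rate must be in [0, 1]")
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop("outlier_rate must be in [0, 1]")
  }
  if (pandemic_dropout_multiplier < 1) {
    stop("pandemic_dropout_multiplier must be >= 1")
  }
  if (outlier_scale <= 0) stop("outlier_scale must be positive")
  structure(list(dropout_rate = dropout_rate,
                 pandemic_dropout_multiplier = pandemic_dropout_multiplier,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale,
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Apply a corruption process to a facility panel
#'
#' Returns a copy of the panel with some records removed (missing reports)
#' and some counts replaced by \code{outlier_scale} times the facility's
#' own pre-corruption mean. Every altered cell is recorded in the
#' \code{"corruption_log"} attribute (columns: facility_id, unit_id,
#' indicator, month, action, original, new).
#'
#' @param panel a [facility_panel()].
#' @param spec a [corruption_spec()].
#' @param timeline a [study_timeline()]; defines which months count as
#'   pandemic months for the dropout multiplier.
#' @return A corrupted [facility_panel()].
#' @export
corrupt_panel <- function(panel, spec, timeline = study_timeline()) {
  model <- attr(panel, "model")
  panel <- facility_panel(panel)
  stopifnot(inherits(spec, "corruption_spec"),
            inherits(timeline, "study_timeline"))
  if (!nrow(panel)) stop("cannot corrupt an empty panel")

  n <- nrow(panel)
  p_drop <- pmin(1, spec$dropout_rate *
                   ifelse(panel$month > timeline$baseline_months,
                          spec$pandemic_dropout_multiplier, 1))
  fkey <- paste(panel$facility_id, panel$indicator)
  fac_mean <- tapply(panel$count, fkey, mean)

  draws <- with_preserved_seed(spec$seed, {
    list(drop = stats::runif(n) < p_drop,
         outlier = stats::runif(n) < spec$outlier_rate)
  })
  drop <- draws$drop
  outlier <- draws$outlier & !drop

  log_rows <- function(sel, action, new) {
    data.frame(facility_id = panel$facility_id[sel],
               unit_id = panel$unit_id[sel],
               indicator = panel$indicator[sel],
               month = panel$month[sel],
               action = rep_len(action, sum(sel)),
               original = panel$count[sel],
               new = rep_len(new, sum(sel)))
  }
  log <- rbind(
    log_rows(drop, "dropped", NA_real_),
    log_rows(outlier, "outlier",
             if (any(outlier)) round(spec$outlier_scale *
               as.numeric(fac_mean[fkey[outlier]])) else numeric(0)))

  panel$count[outlier] <- round(spec$outlier_scale *
                                  as.numeric(fac_mean[fkey[outlier]]))
  out <- facility_panel(panel[!drop, , drop = FALSE])
  rownames(log) <- NULL
  attr(out, "corruption_log") <- log
  attr(out, "model") <- model
  out
}

#' Write the generating parameters as a JSON sidecar
#'
#' Companion file for a simulated panel CSV, recording every generating
#' parameter and the seed so any panel can be regenerated exactly.
#'
#' @param model a [generating_model()].
#' @param path output JSON path.
#' @export
write_model_sidecar <- function(model, path) {
  stopifnot(inherits(model, "generating_model"))
  x <- model
  x$timeline <- unclass(x$timeline)
  x$season_map <- as.list(x$season_map)
  class(x) <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
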