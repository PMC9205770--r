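#' End-to-end run configuration
#'
#' A single declarative object driving the whole pipeline: input source
#' (a facility-panel CSV or a list of synthetic generating models with an
#' optional corruption process), cleaning configuration, study timeline,
#' season mapping, service groupings with per-group denominators, an
#' optional sub-national unit subset (for metropolitan-region
#' sub-analyses), the significance level and the RNG seed. All the
#' analysis defaults (15/24-month completeness, 3.5 SD outlier rule,
#' 6-month shock window, final-quarter resumption, alpha 0.05) are the
#' config defaults.
#'
#' When \code{seed} is non-NULL it overrides the seeds of the synthetic
#' models (model \code{i} gets \code{seed + i - 1}) and of the corruption
#' process (\code{seed + 1000}), so one integer reproduces a full run.
#'
#' @param input either \code{list(csv = "path")} or
#'   \code{list(models = list(<generating_model>, ...),
#'   corruption = <corruption_spec> or NULL)}.
#' @param cleaning a [cleaning_config()].
#' @param timeline a [study_timeline()].
#' @param season_map month-to-season map; default [default_season_map()].
#' @param groups named list of indicator groupings for missed-care totals.
#' @param denominators named list of [denominator_spec()] keyed by group.
#' @param unit_subset optional character vector of unit ids to restrict
#'   the analysis to.
#' @param alpha two-sided significance level.
#' @param baseline_mean_mode denominator convention, see [baseline_mean()].
#' @param output_dir directory for run artifacts (created on demand).
#' @param seed integer master seed (see above), or NULL to keep the
#'   models' own seeds.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(input, cleaning = cleaning_config(),
                       timeline = study_timeline(), season_map = NULL,
                       groups = NULL, denominators = NULL,
                       unit_subset = NULL, alpha = 0.05,
                       baseline_mean_mode = "unit_month",
                       output_dir = tempfile("rhisits_run"), seed = 1L) {
  if (is.null(input) ||
      sum(!is.null(input$csv), !is.null(input$models)) != 1L) {
    stop("input must name exactly one source: csv= or models=")
  }
  stopifnot(inherits(cleaning, "cleaning_config"),
            inherits(timeline, "study_timeline"))
  if (is.null(season_map)) {
    season_map <- default_season_map(timeline$total_months)
  }
  check_season_map(season_map, timeline$total_months)
  if (!is.null(input$models)) {
    ok <- vapply(input$models, inherits, logical(1), "generating_model")
    if (!all(ok)) stop("input$models must be generating_model objects")
    inds <- vapply(input$models, `[[`, character(1), "indicator")
    if (anyDuplicated(inds)) stop("duplicate indicator among input models")
    if (!is.null(input$corruption)) {
      stopifnot(inherits(input$corruption, "corruption_spec"))
    }
  }
  if (!is.null(groups)) {
    if (is.null(names(groups))) stop("groups must be a named list")
    if (!is.null(denominators)) {
      ok <- vapply(denominators, inherits, logical(1), "denominator_spec")
      if (!all(ok)) stop("denominators must be denominator_spec objects")
      extra <- setdiff(names(denominators), names(groups))
      if (length(extra)) {
        stop("denominator(s) for unknown group(s): ",
             paste(extra, collapse = ", "))
      }
    }
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(input = input, cleaning = cleaning, timeline = timeline,
                 season_map = season_map, groups = groups,
                 denominators = denominators, unit_subset = unit_subset,
                 alpha = alpha, baseline_mean_mode = baseline_mean_mode,
                 output_dir = output_dir,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

stage <- function(name, indicator = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "'",
         if (!is.null(indicator)) paste0(" (indicator '", indicator, "')"),
         " failed: ", conditionMessage(e), call. = FALSE)
  })
}

acquire_panel <- function(config) {
  if (!is.null(config$input$csv)) {
    return(read_facility_panel(config$input$csv))
  }
  models <- config$input$models
  if (!is.null(config$seed)) {
    for (i in seq_along(models)) {
      models[[i]]$seed <- config$seed + i - 1L
    }
  }
  panel <- do.call(rbind, lapply(models, function(m) {
    as.data.frame(simulate_panel(m))
  }))
  panel <- facility_panel(panel)
  if (!is.null(config$input$corruption)) {
    cor <- config$input$corruption
    if (!is.null(config$seed)) cor$seed <- config$seed + 1000L
    panel <- corrupt_panel(panel, cor, config$timeline)
  }
  panel
}

# all pipeline stages, in memory; run_pipeline() adds the file outputs
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tl <- config$timeline

  raw <- stage("input", NULL, acquire_panel(config))
  log <- data.frame(stage = "input", records_in = NA_integer_,
                    records_out = nrow(raw))

  cleaned <- stage("cleaning", NULL, clean_panel(raw, config$cleaning))
  log <- rbind(log, data.frame(stage = "cleaning", records_in = nrow(raw),
                               records_out = nrow(cleaned$panel)))

  panel <- cleaned$panel
  if (!is.null(config$unit_subset)) {
    missing_units <- setdiff(config$unit_subset, unique(panel$unit_id))
    if (length(missing_units)) {
      stop("unit_subset names unknown unit(s): ",
           paste(missing_units, collapse = ", "))
    }
    keep <- panel$unit_id %in% config$unit_subset
    panel <- facility_panel(panel[keep, , drop = FALSE])
    log <- rbind(log, data.frame(stage = "unit_subset",
                                 records_in = nrow(cleaned$panel),
                                 records_out = nrow(panel)))
  }

  units <- stage("aggregation", NULL, aggregate_to_units(panel))
  log <- rbind(log, data.frame(stage = "aggregation",
                               records_in = nrow(panel),
                               records_out = nrow(units)))

  indicators <- panel_indicators(units)
  fits <- list(); effects <- NULL; missed <- list(); cf_all <- NULL
  for (ind in indicators) {
    up <- subset_indicator(units, ind)
    fit <- stage("fit", ind,
                 its_fit(up, timeline = tl,
                         season_map = config$season_map))
    bm <- stage("effects", ind,
                baseline_mean(up, tl, mode = config$baseline_mean_mode))
    eff <- stage("effects", ind, effect_table(fit, bm, config$alpha))
    cf <- stage("missed_care", ind, counterfactual_series(fit))
    missed[[ind]] <- stage("missed_care", ind, cumulative_missed(cf))
    fits[[ind]] <- fit
    effects <- rbind(effects, eff)
    cf_all <- rbind(cf_all, cf)
  }

  grouped <- NULL
  if (!is.null(config$groups)) {
    universe <- if (!is.null(config$input$models)) {
      vapply(config$input$models, `[[`, character(1), "indicator")
    } else {
      union(panel_indicators(raw), indicators)
    }
    grouped <- stage("missed_care", NULL,
                     group_services(missed, config$groups, universe))
    if (!is.null(config$denominators)) {
      for (g in names(config$denominators)) {
        grouped[[g]] <- normalize_missed(grouped[[g]],
                                         config$denominators[[g]])
      }
    }
  }

  structure(list(config = config, raw_panel = raw,
                 cleaned_panel = panel, cleaning_report = cleaned$report,
                 unit_panel = units, fits = fits, effects = effects,
                 counterfactual = cf_all, missed = missed,
                 grouped_missed = grouped, stage_log = log),
            class = "run_artifacts")
}

#' Run the full disruption-analysis pipeline
#'
#' Stages, in order: input acquisition (CSV or synthetic generation with
#' optional corruption), two-step cleaning, optional unit subsetting,
#' aggregation to sub-national units, per-indicator segmented ITS fits,
#' percent-change effect estimates, counterfactual missed-care totals with
#' grouping and per-1,000 normalization, and file outputs. Any stage
#' failure aborts with the stage name and the offending indicator. With a
#' fixed seed, two runs produce byte-identical artifacts.
#'
#' Files written to \code{config$output_dir}: \code{cleaned_panel.csv},
#' the cleaning report tables, \code{unit_panel.csv},
#' \code{coefficients.csv}, \code{effects.csv},
#' \code{missed_monthly.csv}, \code{missed_summary.csv},
#' \code{trend_data.csv} (observed, segmented-fit and counterfactual
#' national totals per month), \code{stage_log.csv} and
#' \code{manifest.json} (config, seed, package version).
#'
#' @param config a [run_config()].
#' @return Invisibly, a \code{run_artifacts} list holding every
#'   intermediate object (panels, fits, effect and missed-care tables,
#'   cleaning report, stage log).
#' @export
run_pipeline <- function(config) {
  art <- run_analysis(config)
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  write_facility_panel(art$cleaned_panel, file.path(dir,
                                                    "cleaned_panel.csv"))
  write_cleaning_report(art$cleaning_report, dir)
  write_unit_panel(art$unit_panel, file.path(dir, "unit_panel.csv"))

  coefs <- do.call(rbind, lapply(names(art$fits), function(ind) {
    tab <- summary(art$fits[[ind]], alpha = config$alpha)$coefficients
    cbind(indicator = ind, tab)
  }))
  utils::write.csv(coefs, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(art$effects, file.path(dir, "effects.csv"),
                   row.names = FALSE)

  monthly <- do.call(rbind, lapply(names(art$missed), function(ind) {
    cbind(indicator = ind, art$missed[[ind]]$monthly)
  }))
  utils::write.csv(monthly, file.path(dir, "missed_monthly.csv"),
                   row.names = FALSE)

  rows <- lapply(names(art$missed), function(ind)
    missed_summary_row(art$missed[[ind]], ind))
  if (!is.null(art$grouped_missed)) {
    rows <- c(rows, lapply(names(art$grouped_missed), function(g)
      missed_summary_row(art$grouped_missed[[g]], g)))
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(dir, "missed_summary.csv"), row.names = FALSE)

  trend <- do.call(rbind, lapply(names(art$fits), function(ind) {
    fit <- art$fits[[ind]]
    d <- fit$design
    months <- sort(unique(d$month))
    data.frame(indicator = ind, month = months,
               observed = as.numeric(rowsum(d$y, d$month)[
                 as.character(months), ]),
               fitted = as.numeric(rowsum(fit$fitted.values, d$month)[
                 as.character(months), ]),
               counterfactual = as.numeric(rowsum(
                 predict(fit, counterfactual = TRUE), d$month)[
                   as.character(months), ]))
  }))
  utils::write.csv(trend, file.path(dir, "trend_data.csv"),
                   row.names = FALSE)
  utils::write.csv(art$stage_log, file.path(dir, "stage_log.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "rhisits",
    version = as.character(utils::packageVersion("rhisits")),
    seed = config$seed,
    alpha = config$alpha,
    timeline = unclass(config$timeline),
    cleaning = unclass(config$cleaning),
    baseline_mean_mode = config$baseline_mean_mode,
    unit_subset = config$unit_subset,
    groups = config$groups,
    input = if (!is.null(config$input$csv)) {
      list(kind = "csv", path = config$input$csv)
    } else {
      list(kind = "synthetic",
           indicators = vapply(config$input$models, `[[`, character(1),
                               "indicator"),
           corrupted = !is.null(config$input$corruption))
    })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(art)
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat("Pipeline run:", length(x$fits), "indicator(s),",
      nrow(x$unit_panel), "unit-month records\n")
  print(x$stage_log, row.names = FALSE)
  invisible(x)
}

#' Sensitivity of effect estimates to the completeness threshold
#'
#' Reruns the full pipeline at each completeness threshold and lays the
#' effect estimates side by side, together with the number of
#' facility-indicator series retained (non-increasing in the threshold).
#'
#' @param config a [run_config()].
#' @param thresholds integer vector of \code{min_months_reported} values
#'   (default \code{c(12, 15, 18, total_months)}).
#' @return Data frame: one row per threshold x indicator x effect kind,
#'   with percent-change estimate, CI, p value and series retained.
#' @export
threshold_sensitivity <- function(config, thresholds = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(thresholds)) {
    thresholds <- unique(c(12L, 15L, 18L, config$cleaning$total_months))
  }
  thresholds <- as.integer(thresholds)
  if (!length(thresholds)) stop("thresholds must be non-empty")
  if (any(thresholds < 1L | thresholds > config$cleaning$total_months)) {
    stop("thresholds must lie in 1..total_months")
  }
  out <- NULL
  for (th in thresholds) {
    cfg <- config
    cfg$cleaning$min_months_reported <- th
    art <- run_analysis(cfg)
    retained <- sum(art$cleaning_report$exclusions$retained)
    eff <- art$effects
    out <- rbind(out, cbind(threshold = th, series_retained = retained,
                            eff))
  }
  rownames(out) <- NULL
  out
}
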