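#' Configuration of the two-step facility-level cleaning procedure
#'
#' Step 1 keeps, per indicator, only facilities that reported at least
#' \code{min_months_reported} of the \code{total_months} study months
#' (boundary inclusive: a facility at exactly the threshold is retained; a
#' reported zero counts as reported). Step 2 sets to missing any count more
#' than \code{outlier_z} standard deviations *above* the facility's own
#' mean; low values are kept by default, since service use may genuinely
#' collapse during a pandemic and removing low outliers would erase the
#' signal under study.
#'
#' @param min_months_reported completeness threshold (default 15).
#' @param total_months study length in months (default 24).
#' @param outlier_z standard-deviation multiple for the high-outlier rule
#'   (default 3.5).
#' @param remove_low_outliers also drop counts below
#'   \code{mean - outlier_z * sd} (default \code{FALSE}).
#' @param iterate_outliers recompute facility mean/sd and re-flag until no
#'   new outliers emerge (default \code{FALSE}: a single pass).
#' @return An object of class \code{cleaning_config}.
#' @export
cleaning_config <- function(min_months_reported = 15L, total_months = 24L,
                            outlier_z = 3.5, remove_low_outliers = FALSE,
                            iterate_outliers = FALSE) {
  min_months_reported <- as.integer(min_months_reported)
  total_months <- as.integer(total_months)
  if (min_months_reported < 1L || min_months_reported > total_months) {
    stop("min_months_reported must be in 1..total_months")
  }
  if (outlier_z <= 0) stop("outlier_z must be positive")
  structure(list(min_months_reported = min_months_reported,
                 total_months = total_months, outlier_z = outlier_z,
                 remove_low_outliers = isTRUE(remove_low_outliers),
                 iterate_outliers = isTRUE(iterate_outliers)),
            class = "cleaning_config")
}

empty_outlier_log <- function() {
  data.frame(facility_id = character(), unit_id = character(),
             indicator = character(), month = integer(),
             count = numeric(), facility_mean = numeric(),
             facility_sd = numeric(), z = numeric())
}

#' Completeness filter: drop under-reporting facilities
#'
#' Per indicator, retains only facilities with at least
#' \code{config$min_months_reported} reported (non-missing) months out of
#' the study period. Guards against mistaking reporting gaps for true
#' service declines, the main bias threat when the event under study also
#' disrupts reporting.
#'
#' @param panel a [facility_panel()].
#' @param config a [cleaning_config()].
#' @return List with elements \code{panel} (filtered) and \code{report}, a
#'   \code{cleaning_report} whose \code{exclusions} table lists every
#'   facility-indicator with its months reported and retention decision.
#' @export
filter_reporting_completeness <- function(panel, config = cleaning_config()) {
  panel <- facility_panel(panel)
  stopifnot(inherits(config, "cleaning_config"))
  if (nrow(panel) && any(panel$month > config$total_months)) {
    stop("panel has month indices beyond config$total_months")
  }
  if (!nrow(panel)) {
    return(list(panel = panel, report = cleaning_report(
      exclusions = data.frame(indicator = character(),
                              facility_id = character(),
                              months_reported = integer(),
                              retained = logical()))))
  }
  key <- paste(panel$indicator, panel$facility_id, sep = "\r")
  months <- tapply(panel$month, key, length)
  keys <- names(months)
  split_at <- regexpr("\r", keys, fixed = TRUE)
  excl <- data.frame(
    indicator = substr(keys, 1L, split_at - 1L),
    facility_id = substring(keys, split_at + 1L),
    months_reported = as.integer(months),
    retained = as.integer(months) >= config$min_months_reported)
  excl <- excl[order(excl$indicator, excl$facility_id), ]
  rownames(excl) <- NULL

  keep <- excl$retained[match(key, keys)]
  out <- facility_panel(panel[keep, , drop = FALSE])

  gone <- setdiff(unique(panel$indicator), unique(out$indicator))
  if (length(gone)) {
    warning("completeness filter removed every facility for indicator(s): ",
            paste(gone, collapse = ", "))
  }
  list(panel = out, report = cleaning_report(exclusions = excl))
}

flag_once <- function(panel, config) {
  key <- paste(panel$indicator, panel$facility_id, sep = "\r")
  m <- tapply(panel$count, key, mean)
  s <- tapply(panel$count, key, stats::sd)
  fm <- as.numeric(m[key])
  fs <- as.numeric(s[key])
  hi <- !is.na(fs) & fs > 0 & panel$count > fm + config$outlier_z * fs
  lo <- if (config$remove_low_outliers) {
    !is.na(fs) & fs > 0 & panel$count < fm - config$outlier_z * fs
  } else rep(FALSE, nrow(panel))
  flag <- hi | lo
  log <- data.frame(facility_id = panel$facility_id[flag],
                    unit_id = panel$unit_id[flag],
                    indicator = panel$indicator[flag],
                    month = panel$month[flag],
                    count = panel$count[flag],
                    facility_mean = fm[flag], facility_sd = fs[flag],
                    z = (panel$count[flag] - fm[flag]) / fs[flag])
  list(panel = facility_panel(panel[!flag, , drop = FALSE]), log = log)
}

#' High-outlier rule: set extreme counts to missing
#'
#' For each facility-indicator series, computes the mean and standard
#' deviation over its reported months and sets to missing every count
#' strictly greater than \code{mean + outlier_z * sd}. Statistics include
#' the candidate point itself (no leave-one-out masking), and flagging is a
#' single pass unless \code{iterate_outliers} is set. A constant series
#' (sd = 0) flags nothing. Counts below \code{mean - outlier_z * sd} are
#' retained unless \code{remove_low_outliers}.
#'
#' Apply after [filter_reporting_completeness()]; order matters because the
#' outlier statistics should not be computed on facilities about to be
#' dropped.
#'
#' @param panel a completeness-filtered [facility_panel()].
#' @param config a [cleaning_config()].
#' @return List with \code{panel} (flagged cells removed) and
#'   \code{report}, whose \code{outliers} table records every flagged cell
#'   with its original value, facility mean/sd and z-score.
#' @export
flag_high_outliers <- function(panel, config = cleaning_config()) {
  panel <- facility_panel(panel)
  stopifnot(inherits(config, "cleaning_config"))
  if (!nrow(panel)) {
    return(list(panel = panel,
                report = cleaning_report(outliers = empty_outlier_log())))
  }
  log <- empty_outlier_log()
  repeat {
    step <- flag_once(panel, config)
    log <- rbind(log, step$log)
    panel <- step$panel
    if (!config$iterate_outliers || nrow(step$log) == 0L || !nrow(panel)) {
      break
    }
  }
  rownames(log) <- NULL
  list(panel = panel, report = cleaning_report(outliers = log))
}

#' Raw-versus-cleaned retention audit
#'
#' Compares the total of each indicator before and after cleaning so that
#' an over-aggressive filter (a cleaned/raw ratio far below 1) is visible,
#' and tabulates facilities reporting per month in the cleaned panel so
#' stability of the reporting denominator can be checked.
#'
#' @param raw the panel before cleaning.
#' @param cleaned the panel after cleaning.
#' @return A \code{cleaning_report} with \code{retention} (per-indicator
#'   raw sum, cleaned sum, ratio in (0, 1], \code{undefined_ratio} flag
#'   when the raw sum is zero) and \code{monthly_reporting} (facilities
#'   reporting per indicator-month in the cleaned panel).
#' @export
audit_retention <- function(raw, cleaned) {
  raw <- facility_panel(raw)
  cleaned <- facility_panel(cleaned)
  inds <- panel_indicators(raw)
  if (!setequal(inds, panel_indicators(cleaned))) {
    # indicators can disappear entirely; keep the union so the audit shows it
    inds <- sort(union(inds, panel_indicators(cleaned)))
  }
  raw_sum <- vapply(inds, function(i) sum(raw$count[raw$indicator == i]),
                    numeric(1))
  cl_sum <- vapply(inds, function(i)
    sum(cleaned$count[cleaned$indicator == i]), numeric(1))
  retention <- data.frame(indicator = inds, raw_sum = raw_sum,
                          cleaned_sum = cl_sum,
                          ratio = ifelse(raw_sum > 0, cl_sum / raw_sum,
                                         NA_real_),
                          undefined_ratio = raw_sum == 0)
  rownames(retention) <- NULL

  if (nrow(cleaned)) {
    key <- interaction(cleaned$indicator, cleaned$month, drop = TRUE)
    n <- tapply(cleaned$facility_id, key, length)
    first <- !duplicated(key)
    monthly <- data.frame(indicator = cleaned$indicator[first],
                          month = cleaned$month[first],
                          n_facilities = as.integer(n[as.character(
                            key[first])]))
    monthly <- monthly[order(monthly$indicator, monthly$month), ]
    rownames(monthly) <- NULL
  } else {
    monthly <- data.frame(indicator = character(), month = integer(),
                          n_facilities = integer())
  }
  cleaning_report(retention = retention, monthly_reporting = monthly)
}

#' Run the full two-step cleaning procedure
#'
#' Completeness filter, then high-outlier flagging, then the retention
#' audit against the raw input, in that order.
#'
#' @param panel a raw [facility_panel()].
#' @param config a [cleaning_config()].
#' @return List with \code{panel} (cleaned) and \code{report} (a merged
#'   \code{cleaning_report} with exclusions, outliers, retention and
#'   monthly reporting tables).
#' @examples
#' m <- generating_model(n_units = 2, facilities_per_unit = 4)
#' res <- clean_panel(simulate_panel(m))
#' res$report
#' @export
clean_panel <- function(panel, config = cleaning_config()) {
  panel <- facility_panel(panel)
  s1 <- filter_reporting_completeness(panel, config)
  s2 <- flag_high_outliers(s1$panel, config)
  audit <- audit_retention(panel, s2$panel)
  list(panel = s2$panel,
       report = merge_reports(s1$report, s2$report, audit))
}

#' Retention across completeness thresholds
#'
#' Reruns the completeness filter at several thresholds (the sensitivity
#' sweep companion to the default of 15): stricter thresholds can only
#' retain fewer facilities.
#'
#' @param panel a raw [facility_panel()].
#' @param thresholds integer vector of \code{min_months_reported} values
#'   (default \code{c(12, 15, 18, total_months)}).
#' @param config base [cleaning_config()]; its threshold is replaced by
#'   each sweep value in turn.
#' @return Data frame with one row per indicator x threshold: facilities
#'   retained and the cleaned/raw count-sum ratio after full cleaning at
#'   that threshold.
#' @export
completeness_sweep <- function(panel, thresholds = NULL,
                               config = cleaning_config()) {
  panel <- facility_panel(panel)
  if (is.null(thresholds)) {
    thresholds <- unique(c(12L, 15L, 18L, config$total_months))
  }
  thresholds <- as.integer(thresholds)
  if (!length(thresholds)) stop("thresholds must be non-empty")
  if (any(thresholds < 1L | thresholds > config$total_months)) {
    stop("thresholds must lie in 1..total_months")
  }
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$min_months_reported <- th
    res <- suppressWarnings(clean_panel(panel, cfg))
    ret <- res$report$retention
    excl <- res$report$exclusions
    n_ret <- vapply(ret$indicator, function(i)
      sum(excl$retained[excl$indicator == i]), integer(1))
    data.frame(threshold = th, indicator = ret$indicator,
               facilities_retained = n_ret, retention_ratio = ret$ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cleaning_report <- function(exclusions = NULL, outliers = NULL,
                            retention = NULL, monthly_reporting = NULL) {
  structure(list(exclusions = exclusions, outliers = outliers,
                 retention = retention,
                 monthly_reporting = monthly_reporting),
            class = "cleaning_report")
}

merge_reports <- function(...) {
  parts <- list(...)
  out <- cleaning_report()
  for (f in c("exclusions", "outliers", "retention",
              "monthly_reporting")) {
    for (p in parts) {
      if (is.null(out[[f]]) && !is.null(p[[f]])) out[f] <- list(p[[f]])
    }
  }
  out
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  if (!is.null(x$exclusions)) {
    tab <- table(x$exclusions$indicator, x$exclusions$retained)
    cat("  completeness: ", sum(x$exclusions$retained), "/",
        nrow(x$exclusions), " facility-indicator series retained\n",
        sep = "")
    if (any(!x$exclusions$retained)) {
      utils::capture.output(print(tab))  # keep print quiet but available
    }
  }
  if (!is.null(x$outliers)) {
    cat("  high outliers flagged: ", nrow(x$outliers), "\n", sep = "")
  }
  if (!is.null(x$retention)) {
    cat("  retention ratios (cleaned/raw):\n")
    for (i in seq_len(nrow(x$retention))) {
      cat(sprintf("    %-20s %.3f\n", x$retention$indicator[i],
                  x$retention$ratio[i]))
    }
  }
  invisible(x)
}

#' Serialize a cleaning report to CSV tables plus a JSON summary
#'
#' Writes \code{cleaning_exclusions.csv}, \code{cleaning_outliers.csv},
#' \code{cleaning_retention.csv}, \code{cleaning_monthly_reporting.csv}
#' (whichever tables the report holds) and \code{cleaning_summary.json}
#' into \code{dir}.
#'
#' @param report a \code{cleaning_report}.
#' @param dir output directory (created if needed).
#' @export
write_cleaning_report <- function(report, dir) {
  stopifnot(inherits(report, "cleaning_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c(exclusions = "cleaning_exclusions.csv",
              outliers = "cleaning_outliers.csv",
              retention = "cleaning_retention.csv",
              monthly_reporting = "cleaning_monthly_reporting.csv")
  for (f in names(tables)) {
    if (!is.null(report[[f]])) {
      utils::write.csv(report[[f]], file.path(dir, tables[[f]]),
                       row.names = FALSE)
    }
  }
  summary <- list(
    n_series = if (!is.null(report$exclusions)) nrow(report$exclusions),
    n_series_retained = if (!is.null(report$exclusions))
      sum(report$exclusions$retained),
    n_outliers_flagged = if (!is.null(report$outliers))
      nrow(report$outliers),
    retention = if (!is.null(report$retention))
      stats::setNames(as.list(report$retention$ratio),
                      report$retention$indicator))
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       file.path(dir, "cleaning_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
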