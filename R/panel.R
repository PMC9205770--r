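#' Facility-month count panels
#'
#' A facility panel is a long-format data frame with one row per *reported*
#' facility-month-indicator cell: columns \code{facility_id}, \code{unit_id}
#' (sub-national unit), \code{indicator}, \code{month} (integer index) and
#' \code{count}. A month a facility did not report is an absent row, not a
#' zero: reported zeros are legitimate data, and the completeness filter
#' counts them as reported.
#'
#' @param x data frame with the five columns above.
#' @return \code{x} with class \code{c("facility_panel", "data.frame")},
#'   rows ordered by indicator, unit, facility, month.
#' @export
facility_panel <- function(x) {
  need <- c("facility_id", "unit_id", "indicator", "month", "count")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("facility panel lacks column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  x$facility_id <- as.character(x$facility_id)
  x$unit_id <- as.character(x$unit_id)
  x$indicator <- as.character(x$indicator)
  x$month <- as.integer(x$month)
  x$count <- as.numeric(x$count)
  x <- x[!is.na(x$count), , drop = FALSE]
  if (nrow(x) && any(x$count < 0)) stop("negative counts in facility panel")
  if (nrow(x) && any(x$month < 1L)) stop("month indices must be >= 1")
  x <- x[order(x$indicator, x$unit_id, x$facility_id, x$month), ,
         drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("facility_panel", "data.frame")
  x
}

#' Sub-national unit-month panel
#'
#' One row per unit-indicator-month with the summed count over reporting
#' facilities (\code{Y_it}) and the number of facilities contributing.
#' Unit-months with no reporting facility are absent, not zero.
#'
#' @param x data frame with columns \code{unit_id}, \code{indicator},
#'   \code{month}, \code{count}, \code{n_facilities}.
#' @return \code{x} with class \code{c("unit_panel", "data.frame")}.
#' @export
unit_panel <- function(x) {
  need <- c("unit_id", "indicator", "month", "count", "n_facilities")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("unit panel lacks column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x)[need]
  x$unit_id <- as.character(x$unit_id)
  x$indicator <- as.character(x$indicator)
  x$month <- as.integer(x$month)
  x$count <- as.numeric(x$count)
  x$n_facilities <- as.integer(x$n_facilities)
  key <- paste(x$unit_id, x$indicator, x$month)
  if (anyDuplicated(key)) {
    stop("duplicate unit x indicator x month records in unit panel")
  }
  x <- x[order(x$indicator, x$unit_id, x$month), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("unit_panel", "data.frame")
  x
}

#' Aggregate a cleaned facility panel to sub-national units
#'
#' The regression's observation unit is the sub-national unit-month: the
#' unit count is the sum of all non-missing facility counts for that
#' indicator and month. Unit-months with zero contributing facilities do
#' not appear in the output (absence, not zero), so downstream model fits
#' are complete-case.
#'
#' @param panel a [facility_panel()] (normally after cleaning).
#' @return A [unit_panel()].
#' @examples
#' p <- facility_panel(data.frame(
#'   facility_id = c("f1", "f2", "f3"), unit_id = "u1",
#'   indicator = "anc1", month = 1L, count = c(10, 20, 30)))
#' aggregate_to_units(p)$count  # 60
#' @export
aggregate_to_units <- function(panel) {
  panel <- facility_panel(panel)
  if (!nrow(panel)) {
    return(unit_panel(data.frame(unit_id = character(), indicator = character(),
                                 month = integer(), count = numeric(),
                                 n_facilities = integer())))
  }
  # a facility mapped to several units would double-count its visits
  fu <- unique(panel[c("facility_id", "unit_id")])
  if (anyDuplicated(fu$facility_id)) {
    bad <- fu$facility_id[duplicated(fu$facility_id)]
    stop("facility mapped to multiple units: ",
         paste(unique(bad), collapse = ", "))
  }
  key <- interaction(panel$unit_id, panel$indicator, panel$month, drop = TRUE)
  agg <- data.frame(
    key = levels(key),
    count = as.numeric(tapply(panel$count, key, sum)),
    n_facilities = as.integer(tapply(panel$count, key, length))
  )
  first <- !duplicated(key)
  meta <- data.frame(key = as.character(key[first]),
                     unit_id = panel$unit_id[first],
                     indicator = panel$indicator[first],
                     month = panel$month[first])
  out <- merge(meta, agg, by = "key")
  unit_panel(out[c("unit_id", "indicator", "month", "count", "n_facilities")])
}

#' Read / write facility panels as long-format CSV
#'
#' The on-disk format has header
#' \code{facility_id,unit_id,indicator,month,count} with an empty
#' \code{count} for a missing (non-reported) facility-month. On reading,
#' empty counts become absent records; on writing, \code{complete_grid}
#' optionally emits the full facility x indicator x month grid with empty
#' counts for the missing cells so reporting gaps are visible in the file.
#'
#' @param path file path.
#' @param panel a [facility_panel()].
#' @param complete_grid emit explicit empty rows for non-reported months
#'   (requires \code{total_months}).
#' @param total_months grid length when \code{complete_grid = TRUE}.
#' @return \code{read_facility_panel} returns a [facility_panel()];
#'   \code{write_facility_panel} returns \code{path} invisibly.
#' @export
read_facility_panel <- function(path) {
  x <- utils::read.csv(path, colClasses = c(
    facility_id = "character", unit_id = "character",
    indicator = "character", month = "integer", count = "numeric"))
  facility_panel(x)
}

#' @rdname read_facility_panel
#' @export
write_facility_panel <- function(panel, path, complete_grid = FALSE,
                                 total_months = NULL) {
  panel <- facility_panel(panel)
  out <- panel
  if (complete_grid) {
    if (is.null(total_months)) {
      stop("complete_grid = TRUE requires total_months")
    }
    fac <- unique(panel[c("facility_id", "unit_id", "indicator")])
    grid <- fac[rep(seq_len(nrow(fac)), each = total_months), ,
                drop = FALSE]
    grid$month <- rep(seq_len(total_months), times = nrow(fac))
    out <- merge(grid, panel, all.x = TRUE,
                 by = c("facility_id", "unit_id", "indicator", "month"))
    out <- out[order(out$indicator, out$unit_id, out$facility_id,
                     out$month), ]
  }
  out <- out[c("facility_id", "unit_id", "indicator", "month", "count")]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read / write unit panels as CSV
#'
#' Long format \code{unit_id,indicator,month,count,n_facilities}; the
#' panel round-trips without loss.
#'
#' @param panel a [unit_panel()].
#' @param path file path.
#' @export
write_unit_panel <- function(panel, path) {
  panel <- unit_panel(panel)
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_unit_panel
#' @export
read_unit_panel <- function(path) {
  x <- utils::read.csv(path, colClasses = c(
    unit_id = "character", indicator = "character", month = "integer",
    count = "numeric", n_facilities = "integer"))
  unit_panel(x)
}

panel_indicators <- function(panel) sort(unique(panel$indicator))

subset_indicator <- function(panel, indicator) {
  out <- panel[panel$indicator == indicator, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(panel)
  out
}
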