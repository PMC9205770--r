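test_that("completeness threshold is boundary-inclusive", {
  # full reporter, exactly-15, and 14-month reporters
  p <- make_panel(full = setNames(rep(100, 24), 1:24),
                  at15 = setNames(rep(100, 15), 1:15),
                  at14 = setNames(rep(100, 14), 1:14))
  res <- filter_reporting_completeness(p, cleaning_config())
  kept <- unique(res$panel$facility_id)
  expect_setequal(kept, c("full", "at15"))
  excl <- res$report$exclusions
  expect_equal(excl$retained[excl$facility_id == "at14"], FALSE)
  expect_equal(excl$months_reported[excl$facility_id == "at15"], 15L)
})

test_that("a reported zero counts as reported", {
  p <- make_panel(zeros = setNames(rep(0, 24), 1:24))
  res <- filter_reporting_completeness(p, cleaning_config())
  expect_equal(nrow(res$panel), 24)
})

test_that("raising the threshold never increases retention", {
  m <- generating_model(n_units = 4, facilities_per_unit = 10, seed = 21)
  p <- corrupt_panel(simulate_panel(m),
                     corruption_spec(dropout_rate = 0.25, seed = 4))
  kept <- vapply(c(1, 8, 12, 15, 18, 24), function(th) {
    r <- suppressWarnings(
      filter_reporting_completeness(p, cleaning_config(th)))
    length(unique(r$panel$facility_id))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("a constant series flags no outliers", {
  p <- make_panel(const = setNames(rep(100, 24), 1:24))
  res <- flag_high_outliers(p, cleaning_config())
  expect_equal(nrow(res$panel), 24)
  expect_equal(nrow(res$report$outliers), 0)
})

test_that("a single spike among constants exceeds 3.5 facility SDs and is removed", {
  # 23 values of 100 and one of 500: the spike sits
  # (d * 23/24) / (d / sqrt(24)) = sqrt(24) * 23/24 = 4.69 SDs above the
  # mean (statistics include the spike itself), so it must be flagged
  counts <- setNames(c(rep(100, 23), 500), 1:24)
  p <- make_panel(spiky = counts)
  res <- flag_high_outliers(p, cleaning_config())
  out <- res$report$outliers
  expect_equal(nrow(out), 1)
  expect_equal(out$month, 24L)
  expect_equal(out$count, 500)
  expect_equal(out$z, sqrt(24) * 23 / 24, tolerance = 1e-12)
  expect_false(24 %in% res$panel$month)
  # no non-flagged cell was altered
  expect_equal(res$panel$count, rep(100, 23))
})

test_that("low outliers are retained by default but removable by flag", {
  counts <- setNames(c(rep(500, 23), 100), 1:24)  # one deep low value
  p <- make_panel(dip = counts)
  res <- flag_high_outliers(p, cleaning_config())
  expect_equal(nrow(res$report$outliers), 0)
  expect_equal(nrow(res$panel), 24)
  res2 <- flag_high_outliers(p, cleaning_config(remove_low_outliers = TRUE))
  expect_equal(nrow(res2$report$outliers), 1)
  expect_equal(res2$report$outliers$month, 24L)
})

test_that("single-pass flagging is idempotent on the recomputed panel", {
  m <- generating_model(n_units = 3, facilities_per_unit = 8, seed = 31)
  p <- corrupt_panel(simulate_panel(m),
                     corruption_spec(dropout_rate = 0, outlier_rate = 0.03,
                                     outlier_scale = 6, seed = 8))
  once <- flag_high_outliers(p, cleaning_config())
  twice <- flag_high_outliers(once$panel, cleaning_config())
  expect_equal(nrow(twice$report$outliers), 0)
  expect_equal(as.data.frame(twice$panel), as.data.frame(once$panel))
})

test_that("injected 5x-mean outliers are caught with few false flags", {
  # Detection-power fixture: one spike per corrupted facility series. Two
  # *equal* spikes among 24 points can never exceed 3.32 SDs of a series
  # whose statistics include them (the k=2 analogue of the single-spike
  # bound sqrt(24)*23/24 = 4.69), so multi-spike series are inherently
  # maskable under any include-the-candidate z rule; realistic data-entry
  # error rates (<1% of cells) make such collisions rare, and the fixture
  # injects singletons to measure the rule's power, not the collision rate.
  m <- generating_model(n_units = 10, facilities_per_unit = 20, seed = 51)
  panel <- simulate_panel(m)
  set.seed(14)
  facs <- sample(unique(panel$facility_id), 100)
  injected_key <- character(0)
  for (f in facs) {
    rows <- which(panel$facility_id == f)
    r <- sample(rows, 1)
    panel$count[r] <- round(5 * mean(panel$count[rows]))
    injected_key <- c(injected_key, paste(f, panel$month[r]))
  }
  res <- flag_high_outliers(panel, cleaning_config())
  flagged_key <- paste(res$report$outliers$facility_id,
                       res$report$outliers$month)
  hit <- mean(injected_key %in% flagged_key)
  n_clean_cells <- nrow(panel) - length(injected_key)
  false_flags <- sum(!(flagged_key %in% injected_key))
  expect_gte(hit, 0.95)
  # false-flag bound: < 1% of the ~4700 uncorrupted cells; at the NB tail
  # probability beyond 3.5 facility SDs the binomial sampling error on
  # this rate is far below the 1% bound
  expect_lt(false_flags / n_clean_cells, 0.01)
})

test_that("low-rate corruption injections are flagged in singleton series", {
  m <- generating_model(n_units = 10, facilities_per_unit = 20, seed = 52)
  dirty <- corrupt_panel(simulate_panel(m),
                         corruption_spec(dropout_rate = 0,
                                         outlier_rate = 0.01,
                                         outlier_scale = 5, seed = 15))
  log <- attr(dirty, "corruption_log")
  singletons <- names(which(table(log$facility_id) == 1))
  res <- flag_high_outliers(dirty, cleaning_config())
  flagged_key <- paste(res$report$outliers$facility_id,
                       res$report$outliers$month)
  lone <- log[log$facility_id %in% singletons, ]
  hit <- mean(paste(lone$facility_id, lone$month) %in% flagged_key)
  expect_gte(hit, 0.95)
})

test_that("retention audit reports exact cleaned/raw ratios", {
  # identity: cleaned == raw
  p <- simulate_panel(flat_model())
  r <- audit_retention(p, p)
  expect_true(all(r$retention$ratio == 1))
  # dropping a facility holding 10% of the total gives ratio 0.9
  big <- make_panel(a = setNames(rep(90, 24), 1:24),
                    b = setNames(rep(10, 24), 1:24))
  cleaned <- facility_panel(big[big$facility_id == "a", ])
  r2 <- audit_retention(big, cleaned)
  expect_equal(r2$retention$ratio, 0.9)
  # zero raw sum flags an undefined ratio
  z <- make_panel(z = setNames(rep(0, 24), 1:24))
  r3 <- audit_retention(z, z)
  expect_true(r3$retention$undefined_ratio)
  expect_true(is.na(r3$retention$ratio))
})

test_that("monthly reporting counts track facilities per month", {
  p <- make_panel(a = setNames(rep(5, 24), 1:24),
                  b = setNames(rep(5, 12), 1:12))
  r <- audit_retention(p, p)
  mr <- r$monthly_reporting
  expect_equal(mr$n_facilities[mr$month == 1], 2L)
  expect_equal(mr$n_facilities[mr$month == 24], 1L)
})

test_that("threshold sweep retention is monotonically non-increasing", {
  m <- generating_model(n_units = 5, facilities_per_unit = 10, seed = 61)
  p <- corrupt_panel(simulate_panel(m),
                     corruption_spec(dropout_rate = 0.3, seed = 6))
  sweep <- completeness_sweep(p, thresholds = c(12, 15, 18, 24))
  expect_true(all(diff(sweep$facilities_retained) <= 0))
  ratios <- sweep$retention_ratio
  expect_true(all(diff(ratios[!is.na(ratios)]) <= 1e-12))
  expect_error(completeness_sweep(p, thresholds = integer()), "non-empty")
})

test_that("cleaning report serializes to CSV tables and a JSON summary", {
  m <- generating_model(n_units = 3, facilities_per_unit = 5, seed = 71)
  p <- corrupt_panel(simulate_panel(m),
                     corruption_spec(dropout_rate = 0.2,
                                     outlier_rate = 0.02, seed = 9))
  res <- clean_panel(p)
  dir <- tempfile("report")
  write_cleaning_report(res$report, dir)
  expect_true(file.exists(file.path(dir, "cleaning_exclusions.csv")))
  expect_true(file.exists(file.path(dir, "cleaning_retention.csv")))
  js <- jsonlite::read_json(file.path(dir, "cleaning_summary.json"))
  expect_equal(js$n_series, nrow(res$report$exclusions))
})
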