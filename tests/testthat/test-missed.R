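test_that("no pandemic effect means counterfactual equals observed", {
  m <- integer_model(n_units = 3, facilities_per_unit = 4,
                     beta2 = 0, beta3 = 0, beta4 = 0)
  fit <- its_fit(aggregate_to_units(simulate_panel(m)))
  cf <- counterfactual_series(fit)
  expect_lt(max(abs(cf$deficit)), 1e-8)
  expect_equal(cumulative_missed(cf)$total, 0, tolerance = 1e-8)
})

test_that("a pure level shock yields the closed-form missed total", {
  # shock-only: deficit = -beta2 * F per unit-month over shock_months;
  # cumulative = -beta2 * F * n_units * shock_months
  m <- integer_model(n_units = 5, facilities_per_unit = 4,
                     beta2 = -30, beta3 = 0, beta4 = 0)
  fit <- its_fit(aggregate_to_units(simulate_panel(m)))
  cf <- counterfactual_series(fit)
  res <- cumulative_missed(cf)
  expect_equal(res$total, 30 * 4 * 5 * 6, tolerance = 1e-7)
  shock <- res$monthly$month %in% 16:21
  expect_equal(res$monthly$deficit[shock], rep(30 * 4 * 5, 6),
               tolerance = 1e-7)
  expect_equal(res$monthly$deficit[!shock], rep(0, 3), tolerance = 1e-7)
  # resumption-level analogue
  m4 <- integer_model(n_units = 5, facilities_per_unit = 4,
                      beta2 = 0, beta3 = 0, beta4 = -10)
  cf4 <- counterfactual_series(its_fit(aggregate_to_units(
    simulate_panel(m4))))
  expect_equal(cumulative_missed(cf4)$total, 10 * 4 * 5 * 3,
               tolerance = 1e-7)
})

test_that("full generating model matches the hand-derived missed formula", {
  # deficits: shock months z = 1..6 give -(beta2 + beta3 z) per facility,
  # resumption months give -beta4
  m <- integer_model(n_units = 4, facilities_per_unit = 5)
  fit <- its_fit(aggregate_to_units(simulate_panel(m)))
  res <- cumulative_missed(counterfactual_series(fit))
  per_fac <- -sum(m$beta2 + m$beta3 * (1:6)) - 3 * m$beta4
  expect_equal(res$total, per_fac * 4 * 5, tolerance = 1e-7)
})

test_that("seasonal swings cancel out of the deficits", {
  m <- integer_model(n_units = 4, facilities_per_unit = 5,
                     beta2 = 0, beta3 = 0, beta4 = 0,
                     season_effects = c(winter = -50, spring = 0,
                                        summer = 50, fall = 10))
  fit <- its_fit(aggregate_to_units(simulate_panel(m)))
  res <- cumulative_missed(counterfactual_series(fit))
  expect_lt(max(abs(res$monthly$deficit)), 1e-7)
})

test_that("observed above prediction gives meaningful negative totals", {
  cf <- data.frame(unit_id = "u1", indicator = "anc", month = 16:24,
                   observed = 110, predicted = 100,
                   deficit = -10)
  expect_equal(cumulative_missed(cf)$total, -90)
  cf2 <- transform(cf, observed = 80)
  expect_equal(cumulative_missed(cf2)$total, 180)
  cf3 <- transform(cf, observed = 100)
  expect_equal(cumulative_missed(cf3)$total, 0)
})

test_that("window handling: subsets allowed, empty or foreign months not", {
  cf <- data.frame(unit_id = "u1", indicator = "anc", month = 16:24,
                   observed = 80, predicted = 100, deficit = 20)
  expect_equal(cumulative_missed(cf, window = 16:18)$total, 60)
  expect_error(cumulative_missed(cf, window = integer()), "non-empty")
  expect_error(cumulative_missed(cf, window = 10:12), "absent")
  m <- integer_model(n_units = 3, facilities_per_unit = 2)
  fit <- its_fit(aggregate_to_units(simulate_panel(m)))
  expect_error(counterfactual_series(fit, months = 25), "outside")
})

test_that("normalization reproduces the arithmetic chain", {
  cf <- data.frame(unit_id = "u", indicator = "anc", month = 16,
                   observed = 0, predicted = 500, deficit = 500)
  res <- cumulative_missed(cf)
  # births basis: 100,000 people at CBR 20 -> 2,000 births -> 250 per 1,000
  r1 <- normalize_missed(res, denominator_spec(1e5, 20))
  expect_equal(r1$rate_per_1000, 250)
  # population basis: 48,000 missed over 1,000,000 people -> 48 per 1,000
  res2 <- res; res2$total <- 48000
  r2 <- normalize_missed(res2, denominator_spec(1e6,
                                                basis = "population"))
  expect_equal(r2$rate_per_1000, 48)
  # zero missed -> zero rate; homogeneity in both arguments
  res0 <- res; res0$total <- 0
  expect_equal(normalize_missed(res0,
                                denominator_spec(1e5, 20))$rate_per_1000, 0)
  res3 <- res; res3$total <- res$total * 7
  expect_equal(normalize_missed(res3, denominator_spec(1e5, 20))$
                 rate_per_1000, 250 * 7)
  expect_equal(normalize_missed(res, denominator_spec(2e5, 20))$
                 rate_per_1000, 125)
  expect_error(denominator_spec(0, 20), "positive")
  expect_error(denominator_spec(1e5), "crude_birth_rate")
})

test_that("service groups sum members and exclude incomplete groups", {
  mk <- function(ind, total) {
    cf <- data.frame(unit_id = "u", indicator = ind, month = 16:18,
                     observed = 0, predicted = total / 3,
                     deficit = total / 3)
    cumulative_missed(cf)
  }
  results <- list(anc = mk("anc", 100), delivery = mk("delivery", 50),
                  pnc = mk("pnc", 59), bcg = mk("bcg", 40))
  groups <- list(maternal = c("anc", "delivery", "pnc"),
                 vaccination = c("bcg", "measles"))
  out <- group_services(results, groups,
                        universe = c(names(results), "measles"))
  expect_equal(out$maternal$total, 209)
  expect_false(out$maternal$excluded)
  expect_true(out$vaccination$excluded)
  expect_match(out$vaccination$exclusion_reason, "measles")
  # a normalized excluded group stays excluded rather than gaining a rate
  norm <- normalize_missed(out$vaccination, denominator_spec(1e5, 20))
  expect_true(norm$excluded)
  # unknown indicator in the grouping is an error, as is an empty grouping
  expect_error(group_services(results, list(g = c("anc", "nonsense"))),
               "unknown indicator")
  expect_error(group_services(results, list()), "non-empty")
})
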