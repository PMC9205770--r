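test_that("a noiseless panel is interpolated exactly", {
  m <- integer_model(n_units = 4, facilities_per_unit = 5)
  up <- aggregate_to_units(simulate_panel(m))
  d <- build_design(up)
  fit <- its_fit(d)
  exp <- expected_unit_coefs(m, d)
  expect_equal(coef(fit), exp, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  # zero residuals imply a zero sandwich
  expect_lt(max(abs(vcov(fit))), 1e-12)
})

test_that("an all-zero response gives all-zero coefficients", {
  m <- integer_model(n_units = 3, facilities_per_unit = 2)
  up <- aggregate_to_units(simulate_panel(m))
  up$count <- 0
  fit <- its_fit(unit_panel(up))
  expect_true(all(abs(coef(fit)) < 1e-12))
})

test_that("OLS and clustered vcov match brute-force oracles on 50 random panels", {
  set.seed(20240601)
  for (rep in 1:50) {
    n_units <- sample(3:6, 1)
    m <- generating_model(
      n_units = n_units, facilities_per_unit = sample(2:4, 1),
      beta0 = runif(1, 80, 150), beta1 = runif(1, -1, 1),
      beta2 = runif(1, -40, 0), beta3 = runif(1, -2, 4),
      beta4 = runif(1, -20, 5),
      season_effects = c(winter = runif(1, -10, 0), spring = 0,
                         summer = runif(1, 0, 10), fall = runif(1, -5, 5)),
      unit_effects = runif(n_units, -15, 15),
      dispersion = runif(1, 0.01, 0.2), seed = sample.int(1e6, 1))
    d <- build_design(aggregate_to_units(simulate_panel(m)))
    fit <- its_fit(d)
    beta_oracle <- ols_oracle(d$matrix, d$y)
    expect_equal(unname(coef(fit)), beta_oracle, tolerance = 1e-8)
    v_oracle <- cluster_vcov_oracle(d$matrix, residuals(fit), d$cluster)
    expect_equal(unname(vcov(fit)), unname(v_oracle), tolerance = 1e-8)
  }
})

test_that("clustered vcov agrees with an established sandwich implementation", {
  m <- generating_model(n_units = 6, facilities_per_unit = 3, seed = 77)
  up <- aggregate_to_units(simulate_panel(m))
  d <- build_design(up)
  fit <- its_fit(d)
  df <- data.frame(y = d$y, d$matrix[, -1], cluster = d$cluster)
  lmfit <- lm(y ~ ., data = df[setdiff(names(df), "cluster")])
  v_ref <- sandwich::vcovCL(lmfit, cluster = df$cluster, type = "HC1",
                            cadjust = TRUE)
  expect_equal(unname(vcov(fit)), unname(v_ref), tolerance = 1e-8)
})

test_that("singleton clusters reduce the sandwich to the HC1 estimator", {
  # every observation its own cluster: meat = sum x_i x_i' e_i^2 and the
  # scaling [n/(n-1)]*[(n-1)/(n-k)] collapses to the HC1 factor n/(n-k)
  m <- integer_model(n_units = 4, facilities_per_unit = 2)
  up <- aggregate_to_units(simulate_panel(m))
  set.seed(5)
  up$count <- up$count + rnorm(nrow(up), 0, 5)
  d <- build_design(unit_panel(up))
  fit <- its_fit(d)
  fit$cluster <- as.character(seq_len(fit$n_obs))
  v <- cluster_robust_vcov(fit, type = "stata")
  X <- d$matrix
  e <- residuals(fit)
  n <- nrow(X); k <- ncol(X)
  hc1 <- (n / (n - k)) * solve(crossprod(X)) %*%
    crossprod(X * e) %*% solve(crossprod(X))
  expect_equal(unname(v), unname(hc1), tolerance = 1e-8)
})

test_that("alternative small-sample scalings are selectable and ordered", {
  m <- generating_model(n_units = 5, facilities_per_unit = 3, seed = 13)
  d <- build_design(aggregate_to_units(simulate_panel(m)))
  fit <- its_fit(d)
  v_none <- cluster_robust_vcov(fit, "none")
  v_cl <- cluster_robust_vcov(fit, "cluster")
  v_st <- cluster_robust_vcov(fit, "stata")
  expect_equal(unname(v_cl), unname(v_none) * 5 / 4, tolerance = 1e-12)
  expect_true(all(diag(v_st) >= diag(v_cl)))
  ev <- eigen(v_st, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))  # positive semi-definite
})

test_that("inference uses t critical values with G-2 degrees of freedom", {
  m <- generating_model(n_units = 12, facilities_per_unit = 3, seed = 99)
  up <- aggregate_to_units(simulate_panel(m))
  fit <- its_fit(up)
  tab <- summary(fit)$coefficients
  expect_true(all(tab$df == 10))
  # CI half-width / SE equals the t quantile at df = 10 (about 2.228)
  i <- which(tab$term == "covid_level")
  half <- (tab$ci_high[i] - tab$ci_low[i]) / 2
  expect_equal(half / tab$std_error[i], qt(0.975, 10), tolerance = 1e-10)
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  # large-G limit approaches the normal critical value
  expect_equal(qt(0.975, 1e6), qnorm(0.975), tolerance = 1e-4)
})

test_that("a zero estimate with positive SE has p = 1", {
  m <- integer_model(n_units = 4, facilities_per_unit = 2)
  up <- aggregate_to_units(simulate_panel(m))
  set.seed(8)
  up$count <- up$count + rnorm(nrow(up), 0, 3)
  fit <- its_fit(unit_panel(up))
  fit$coefficients["covid_level"] <- 0
  tab <- summary(fit)$coefficients
  expect_equal(tab$p_value[tab$term == "covid_level"], 1)
})

test_that("inference demands enough clusters", {
  m <- integer_model(n_units = 2, facilities_per_unit = 2)
  up <- aggregate_to_units(simulate_panel(m))
  fit <- its_fit(up)      # G = 2: fitting is possible
  expect_error(summary(fit), "at least 3 clusters")
})

test_that("permuting months within units destroys the shock estimate", {
  m <- generating_model(n_units = 6, facilities_per_unit = 10,
                        beta2 = -40, seed = 3)
  up <- aggregate_to_units(simulate_panel(m))
  fit <- its_fit(up)
  b2 <- coef(fit)[["covid_level"]]
  set.seed(17)
  perm <- as.data.frame(up)
  for (u in unique(perm$unit_id)) {
    rows <- which(perm$unit_id == u)
    perm$count[rows] <- perm$count[sample(rows)]
  }
  b2_perm <- coef(its_fit(unit_panel(perm)))[["covid_level"]]
  expect_lt(abs(b2_perm), abs(b2) / 4)
})

test_that("fits serialize to JSON with coefficients, vcov and df", {
  m <- generating_model(n_units = 4, facilities_per_unit = 2, seed = 55)
  fit <- its_fit(aggregate_to_units(simulate_panel(m)))
  f <- tempfile(fileext = ".json")
  write_its_fit(fit, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$G, 4)
  expect_equal(js$df, 2)
  expect_equal(js$beta$covid_level, coef(fit)[["covid_level"]])
})
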