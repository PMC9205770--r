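# Shared fixtures and independent oracle routines.

# Noiseless generating model whose linear predictor is integer-valued at
# every cell, so rounding in the deterministic draw is a no-op and OLS can
# recover the generating coefficients exactly.
integer_model <- function(n_units = 10L, facilities_per_unit = 20L,
                          beta0 = 100, beta1 = 2, beta2 = -30, beta3 = 3,
                          beta4 = -10,
                          season_effects = c(winter = -8, spring = 0,
                                             summer = 8, fall = 4),
                          timeline = study_timeline(), ...) {
  generating_model(
    n_units = n_units, facilities_per_unit = facilities_per_unit,
    timeline = timeline, beta0 = beta0, beta1 = beta1, beta2 = beta2,
    beta3 = beta3, beta4 = beta4, season_effects = season_effects,
    unit_effects = seq(-2 * n_units, 2 * n_units - 4, by = 4)[
      seq_len(n_units)],
    dispersion = 0, ...)
}

# A flat model: no trend, no pandemic effects, no season/unit structure.
flat_model <- function(n_units = 2L, facilities_per_unit = 3L, beta0 = 100,
                       dispersion = 0, ...) {
  generating_model(
    n_units = n_units, facilities_per_unit = facilities_per_unit,
    beta0 = beta0, beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0,
    season_effects = c(winter = 0, spring = 0, summer = 0, fall = 0),
    unit_effects = rep(0, n_units), dispersion = dispersion, ...)
}

# Hand-rolled facility panel from per-facility month/count vectors.
make_panel <- function(..., unit = "u1", indicator = "svc") {
  series <- list(...)
  rows <- lapply(names(series), function(f) {
    counts <- series[[f]]
    months <- as.integer(names(counts))
    if (is.null(names(counts))) months <- seq_along(counts)
    data.frame(facility_id = f, unit_id = unit, indicator = indicator,
               month = months, count = as.numeric(counts))
  })
  facility_panel(do.call(rbind, rows))
}

# In-memory pipeline run (no file outputs) for comparisons.
run_analysis_for_test <- function(cfg) rhisits:::run_analysis(cfg)

# Brute-force normal-equations OLS oracle.
ols_oracle <- function(X, y) {
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)
}

# Literal loop-over-clusters sandwich oracle with the Stata-style factor.
cluster_vcov_oracle <- function(X, resid, cluster,
                                type = c("stata", "cluster", "none")) {
  type <- match.arg(type)
  n <- nrow(X); k <- ncol(X)
  ids <- unique(cluster)
  G <- length(ids)
  bread <- solve(t(X) %*% X)
  meat <- matrix(0, k, k)
  for (g in ids) {
    rows <- which(cluster == g)
    Xg <- X[rows, , drop = FALSE]
    eg <- resid[rows]
    sg <- t(Xg) %*% eg
    meat <- meat + sg %*% t(sg)
  }
  adj <- switch(type, stata = (G / (G - 1)) * ((n - 1) / (n - k)),
                cluster = G / (G - 1), none = 1)
  adj * bread %*% meat %*% bread
}

# Expected design-scale coefficients implied by a generating model once
# facility counts are summed within units (everything scales by the number
# of facilities) and reference levels are absorbed into the intercept.
expected_unit_coefs <- function(model, design) {
  F <- model$facilities_per_unit
  season_levels <- sort(unique(model$season_map))
  unit_ids <- sprintf("unit%02d", seq_len(model$n_units))
  ref_season <- season_levels[1]
  exp <- c(intercept = F * (model$beta0 +
                              model$season_effects[[ref_season]] +
                              model$unit_effects[1]),
           trend = F * model$beta1,
           covid_level = F * model$beta2,
           covid_slope = F * model$beta3,
           resumption_level = F * model$beta4)
  for (s in season_levels[-1]) {
    exp[paste0("season_", s)] <-
      F * (model$season_effects[[s]] - model$season_effects[[ref_season]])
  }
  for (i in seq_along(unit_ids)[-1]) {
    exp[paste0("unit_", unit_ids[i])] <-
      F * (model$unit_effects[i] - model$unit_effects[1])
  }
  exp[colnames(design$matrix)]
}
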