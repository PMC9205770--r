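#' Fit the segmented interrupted time series model
#'
#' Ordinary least squares on the segmented design (QR decomposition via
#' \code{lm.fit}), with cluster-robust sandwich standard errors clustered
#' on the sub-national unit to absorb serial correlation within units.
#' Inference (p values, confidence intervals) uses a t-distribution with
#' \code{G - 2} degrees of freedom, where \code{G} is the number of units —
#' a deliberately conservative small-sample choice for panels with few
#' clusters.
#'
#' The sandwich is
#' \deqn{(X'X)^{-1} \Big(\sum_g X_g' e_g e_g' X_g\Big) (X'X)^{-1}}
#' scaled, by default, by the small-sample factor
#' \eqn{[G/(G-1)] \cdot [(n-1)/(n-k)]} (the convention of the major
#' commercial econometrics packages); \code{vcov_type = "cluster"} applies
#' only \eqn{G/(G-1)}, and \code{"none"} no correction, for sensitivity
#' checks.
#'
#' @param x a [unit_panel()] (single indicator) or a prebuilt
#'   [build_design()] object.
#' @param timeline a [study_timeline()] (panel method).
#' @param season_map month-to-season map (panel method); default
#'   [default_season_map()].
#' @param indicator indicator to select when the panel has several.
#' @param vcov_type small-sample scaling of the cluster sandwich:
#'   \code{"stata"} (default), \code{"cluster"} or \code{"none"}.
#' @param ... passed between methods.
#' @return An object of class \code{its_fit} with components
#'   \code{coefficients}, \code{vcov} (cluster-robust), \code{residuals},
#'   \code{fitted.values}, \code{n_obs}, \code{n_params}, \code{G},
#'   \code{df} (\code{G - 2}), \code{cluster}, \code{design} and
#'   \code{vcov_type}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{vcov}, \code{confint}, \code{predict}, \code{residuals},
#'   \code{fitted}, \code{nobs}, \code{plot}.
#' @examples
#' m <- generating_model(n_units = 4, facilities_per_unit = 5,
#'                       dispersion = 0)
#' fit <- its_fit(aggregate_to_units(simulate_panel(m)))
#' coef(fit)[c("covid_level", "resumption_level")]
#' @export
its_fit <- function(x, ...) UseMethod("its_fit")

#' @rdname its_fit
#' @export
its_fit.unit_panel <- function(x, timeline = study_timeline(),
                               season_map = NULL, indicator = NULL,
                               vcov_type = c("stata", "cluster", "none"),
                               ...) {
  design <- build_design(x, timeline, season_map, indicator)
  its_fit(design, vcov_type = vcov_type, ...)
}

#' @rdname its_fit
#' @export
its_fit.its_design <- function(x, vcov_type = c("stata", "cluster",
                                                "none"), ...) {
  vcov_type <- match.arg(vcov_type)
  X <- x$matrix
  y <- x$y
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) stop("fewer observations (", n, ") than parameters (", k, ")")
  G <- length(unique(x$cluster))
  if (G < 2L) stop("cluster-robust variance needs at least 2 clusters")

  ls <- stats::lm.fit(X, y)
  if (any(is.na(ls$coefficients))) {
    stop("rank-deficient fit; collinear column(s): ",
         paste(colnames(X)[is.na(ls$coefficients)], collapse = ", "))
  }
  beta <- ls$coefficients
  if (!all(is.finite(beta))) stop("non-finite coefficients")
  res <- as.numeric(y - X %*% beta)

  fit <- structure(
    list(coefficients = beta, residuals = res,
         fitted.values = as.numeric(X %*% beta),
         n_obs = n, n_params = k, G = G, df = G - 2L,
         cluster = x$cluster, design = x, vcov_type = vcov_type,
         call = match.call()),
    class = "its_fit")
  fit$vcov <- cluster_robust_vcov(fit, type = vcov_type)
  fit
}

#' Cluster-robust sandwich covariance of an ITS fit
#'
#' Computes \eqn{(X'X)^{-1} M (X'X)^{-1}} with meat
#' \eqn{M = \sum_g X_g'e_g e_g'X_g} over clusters \eqn{g}, scaled by a
#' small-sample factor chosen by \code{type}: \code{"stata"} applies
#' \eqn{[G/(G-1)]\,[(n-1)/(n-k)]}, \code{"cluster"} only
#' \eqn{G/(G-1)}, \code{"none"} neither. The result is symmetrized. With
#' every observation its own cluster and the \code{"stata"} scaling this
#' reduces to the familiar HC1-scaled heteroskedasticity-robust estimator
#' up to the \eqn{n/(n-1)} degenerate-cluster factor.
#'
#' @param fit an [its_fit()] object.
#' @param type small-sample scaling (see above).
#' @return Symmetric positive semi-definite matrix with dimnames matching
#'   the coefficients.
#' @export
cluster_robust_vcov <- function(fit, type = c("stata", "cluster",
                                              "none")) {
  stopifnot(inherits(fit, "its_fit"))
  type <- match.arg(type)
  X <- fit$design$matrix
  e <- fit$residuals
  cl <- fit$cluster
  G <- length(unique(cl))
  if (G < 2L) stop("cluster-robust variance needs at least 2 clusters")
  sizes <- table(cl)
  if (any(sizes == 0)) stop("cluster with zero observations")
  n <- nrow(X)
  k <- ncol(X)

  bread <- chol2inv(chol(crossprod(X)))
  score <- rowsum(X * e, group = cl)      # X_g' e_g stacked by cluster
  meat <- crossprod(as.matrix(score))
  adj <- switch(type,
                stata = (G / (G - 1)) * ((n - 1) / (n - k)),
                cluster = G / (G - 1),
                none = 1)
  V <- adj * bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' @export
residuals.its_fit <- function(object, ...) object$residuals

#' @export
fitted.its_fit <- function(object, ...) object$fitted.values

#' @export
nobs.its_fit <- function(object, ...) object$n_obs

#' @export
print.its_fit <- function(x, ...) {
  cat("Segmented ITS fit (OLS, cluster-robust SEs) for indicator '",
      x$design$indicator, "'\n", sep = "")
  cat("  n = ", x$n_obs, " unit-months, k = ", x$n_params,
      ", G = ", x$G, " units, df = ", x$df, "\n", sep = "")
  main <- c("intercept", "trend", "covid_level", "covid_slope",
            "resumption_level")
  print(round(x$coefficients[main], 4))
  cat("(season and unit fixed effects omitted; see summary())\n")
  invisible(x)
}

#' Coefficient table with cluster-robust t(G-2) inference
#'
#' Standard errors are square roots of the sandwich diagonal; two-sided p
#' values and confidence limits use critical values from a t-distribution
#' with \code{G - 2} degrees of freedom.
#'
#' @param object an [its_fit()].
#' @param alpha two-sided significance level (default 0.05 for 95\% CIs).
#' @param ... ignored.
#' @return An object of class \code{summary.its_fit} whose
#'   \code{coefficients} element is a data frame with columns
#'   \code{term, estimate, std_error, t_value, p_value, ci_low, ci_high,
#'   df}.
#' @export
summary.its_fit <- function(object, alpha = 0.05, ...) {
  if (object$G < 3L) {
    stop("inference needs at least 3 clusters (df = G - 2 >= 1)")
  }
  d <- diag(object$vcov)
  # zero variances are legitimate for an exact (zero-residual) fit
  if (any(d < 0)) stop("negative variance on the vcov diagonal")
  se <- sqrt(d)
  est <- object$coefficients
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  df <- object$df
  crit <- stats::qt(1 - alpha / 2, df)
  tab <- data.frame(term = names(est), estimate = unname(est),
                    std_error = unname(se), t_value = unname(tval),
                    p_value = unname(2 * stats::pt(-abs(tval), df)),
                    ci_low = unname(est - crit * se),
                    ci_high = unname(est + crit * se), df = df)
  rownames(tab) <- NULL
  structure(list(coefficients = tab, alpha = alpha, G = object$G,
                 n_obs = object$n_obs, indicator = object$design$indicator,
                 vcov_type = object$vcov_type),
            class = "summary.its_fit")
}

#' @export
print.summary.its_fit <- function(x, ...) {
  cat("Segmented ITS fit for indicator '", x$indicator, "' (",
      x$n_obs, " unit-months, G = ", x$G, ", ", (1 - x$alpha) * 100,
      "% CIs, t df = G - 2)\n", sep = "")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 5))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
confint.its_fit <- function(object, parm, level = 0.95, ...) {
  tab <- summary(object, alpha = 1 - level)$coefficients
  out <- as.matrix(tab[c("ci_low", "ci_high")])
  rownames(out) <- tab$term
  colnames(out) <- paste0(format(100 * c((1 - level) / 2,
                                         1 - (1 - level) / 2)), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Predictions from an ITS fit, observed or counterfactual
#'
#' With \code{counterfactual = TRUE}, the pandemic terms (shock level,
#' shock slope, resumption level) are forced to zero while trend, season
#' and unit terms are retained: the prediction is what service volume
#' would have been had the pre-pandemic trend continued, adjusted for
#' seasonality — the counterfactual that missed-care estimation subtracts
#' observed counts from.
#'
#' @param object an [its_fit()].
#' @param newdesign optional [build_design()] object to predict for
#'   (default: the fitting design).
#' @param counterfactual zero out the pandemic terms (default FALSE).
#' @param ... ignored.
#' @return Numeric vector of predicted unit-month counts, aligned to the
#'   design rows.
#' @export
predict.its_fit <- function(object, newdesign = NULL,
                            counterfactual = FALSE, ...) {
  design <- if (is.null(newdesign)) object$design else newdesign
  stopifnot(inherits(design, "its_design"))
  X <- design$matrix
  if (!identical(colnames(X), names(object$coefficients))) {
    stop("newdesign columns do not match the fitted coefficients")
  }
  if (counterfactual) {
    zero <- design$coef_group %in% c("covid_level", "covid_slope",
                                     "resumption_level")
    X[, zero] <- 0
  }
  as.numeric(X %*% object$coefficients)
}

#' @export
plot.its_fit <- function(x, ...) {
  d <- x$design
  obs <- rowsum(d$y, d$month)
  fitd <- rowsum(x$fitted.values, d$month)
  cfd <- rowsum(predict(x, counterfactual = TRUE), d$month)
  months <- as.integer(rownames(obs))
  ylim <- range(obs, fitd, cfd)
  plot(months, obs, type = "b", pch = 16, ylim = ylim,
       xlab = "study month", ylab = "total count across units",
       main = paste0("Observed vs fitted and counterfactual: ",
                     d$indicator), ...)
  lines(months, fitd, col = "firebrick", lwd = 2)
  lines(months, cfd, col = "steelblue", lwd = 2, lty = 2)
  abline(v = d$timeline$baseline_months + 0.5, lty = 3)
  abline(v = d$timeline$resumption_start - 0.5, lty = 3)
  legend("bottomleft", bty = "n",
         legend = c("observed", "segmented fit", "counterfactual"),
         col = c("black", "firebrick", "steelblue"),
         lty = c(1, 1, 2), pch = c(16, NA, NA))
  invisible(x)
}

#' Serialize an ITS fit to JSON
#'
#' Writes coefficients, the cluster-robust covariance, degrees of freedom
#' and sample sizes so downstream tooling can consume the fit without R.
#'
#' @param fit an [its_fit()].
#' @param path output JSON path.
#' @export
write_its_fit <- function(fit, path) {
  stopifnot(inherits(fit, "its_fit"))
  jsonlite::write_json(
    list(indicator = fit$design$indicator,
         beta = as.list(fit$coefficients),
         vcov = unname(apply(fit$vcov, 1, as.list)),
         vcov_terms = colnames(fit$vcov),
         df = fit$df, n_obs = fit$n_obs, G = fit$G,
         vcov_type = fit$vcov_type),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
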