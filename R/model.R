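#' Fit the case-crossover distributed-lag temperature model
#'
#' The package's central model: each case of the rare outcome is expanded
#' into its time-stratified referent stratum, daily mean temperature at
#' lags `0..L` enters through a crossbasis (natural cubic spline in
#' temperature, linear term or natural cubic spline in lag), lag-window
#' mean relative humidity is adjusted for with a natural cubic spline, and
#' the conditional logistic likelihood is maximised by Newton-Raphson.
#' Odds ratios contrast a target temperature against the reference
#' (by default the population-weighted 95th and 5th percentiles against
#' the 50th).
#'
#' By default the temperature spline has one internal knot at the median
#' of the case-crossover exposure values with boundary knots at the
#' observed extremes; pass explicit `temp_knots` (e.g. from
#' [aic_knot_scan()]) to override.
#'
#' @param cases `data.frame` of case records (`birth_date`,
#'   `municipality_id`, covariates) — or an already expanded
#'   `cco_dataset`, in which case `exposures` is ignored.
#' @param exposures Lagged exposure table from [build_lagged_exposures()].
#' @param thresholds A `percentile_thresholds` giving the reference (p50)
#'   and contrast (p5, p95) temperatures.
#' @param L Maximum lag (default 1: delivery day and the day before).
#' @param temp_knots Internal knot(s) of the temperature spline; `NULL`
#'   for the default placement.
#' @param lag_kind `"linear"` or `"natural_cubic"` lag basis.
#' @param lag_knots Internal lag knots when `lag_kind = "natural_cubic"`
#'   (default: midpoint of `0..L`).
#' @param humidity Adjust for lag-window mean relative humidity?
#' @param rh_df Degrees of freedom of the humidity spline (default 3: two
#'   internal knots at the 33.3rd/66.7th percentiles).
#' @param rh_knots Explicit humidity knots overriding the percentile rule
#'   (used to hold knots fixed across subgroup refits).
#' @return Object of class `cco_dlnm`: the `cco_fit`, the `crossbasis`,
#'   the humidity spec, the dataset dimensions, and `estimates` — odds
#'   ratios (cumulative and per lag) for the high-vs-moderate and
#'   low-vs-moderate contrasts.
#' @export
cco_dlnm <- function(cases, exposures = NULL, thresholds, L = 1L,
                     temp_knots = NULL, lag_kind = c("linear", "natural_cubic"),
                     lag_knots = NULL, humidity = TRUE, rh_df = 3L,
                     rh_knots = NULL) {
  lag_kind <- match.arg(lag_kind)
  dataset <- if (inherits(cases, "cco_dataset")) cases else expand_cases(cases, exposures, L)
  L <- attr(dataset, "L")
  xcols <- paste0("x_lag", 0:L)
  x_lag <- as.matrix(dataset[, xcols, drop = FALSE])
  xs <- as.vector(x_lag)
  boundary <- range(xs)
  if (is.null(temp_knots)) temp_knots <- stats::median(xs)
  temp_spec <- spline_spec("natural_cubic", temp_knots, boundary)
  lag_spec <- if (lag_kind == "linear") {
    spline_spec("linear", boundary = c(-0.5, max(L, 1) + 0.5))
  } else {
    if (is.null(lag_knots)) lag_knots <- L / 2
    spline_spec("natural_cubic", lag_knots, c(0, L))
  }
  cb <- build_crossbasis(x_lag, temp_spec, lag_spec,
                         center = unname(thresholds$p["p50"]))
  design <- cb$W
  rh_spec <- NULL
  if (humidity) {
    rh <- dataset$rh_mean
    if (is.null(rh_knots)) {
      rh_knots <- stats::quantile(rh, c(1, 2) / 3, names = FALSE)
    }
    rh_bound <- range(rh)
    if (any(rh_knots <= rh_bound[1] | rh_knots >= rh_bound[2]) ||
        anyDuplicated(rh_knots)) {
      # degenerate humidity distribution: fall back to a single knot or linear
      rh_knots <- rh_knots[rh_knots > rh_bound[1] & rh_knots < rh_bound[2]]
      rh_knots <- unique(rh_knots)
    }
    if (diff(rh_bound) > 0) {
      rh_spec <- spline_spec("natural_cubic", rh_knots, rh_bound)
      RH <- ns_basis(rh, rh_spec)
      colnames(RH) <- paste0("rh.", seq_len(ncol(RH)))
      design <- cbind(design, RH)
    }
  }
  fit <- fit_conditional_logistic(dataset, design)
  cb_cols <- seq_len(ncol(cb$W))
  est <- dlnm_estimates(fit, cb, thresholds, cb_cols)
  structure(list(fit = fit, cb = cb, rh_spec = rh_spec, thresholds = thresholds,
                 estimates = est, cb_cols = cb_cols, L = L,
                 n_strata = fit$n_strata,
                 n_dropped_strata = attr(dataset, "n_dropped_strata")),
            class = "cco_dlnm")
}

dlnm_estimates <- function(fit, cb, thresholds, cb_cols) {
  p <- thresholds$p
  contrasts <- list()
  for (side in c("high", "low")) {
    xt <- unname(if (side == "high") p["p95"] else p["p5"])
    xr <- unname(p["p50"])
    contrasts[[paste0(side, "_cumulative")]] <- make_contrast(cb, xt, xr, "cumulative")
    for (l in 0:cb$L) {
      contrasts[[paste0(side, "_lag", l)]] <- make_contrast(cb, xt, xr, l)
    }
  }
  lapply(contrasts, function(a) predict_or(fit, a, cb_cols))
}

#' @export
print.cco_dlnm <- function(x, ...) {
  cat(sprintf("Case-crossover DLNM: %d strata (%d dropped for incomplete exposure), lags 0-%d\n",
              x$n_strata, x$n_dropped_strata, x$L))
  cat(sprintf("temperature spline: %d internal knot(s) at %s; lag basis: %s\n",
              length(x$cb$temp_spec$internal_knots),
              paste(round(x$cb$temp_spec$internal_knots, 2), collapse = ", "),
              x$cb$lag_spec$kind))
  for (nm in c("high_cumulative", "low_cumulative")) print(x$estimates[[nm]])
  invisible(x)
}

#' @export
summary.cco_dlnm <- function(object, ...) {
  out <- list(fit = summary(object$fit),
              estimates = object$estimates,
              thresholds = object$thresholds)
  class(out) <- "summary.cco_dlnm"
  out
}

#' @export
print.summary.cco_dlnm <- function(x, ...) {
  print(x$thresholds)
  cat("\n")
  for (e in x$estimates) print(e)
  cat("\n")
  print(x$fit)
  invisible(x)
}

#' @export
coef.cco_dlnm <- function(object, ...) stats::coef(object$fit)

#' @export
vcov.cco_dlnm <- function(object, ...) stats::vcov(object$fit)

#' @export
logLik.cco_dlnm <- function(object, ...) stats::logLik(object$fit)

#' Predict odds ratios from a fitted case-crossover DLNM
#'
#' @param object A `cco_dlnm`.
#' @param x_target Target temperature(s), degrees C.
#' @param x_ref Reference temperature; defaults to the model's centering
#'   value (the 50th percentile).
#' @param lags `"cumulative"` or a single lag index.
#' @param ... Unused.
#' @return A single `effect_estimate`, or a list of them for vector
#'   `x_target`.
#' @export
predict.cco_dlnm <- function(object, x_target, x_ref = object$cb$center,
                             lags = "cumulative", ...) {
  one <- function(xt) {
    a <- make_contrast(object$cb, xt, x_ref, lags)
    predict_or(object$fit, a, object$cb_cols)
  }
  if (length(x_target) == 1L) one(x_target) else lapply(x_target, one)
}

#' Plot the cumulative temperature-odds ratio curve
#'
#' Odds ratio (with pointwise 95% band) of the outcome over a grid of
#' temperatures against the model's reference temperature.
#'
#' @param x A `cco_dlnm`.
#' @param n_grid Number of grid points across the observed range.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cco_dlnm <- function(x, n_grid = 100L, ...) {
  grid <- seq(x$cb$temp_spec$boundary[1], x$cb$temp_spec$boundary[2],
              length.out = n_grid)
  est <- predict(x, grid)
  or <- vapply(est, function(e) e$or, numeric(1))
  lo <- vapply(est, function(e) e$ci95[1], numeric(1))
  hi <- vapply(est, function(e) e$ci95[2], numeric(1))
  graphics::plot(grid, or, type = "l", log = "y",
                 xlab = "daily mean temperature (deg C)",
                 ylab = "cumulative OR", ...)
  graphics::polygon(c(grid, rev(grid)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::lines(grid, or)
  graphics::abline(h = 1, lty = 2)
  graphics::abline(v = x$cb$center, lty = 3)
  invisible(x)
}
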