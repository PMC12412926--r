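#' Spline specification for the temperature or lag dimension
#'
#' A small container fixing everything needed to rebuild a basis
#' deterministically: the kind (`"natural_cubic"` or `"linear"`), the
#' internal knots, and the boundary knots.
#'
#' @param kind `"natural_cubic"` or `"linear"`.
#' @param internal_knots Numeric vector of internal knots, strictly inside
#'   the boundary, ascending; may be empty for `linear`.
#' @param boundary Length-2 numeric `c(min, max)`.
#' @return Object of class `spline_spec`.
#' @export
spline_spec <- function(kind = c("natural_cubic", "linear"),
                        internal_knots = numeric(), boundary) {
  kind <- match.arg(kind)
  if (missing(boundary) || length(boundary) != 2L || boundary[1] >= boundary[2]) {
    stop("boundary must be c(min, max) with min < max")
  }
  internal_knots <- sort(as.numeric(internal_knots))
  if (length(internal_knots) &&
      (min(internal_knots) <= boundary[1] || max(internal_knots) >= boundary[2])) {
    stop("internal knots must lie strictly inside the boundary")
  }
  structure(list(kind = kind, internal_knots = internal_knots,
                 boundary = as.numeric(boundary)),
            class = "spline_spec")
}

spline_df <- function(spec) {
  switch(spec$kind,
         natural_cubic = length(spec$internal_knots) + 1L,
         linear = 1L)
}

#' Natural cubic spline basis (no intercept)
#'
#' B-spline parameterisation of the natural cubic spline space: cubic
#' between knots, linear beyond the boundary knots (second derivative zero
#' at and outside the boundary), with `length(internal_knots) + 1` columns.
#' Deterministic given the spec, so a serialized spec rebuilds the same
#' basis on the same inputs.
#'
#' @param x Numeric vector of evaluation points.
#' @param spec A `spline_spec` with `kind = "natural_cubic"`.
#' @return Matrix with `length(x)` rows.
#' @export
ns_basis <- function(x, spec) {
  if (!inherits(spec, "spline_spec") || spec$kind != "natural_cubic") {
    stop("ns_basis requires a natural_cubic spline_spec")
  }
  b <- splines::ns(x, knots = spec$internal_knots,
                   Boundary.knots = spec$boundary, intercept = FALSE)
  m <- matrix(as.numeric(b), nrow = length(x))
  colnames(m) <- paste0("ns", seq_len(ncol(m)))
  m
}

#' Basis over the lag dimension
#'
#' `linear`: an intercept column plus the lag index, `[1, l]` for
#' `l = 0..L` (for `L = 0` the linear column is dropped and a single
#' intercept remains). `natural_cubic`: an intercept column plus a natural
#' cubic spline over the lag values.
#'
#' @param L Maximum lag (`>= 0`).
#' @param spec A `spline_spec` over lag values; for `natural_cubic` its
#'   boundary should be `c(0, L)`.
#' @return `(L + 1) x K` matrix, rows indexed by lag `0..L`.
#' @export
lag_basis <- function(L, spec) {
  stopifnot(L >= 0)
  lags <- 0:L
  if (spec$kind == "linear") {
    C <- if (L == 0L) matrix(1, 1L, 1L) else cbind(1, lags)
  } else {
    C <- cbind(1, ns_basis(lags, spec))
  }
  if (ncol(C) > L + 1L) {
    stop("lag basis over-parameterized: ", ncol(C), " columns for ", L + 1L, " lags")
  }
  rownames(C) <- paste0("lag", lags)
  colnames(C) <- paste0("l", seq_len(ncol(C)))
  C
}

#' Crossbasis design matrix for distributed-lag nonlinear models
#'
#' The tensor design combining a basis `B` over temperature with a basis
#' `C` over lag: `W[i, (j,k)] = sum_l B_j(x[i, l]) * C_k(l)`. Columns are
#' ordered with the lag index fastest (`t1.l1, t1.l2, ..., t2.l1, ...`).
#' The default model of the analysis — natural cubic spline with one
#' internal knot in temperature, linear term (with intercept) in lag, over
#' lags 0-1 — gives `2 x 2 = 4` columns.
#'
#' @param x_lag Numeric matrix of lagged exposures, `L + 1` columns
#'   (lag 0 first), complete rows.
#' @param temp_spec `spline_spec` for the temperature dimension
#'   (natural_cubic).
#' @param lag_spec `spline_spec` for the lag dimension.
#' @param center Reference temperature recorded for prediction (does not
#'   change the matrix; contrasts are differences of basis rows).
#' @return Object of class `crossbasis`: list with `W`, `temp_spec`,
#'   `lag_spec`, `L`, `center`, `temp_df`, `lag_df`.
#' @export
build_crossbasis <- function(x_lag, temp_spec, lag_spec, center = NULL) {
  x_lag <- as.matrix(x_lag)
  if (anyNA(x_lag)) stop("x_lag contains missing values; drop incomplete rows upstream")
  L <- ncol(x_lag) - 1L
  C <- lag_basis(L, lag_spec)
  J <- spline_df(temp_spec)
  K <- ncol(C)
  W <- matrix(0, nrow(x_lag), J * K)
  for (l in 0:L) {
    B <- ns_basis(x_lag[, l + 1L], temp_spec)
    for (j in seq_len(J)) {
      cols <- (j - 1L) * K + seq_len(K)
      W[, cols] <- W[, cols] + tcrossprod(B[, j], C[l + 1L, ])
    }
  }
  colnames(W) <- as.vector(t(outer(seq_len(J), seq_len(K),
                                   function(j, k) paste0("cb.t", j, ".l", k))))
  structure(list(W = W, temp_spec = temp_spec, lag_spec = lag_spec,
                 L = L, center = center, temp_df = J, lag_df = K),
            class = "crossbasis")
}

#' @export
print.crossbasis <- function(x, ...) {
  cat(sprintf("crossbasis: %d obs x %d cols (temp df %d x lag df %d), lags 0-%d\n",
              nrow(x$W), ncol(x$W), x$temp_df, x$lag_df, x$L))
  invisible(x)
}

#' Prediction contrast in crossbasis coefficient space
#'
#' The coefficient-space vector `a` such that `a' beta` is the log odds
#' ratio of exposure at `x_target` versus `x_ref` held over the selected
#' lags: `a[(j,k)] = (B_j(x_target) - B_j(x_ref)) * sum_{l in lags} C_k(l)`.
#' With `lags = "cumulative"` the sum runs over all lags 0..L; a single lag
#' gives that lag's contribution, and the cumulative contrast equals the
#' sum of the single-lag contrasts exactly.
#'
#' @param cb A `crossbasis` (only its specs are used).
#' @param x_target,x_ref Target and reference temperatures (degrees C).
#' @param lags `"cumulative"` or a single integer lag in `0..L`.
#' @return Object of class `cco_contrast`: numeric vector `a` with a
#'   `label` attribute.
#' @export
make_contrast <- function(cb, x_target, x_ref, lags = "cumulative") {
  stopifnot(inherits(cb, "crossbasis"))
  C <- lag_basis(cb$L, cb$lag_spec)
  if (identical(lags, "cumulative")) {
    csum <- colSums(C)
    lag_lab <- sprintf("cumulative 0-%d", cb$L)
  } else {
    l <- as.integer(lags)
    if (length(l) != 1L || l < 0L || l > cb$L) stop("lag index outside 0..", cb$L)
    csum <- C[l + 1L, ]
    lag_lab <- sprintf("lag %d", l)
  }
  db <- ns_basis(x_target, cb$temp_spec) - ns_basis(x_ref, cb$temp_spec)
  a <- as.vector(t(tcrossprod(as.numeric(db), csum)))
  # row-major over (j, k): lag index fastest, matching build_crossbasis
  structure(a, class = "cco_contrast",
            label = sprintf("%.1f vs %.1f C, %s", x_target, x_ref, lag_lab),
            x_target = x_target, x_ref = x_ref, lags = lags)
}

#' Serialize / rebuild a crossbasis specification
#'
#' The JSON round-trip stores kinds, knots, boundaries, maximum lag and
#' centering value; rebuilding from the spec on the same lagged exposures
#' reproduces the design matrix exactly.
#'
#' @param cb A `crossbasis`.
#' @return `cb_spec_json`: a JSON string.
#' @export
cb_spec_json <- function(cb) {
  jsonlite::toJSON(list(
    temp = list(kind = cb$temp_spec$kind, internal_knots = cb$temp_spec$internal_knots,
                boundary = cb$temp_spec$boundary),
    lag = list(kind = cb$lag_spec$kind, internal_knots = cb$lag_spec$internal_knots,
               boundary = cb$lag_spec$boundary),
    L = cb$L, center = cb$center
  ), auto_unbox = TRUE, digits = NA)
}

#' @rdname cb_spec_json
#' @param json JSON string from `cb_spec_json`.
#' @param x_lag Lagged exposure matrix to evaluate the rebuilt basis on.
#' @export
cb_from_json <- function(json, x_lag) {
  s <- jsonlite::fromJSON(json)
  ts <- spline_spec(s$temp$kind, s$temp$internal_knots, s$temp$boundary)
  ls <- spline_spec(s$lag$kind, s$lag$internal_knots, s$lag$boundary)
  build_crossbasis(x_lag, ts, ls, center = s$center)
}

#' AIC-driven scan over candidate temperature-knot placements
#'
#' Refits the full model once per candidate knot set and returns the
#' candidate minimising AIC `= -2 loglik + 2 k`; ties break toward the
#' first (lowest-percentile) candidate. Candidates failing to converge are
#' recorded and excluded from the argmin.
#'
#' @param candidates List (or vector) of candidate internal-knot vectors,
#'   in ascending order of position.
#' @param fit_fn Function taking one candidate and returning a fit with
#'   elements `loglik`, `k` and `converged`.
#' @return List with `best` (the selected candidate), `aic_table`
#'   (`data.frame` candidate / aic / converged).
#' @export
aic_knot_scan <- function(candidates, fit_fn) {
  if (!is.list(candidates)) candidates <- as.list(candidates)
  if (length(candidates) == 0L) stop("at least one candidate knot set required")
  rows <- lapply(candidates, function(kn) {
    fit <- fit_fn(kn)
    ok <- isTRUE(fit$converged)
    data.frame(candidate = paste(signif(kn, 6), collapse = ","),
               aic = if (ok) -2 * fit$loglik + 2 * fit$k else NA_real_,
               converged = ok, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!any(tab$converged)) stop("no candidate converged")
  best_i <- which(tab$aic == min(tab$aic, na.rm = TRUE))[1L]
  list(best = candidates[[best_i]], aic_table = tab)
}
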