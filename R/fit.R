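#' Conditional multinomial log-likelihood, score and information
#'
#' The shared likelihood of the matched-set models. Within stratum s with
#' event counts `y` over its rows and total `N_s = sum(y)`, the
#' contribution is `sum_d y_d z_d' beta - N_s log sum_d exp(z_d' beta)`:
#' for one case per stratum and binary `y` this is the conditional
#' logistic likelihood; for daily counts it is the conditional Poisson
#' (multinomial) likelihood.
#'
#' @param beta Coefficient vector.
#' @param X Design matrix.
#' @param y Event counts per row (0/1 for conditional logistic).
#' @param strata Integer stratum index per row.
#' @return List with `loglik`, `score`, `info` (observed information,
#'   i.e. negative Hessian).
#' @keywords internal
condlik_parts <- function(beta, X, y, strata) {
  eta <- drop(X %*% beta)
  # stabilise the within-stratum softmax
  smax <- vapply(split(eta, strata), max, numeric(1))
  sidx <- match(strata, as.integer(names(smax)))
  e <- exp(eta - smax[sidx])
  denom <- rowsum(e, strata)
  N_s <- rowsum(y, strata)
  p <- e / denom[sidx]
  mu <- N_s[sidx] * p
  loglik <- sum(y * eta) - sum(N_s * (log(denom) + smax))
  score <- drop(crossprod(X, y - mu))
  M <- rowsum(X * mu, strata) / sqrt(drop(N_s))
  info <- crossprod(X * sqrt(mu)) - crossprod(M)
  list(loglik = loglik, score = score, info = info, fitted = mu)
}

drop_stratum_constant <- function(X, strata, tol = 1e-10) {
  gm <- rowsum(X, strata) / as.vector(table(strata)[as.character(sort(unique(strata)))])
  sidx <- match(strata, sort(unique(strata)))
  dev <- abs(X - gm[sidx, , drop = FALSE])
  const <- apply(dev, 2, max) < tol
  const
}

#' Fit a matched-set conditional likelihood by Newton-Raphson
#'
#' Core fitter behind [fit_conditional_logistic()] and
#' [fit_conditional_poisson()]. Columns constant within every stratum are
#' unidentifiable under the conditional likelihood; they are detected and
#' dropped with a warning (their coefficients are reported as `NA`).
#' Newton-Raphson with step-halving; convergence when the maximum absolute
#' score falls below `1e-8` or the relative log-likelihood change below
#' `1e-10`; at most 50 iterations. Coefficients exceeding 15 in absolute
#' value trigger a separation flag.
#'
#' @param y Event count per row (0/1 for the logistic case).
#' @param X Design matrix (rows = observation days).
#' @param strata Stratum identifier per row.
#' @param dispersion `"fixed"` (phi = 1, conditional logistic) or
#'   `"pearson"` (quasi-likelihood: phi = Pearson X^2 / (n - k), covariance
#'   scaled by phi).
#' @param max_iter,tol_score,tol_loglik Newton-Raphson controls.
#' @return Object of class `cco_fit`: `beta` (full length, `NA` for
#'   dropped columns), `Sigma`, `loglik`, `k`, `converged`, `separation`,
#'   `n_strata`, `dispersion`, `kept` (logical column mask), `iter`.
#' @export
cco_fit <- function(y, X, strata, dispersion = c("fixed", "pearson"),
                    max_iter = 50L, tol_score = 1e-8, tol_loglik = 1e-10) {
  dispersion <- match.arg(dispersion)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  strata <- as.integer(factor(strata))
  if (length(y) != nrow(X) || length(strata) != nrow(X)) stop("y, X, strata lengths differ")
  if (sum(y) == 0) stop("no cases: every stratum has zero events")
  nz <- rowsum(y, strata)
  if (any(nz == 0)) {
    keep_s <- strata %in% which(nz > 0)
    n_zero <- sum(nz == 0)
    y <- y[keep_s]; X <- X[keep_s, , drop = FALSE]; strata <- as.integer(factor(strata[keep_s]))
  } else n_zero <- 0L
  const <- drop_stratum_constant(X, strata)
  if (any(const)) {
    warning("dropping ", sum(const), " column(s) constant within all strata: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  kept <- !const
  Xk <- X[, kept, drop = FALSE]
  k <- ncol(Xk)
  beta <- numeric(k)
  parts <- condlik_parts(beta, Xk, y, strata)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(parts$info, parts$score), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_parts <- condlik_parts(new_beta, Xk, y, strata)
    halved <- 0L
    while ((!is.finite(new_parts$loglik) || new_parts$loglik < parts$loglik) && halved < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_parts <- condlik_parts(new_beta, Xk, y, strata)
      halved <- halved + 1L
    }
    rel_change <- abs(new_parts$loglik - parts$loglik) /
      (abs(parts$loglik) + .Machine$double.eps)
    beta <- new_beta
    parts <- new_parts
    if (max(abs(parts$score)) < tol_score || rel_change < tol_loglik) {
      converged <- TRUE
      break
    }
  }
  separation <- any(abs(beta) > 15)
  if (!converged || separation) {
    warning("conditional likelihood fit ",
            if (separation) "shows signs of complete separation" else "did not converge")
  }
  Sigma_k <- tryCatch(solve(parts$info), error = function(e) matrix(NA_real_, k, k))
  phi <- 1
  if (dispersion == "pearson") {
    # Pearson X^2 with stratum-conditional fitted means; the residual df
    # counts the conditioned-out stratum intercepts among the parameters
    mu <- parts$fitted
    phi <- sum((y - mu)^2 / mu) / (length(y) - length(unique(strata)) - k)
    Sigma_k <- Sigma_k * phi
  }
  full_beta <- rep(NA_real_, ncol(X))
  names(full_beta) <- colnames(X)
  full_beta[kept] <- beta
  Sigma <- matrix(NA_real_, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  Sigma[kept, kept] <- Sigma_k
  structure(list(beta = full_beta, Sigma = Sigma, loglik = parts$loglik, k = k,
                 converged = converged, separation = separation,
                 n_strata = length(unique(strata)), n_obs = length(y),
                 dispersion = phi, kept = kept, iter = iter,
                 n_zero_strata_dropped = n_zero),
            class = "cco_fit")
}

#' @export
print.cco_fit <- function(x, ...) {
  cat(sprintf("Conditional likelihood fit: %d strata, %d rows, %d parameters\n",
              x$n_strata, x$n_obs, x$k))
  cat(sprintf("logLik %.4f  (converged: %s, %d iterations, dispersion %.3f)\n",
              x$loglik, x$converged, x$iter, x$dispersion))
  print(round(stats::coef(x), 4))
  invisible(x)
}

#' @export
coef.cco_fit <- function(object, ...) object$beta

#' @export
vcov.cco_fit <- function(object, ...) object$Sigma

#' @export
logLik.cco_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
summary.cco_fit <- function(object, ...) {
  se <- sqrt(diag(object$Sigma))
  tab <- data.frame(coef = object$beta, se = se, z = object$beta / se,
                    p = 2 * stats::pnorm(-abs(object$beta / se)))
  structure(list(coefficients = tab, fit = object), class = "summary.cco_fit")
}

#' @export
print.summary.cco_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Conditional logistic regression on a case-crossover dataset
#'
#' Maximises the conditional logistic likelihood over the matched strata
#' of a [expand_cases()] dataset given a design matrix (crossbasis columns
#' plus humidity-spline columns).
#'
#' @param dataset A `cco_dataset`.
#' @param design Design matrix with one row per dataset row.
#' @param ... Passed to [cco_fit()].
#' @return A `cco_fit`.
#' @export
fit_conditional_logistic <- function(dataset, design, ...) {
  stopifnot(nrow(design) == nrow(dataset))
  cco_fit(dataset$is_case, design, dataset$stratum_id, dispersion = "fixed", ...)
}

#' Conditional quasi-Poisson regression on aggregated daily counts
#'
#' The sensitivity estimator: daily case counts aggregated by stratum
#' (municipality x year x month x day-of-week), all-zero strata excluded
#' (their count is reported), conditional Poisson (multinomial) likelihood,
#' and Pearson overdispersion scaling of the covariance.
#'
#' @param counts Nonnegative integer vector of daily case counts.
#' @param design Design matrix, one row per stratum-day.
#' @param strata Stratum identifier per row.
#' @param ... Passed to [cco_fit()].
#' @return A `cco_fit` with `dispersion` = Pearson phi and
#'   `n_zero_strata_dropped`.
#' @export
fit_conditional_poisson <- function(counts, design, strata, ...) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  cco_fit(counts, design, strata, dispersion = "pearson", ...)
}

#' Odds ratio and confidence interval for a crossbasis contrast
#'
#' `log OR = a' beta_cb`, `se = sqrt(a' Sigma_cb a)` over the crossbasis
#' coefficient block only (humidity coefficients are adjustment terms and
#' never enter a contrast), with a normal 95% interval
#' `exp(log OR -/+ 1.96 se)`.
#'
#' @param fit A `cco_fit`.
#' @param contrast A `cco_contrast` from [make_contrast()].
#' @param cb_cols Indices (or names) of the crossbasis columns in the
#'   design; defaults to the first `length(contrast)` columns.
#' @return Object of class `effect_estimate`: list with `label`, `log_or`,
#'   `se`, `or`, `ci95`.
#' @export
predict_or <- function(fit, contrast, cb_cols = seq_along(contrast)) {
  a <- as.numeric(contrast)
  beta <- fit$beta[cb_cols]
  if (length(beta) != length(a)) stop("contrast length does not match crossbasis block")
  if (anyNA(beta)) {
    # dropped (stratum-constant) columns contribute nothing iff their weight is zero
    if (any(a[is.na(beta)] != 0)) {
      stop("contrast puts weight on dropped (stratum-constant) columns")
    }
    a <- a[!is.na(beta)]
    cb_cols <- cb_cols[!is.na(beta)]
    beta <- beta[!is.na(beta)]
  }
  Sig <- fit$Sigma[cb_cols, cb_cols, drop = FALSE]
  log_or <- sum(a * beta)
  se <- sqrt(drop(t(a) %*% Sig %*% a))
  structure(list(label = attr(contrast, "label"),
                 log_or = log_or, se = se, or = exp(log_or),
                 ci95 = exp(log_or + c(-1, 1) * 1.96 * se)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.2f (95%% CI %.2f-%.2f)\n",
              x$label, x$or, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Refit the model within levels of a case covariate
#'
#' Splits the case-crossover dataset by the case's covariate level and
#' refits the identical model specification in each level (same crossbasis
#' and humidity spline knots, for comparability). Levels with zero cases
#' are reported as absent.
#'
#' @param dataset A `cco_dataset` carrying the stratifier column.
#' @param stratifier Name of the covariate column.
#' @param fit_level Function `(subset_dataset) -> list(fit =, estimate =)`
#'   encapsulating the shared model spec (see [run_primary()] for the
#'   packaged one).
#' @return Named list per level: the `fit_level` result plus `n_strata`,
#'   or the string `"no cases"` for empty levels.
#' @export
fit_subgroups <- function(dataset, stratifier, fit_level) {
  if (!stratifier %in% names(dataset)) stop("stratifier not present: ", stratifier)
  col <- dataset[[stratifier]]
  levels_all <- if (is.factor(col)) levels(col) else sort(unique(stats::na.omit(col)))
  out <- list()
  for (lev in as.character(levels_all)) {
    strata_in <- unique(dataset$stratum_id[dataset$is_case == 1L &
                                             !is.na(dataset[[stratifier]]) &
                                             dataset[[stratifier]] == lev])
    if (length(strata_in) == 0L) {
      out[[lev]] <- "no cases"
      next
    }
    sub <- dataset[dataset$stratum_id %in% strata_in, , drop = FALSE]
    class(sub) <- class(dataset)
    attr(sub, "L") <- attr(dataset, "L")
    res <- fit_level(sub)
    res$n_strata <- length(strata_in)
    out[[lev]] <- res
  }
  out
}
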