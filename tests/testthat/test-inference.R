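test_that("matched-pair discordance recovers the closed-form log odds ratio", {
  # 1:1 pairs, binary exposure: 4 pairs case-exposed/control-unexposed,
  # 1 pair the reverse -> beta = log(4/1)
  X <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 0, 1), ncol = 1)
  y <- rep(c(1, 0), 5)
  strata <- rep(1:5, each = 2)
  fit <- cco_fit(y, X, strata)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), log(4), tolerance = 1e-6)
})

test_that("likelihood, score and information match brute-force enumeration", {
  set.seed(41)
  for (rep in 1:3) {
    sizes <- sample(2:5, 3, replace = TRUE)
    strata <- rep(seq_along(sizes), sizes)
    X <- matrix(rnorm(sum(sizes) * 2), ncol = 2)
    y <- as.integer(ave(seq_along(strata), strata, FUN = function(i) i == i[1]))
    beta <- rnorm(2, 0, 0.5)
    parts <- heatcco:::condlik_parts(beta, X, y, strata)
    f <- function(b) brute_condlik(b, X, y, strata)
    expect_equal(parts$loglik, f(beta), tolerance = 1e-8)
    expect_equal(parts$score, num_grad(f, beta), tolerance = 1e-6)
    expect_equal(unname(as.matrix(parts$info)), -num_hess(f, beta), tolerance = 1e-6)
  }
})

test_that("stratum-constant columns are dropped and leave the fit unchanged", {
  set.seed(42)
  strata <- rep(1:40, each = 4)
  X <- matrix(rnorm(160), ncol = 1)
  y <- as.integer(ave(seq_along(strata), strata, FUN = function(i) i == i[1]))
  fit0 <- cco_fit(y, X, strata)
  Xc <- cbind(X, const = strata * 2) # constant within every stratum
  expect_warning(fit1 <- cco_fit(y, Xc, strata), "constant within")
  expect_equal(unname(fit1$beta[1]), unname(fit0$beta[1]), tolerance = 1e-10)
  expect_true(is.na(fit1$beta[2]))
  expect_equal(fit1$loglik, fit0$loglik)
})

test_that("the fit agrees with an established conditional-logistic implementation", {
  skip_if_not_installed("survival")
  library(survival)
  study <- simulate_births(small_config(seed = 6))
  filt <- apply_lowrisk_filters(study$births)
  cls <- classify_outcome(filt$records$apgar5)
  cases <- filt$records[cls$low, c("birth_date", "municipality_id")]
  expo <- build_lagged_exposures(study$climate, 1L)
  ds <- expand_cases(cases, expo)
  X <- cbind(t0 = ds$x_lag0, t1 = ds$x_lag1, rh = ds$rh_mean)
  fit <- cco_fit(ds$is_case, X, ds$stratum_id)
  ref <- survival::clogit(is_case ~ x_lag0 + x_lag1 + rh_mean +
                            strata(stratum_id), data = as.data.frame(ds))
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(fit$Sigma)), unname(diag(vcov(ref))), tolerance = 1e-5)
  expect_equal(fit$loglik, unname(ref$loglik[2]), tolerance = 1e-6)
})

test_that("conditional logistic and conditional Poisson coincide on shared designs", {
  study <- simulate_births(small_config(seed = 9))
  filt <- apply_lowrisk_filters(study$births)
  cls <- classify_outcome(filt$records$apgar5)
  cases <- filt$records[cls$low, c("birth_date", "municipality_id")]
  expo <- build_lagged_exposures(study$climate, 1L)
  ds <- expand_cases(cases, expo)
  agg <- aggregate_counts(cases, expo)
  # one shared design spec evaluated on both row sets
  xs <- c(ds$x_lag0, ds$x_lag1)
  temp <- spline_spec("natural_cubic", median(xs), range(xs) + c(-1, 1))
  lags <- spline_spec("linear", boundary = c(-0.5, 1.5))
  cb_l <- build_crossbasis(as.matrix(ds[, c("x_lag0", "x_lag1")]), temp, lags)
  cb_p <- build_crossbasis(as.matrix(agg[, c("x_lag0", "x_lag1")]), temp, lags)
  fit_l <- fit_conditional_logistic(ds, cb_l$W)
  fit_p <- fit_conditional_poisson(agg$y, cb_p$W, agg$stratum)
  expect_equal(unname(fit_l$beta), unname(fit_p$beta), tolerance = 1e-6)
})

test_that("all-zero strata are excluded from the count model with an accounting", {
  X <- matrix(rnorm(12), ncol = 1)
  y <- c(1L, 0L, 2L, 1L, rep(0L, 4), 1L, 0L, 1L, 0L)
  strata <- rep(1:3, each = 4)
  fit <- fit_conditional_poisson(y, X, strata) # stratum 2 is all-zero
  expect_equal(fit$n_zero_strata_dropped, 1L)
  expect_equal(fit$n_strata, 2L)
})

test_that("Pearson dispersion is near one for Poisson-generated counts", {
  set.seed(44)
  n_strata <- 500
  strata <- rep(seq_len(n_strata), each = 4)
  x <- rnorm(length(strata))
  alpha <- rep(rnorm(n_strata, 0.3, 0.4), each = 4)
  y <- rpois(length(strata), exp(alpha + 0.1 * x))
  fit <- fit_conditional_poisson(y, cbind(x = x), strata)
  expect_true(fit$dispersion > 0.9 && fit$dispersion < 1.1)
  expect_lt(abs(unname(fit$beta) - 0.1), 3 * sqrt(fit$Sigma[1, 1]))
})

test_that("odds-ratio prediction reproduces the delta-method interval arithmetic", {
  fake <- structure(list(beta = c(cb = 0.0770), Sigma = matrix(0.0283^2, 1, 1),
                         kept = TRUE), class = "cco_fit")
  a <- structure(1, class = "cco_contrast", label = "scalar")
  est <- predict_or(fake, a, 1)
  expect_equal(round(est$or, 2), 1.08)
  expect_equal(round(est$ci95, 2), c(1.02, 1.14))
  # zero contrast -> OR exactly 1 with a degenerate interval
  a0 <- structure(0, class = "cco_contrast", label = "null")
  est0 <- predict_or(fake, a0, 1)
  expect_identical(est0$or, 1)
  expect_identical(est0$ci95, c(1, 1))
  # swapping target and reference inverts the OR exactly
  am <- structure(-1, class = "cco_contrast", label = "swapped")
  expect_equal(predict_or(fake, am, 1)$or, 1 / est$or)
  expect_error(predict_or(fake, structure(c(1, 1), class = "cco_contrast"), 1),
               "length")
})

test_that("effect contrasts are invariant to the spline parameterization", {
  study <- simulate_births(small_config(seed = 13))
  filt <- apply_lowrisk_filters(study$births)
  cls <- classify_outcome(filt$records$apgar5)
  cases <- filt$records[cls$low, c("birth_date", "municipality_id")]
  expo <- build_lagged_exposures(study$climate, 1L)
  ds <- expand_cases(cases, expo)
  x_lag <- as.matrix(ds[, c("x_lag0", "x_lag1")])
  xs <- as.vector(x_lag)
  knots_all <- c(min(xs), median(xs), max(xs))
  lagspec <- spline_spec("linear", boundary = c(-0.5, 1.5))
  # parameterization 1: the package basis
  temp <- spline_spec("natural_cubic", knots_all[2], knots_all[c(1, 3)])
  cb <- build_crossbasis(x_lag, temp, lagspec)
  fit1 <- fit_conditional_logistic(ds, cb$W)
  e1 <- predict_or(fit1, make_contrast(cb, quantile(xs, 0.95), median(xs)))
  # parameterization 2: truncated-power basis of the same spline space
  C <- lag_basis(1L, lagspec)
  tp <- function(v) ns_truncpow(v, knots_all)
  J <- ncol(tp(xs[1]))
  W2 <- matrix(0, nrow(x_lag), J * 2)
  for (l in 0:1) {
    B <- tp(x_lag[, l + 1])
    for (j in seq_len(J)) {
      W2[, (j - 1) * 2 + 1:2] <- W2[, (j - 1) * 2 + 1:2] + tcrossprod(B[, j], C[l + 1, ])
    }
  }
  suppressWarnings(fit2 <- cco_fit(ds$is_case, W2, ds$stratum_id))
  db <- tp(quantile(xs, 0.95)) - tp(median(xs))
  a2 <- structure(as.vector(t(tcrossprod(as.numeric(db), colSums(C)))),
                  class = "cco_contrast", label = "tp")
  e2 <- predict_or(fit2, a2, seq_len(ncol(W2)))
  expect_equal(e1$log_or, e2$log_or, tolerance = 1e-6)
  expect_equal(e1$se, e2$se, tolerance = 1e-6)
})

test_that("subgroup refits partition the strata and recover level-specific effects", {
  # single-level stratifier: estimate equals the unstratified fit
  study <- simulate_births(small_config(seed = 10))
  filt <- apply_lowrisk_filters(study$births)
  cls <- classify_outcome(filt$records$apgar5)
  cases <- filt$records[cls$low, c("birth_date", "municipality_id")]
  cases$grp <- "only"
  expo <- build_lagged_exposures(study$climate, 1L)
  ds <- expand_cases(cases, expo)
  fit_level <- function(sub) {
    X <- cbind(t0 = sub$x_lag0, t1 = sub$x_lag1)
    f <- cco_fit(sub$is_case, X, sub$stratum_id)
    list(beta = f$beta)
  }
  whole <- fit_level(ds)
  by_grp <- fit_subgroups(ds, "grp", fit_level)
  expect_equal(by_grp$only$beta, whole$beta)
  expect_equal(by_grp$only$n_strata, length(unique(ds$stratum_id)))
  # two levels: strata counts are conserved
  cases$grp <- rep_len(c("A", "B"), nrow(cases))
  ds2 <- expand_cases(cases, expo)
  two <- fit_subgroups(ds2, "grp", fit_level)
  expect_equal(two$A$n_strata + two$B$n_strata, length(unique(ds2$stratum_id)))
  # a level with zero cases is reported absent
  cases$grp[cases$grp == "B"] <- "A"
  cases$grp[1] <- "B"
  ds3 <- expand_cases(cases[cases$grp == "A", ], expo)
  ds3$grp <- factor(ds3$grp, levels = c("A", "B"))
  three <- fit_subgroups(ds3, "grp", fit_level)
  expect_identical(three$B, "no cases")
})

test_that("subgroup analysis recovers differing true effects per level", {
  # two studies with different injected effects, combined as two levels
  fit_level <- function(sub) {
    x_lag <- as.matrix(sub[, c("x_lag0", "x_lag1")])
    xs <- as.vector(x_lag)
    temp <- spline_spec("natural_cubic", median(xs), range(xs))
    lagspec <- spline_spec("linear", boundary = c(-0.5, 1.5))
    cb <- build_crossbasis(x_lag, temp, lagspec)
    fit <- cco_fit(sub$is_case, cb$W, sub$stratum_id)
    predict_or(fit, make_contrast(cb, quantile(xs, 0.95), median(xs)))
  }
  mk <- function(seed, effect, lev, offset) {
    study <- simulate_births(small_config(seed = seed, true_cum_logor = effect,
                                          daily_births_lambda = c(120, 90)))
    filt <- apply_lowrisk_filters(study$births)
    cls <- classify_outcome(filt$records$apgar5)
    cases <- filt$records[cls$low, c("birth_date", "municipality_id")]
    cases$grp <- lev
    expo <- build_lagged_exposures(study$climate, 1L)
    ds <- expand_cases(cases, expo)
    ds$stratum_id <- ds$stratum_id + offset
    ds
  }
  dsA <- mk(15, 0.5, "A", 0)
  dsB <- mk(16, 0.0, "B", 1e6)
  ds <- rbind(dsA, dsB)
  class(ds) <- class(dsA)
  out <- fit_subgroups(ds, "grp", fit_level)
  # level A carries the effect, level B is null, within simulation error
  expect_true(abs(out$A$log_or - 0.5) < 2.5 * out$A$se)
  expect_true(abs(out$B$log_or) < 2.5 * out$B$se)
  expect_true(out$A$log_or - out$B$log_or > 2 * sqrt(out$A$se^2 + out$B$se^2))
})

test_that("case-crossover estimates stay null under pure calendar confounding", {
  cfg <- small_config(seed = 17, true_cum_logor = 0,
                      month_effects = 0.6 * cos(2 * pi * (1:12 - 1) / 12),
                      daily_births_lambda = c(150, 110))
  res <- pipeline_high_cum(cfg)
  expect_true(abs(res$log_or / res$se) < 3)
})
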