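# shared fixtures: small study configurations and a one-call pipeline estimate

small_config <- function(seed = 1L, daily_births_lambda = c(35, 25),
                         study_start = "2015-01-01", study_end = "2015-12-31",
                         baseline_event_rate = 0.02, frac_nonlowrisk = 0,
                         frac_missing_apgar = 0, ...) {
  sim_config(n_municipalities = 2L,
             study_start = study_start, study_end = study_end,
             daily_births_lambda = daily_births_lambda,
             baseline_event_rate = baseline_event_rate,
             frac_nonlowrisk = frac_nonlowrisk,
             frac_missing_apgar = frac_missing_apgar,
             seed = seed, ...)
}

# run the whole pipeline on a simulated study and return the cumulative
# high-vs-moderate estimate (the primary quantity of the analysis)
pipeline_high_cum <- function(cfg) {
  rc <- run_config(simulation = cfg)
  prep <- heatcco:::prepare_study(rc)
  cases <- prep$cohort[prep$cohort$low_apgar, , drop = FALSE]
  m <- cco_dlnm(cases, prep$exposures, prep$thresholds)
  e <- m$estimates$high_cumulative
  list(log_or = e$log_or, se = e$se, model = m, truth = prep$truth)
}

# a minimal valid registry row, with overridable fields
registry_row <- function(...) {
  base <- list(birth_date = "2015-06-15", municipality_id = "M01", apgar5 = 9,
               birthweight_g = 3200, gest_weeks = 39, plurality = "singleton",
               presentation = "cephalic", anomaly = "no",
               maternal_age_years = 28, education_cat = "<12y", race = "White",
               parity_cat = "nulliparous", prenatal_start = "first_trimester",
               sex = "male", ibp_quintile = 2, koppen = "Cfb")
  utils::modifyList(base, list(...))
}

make_registry <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# independent natural cubic spline oracle: truncated-power construction
# over all knots (boundary included), spanning the same space as ns_basis
# plus an intercept
ns_truncpow <- function(x, knots_all) {
  m <- length(knots_all)
  d <- function(k) {
    (pmax(x - knots_all[k], 0)^3 - pmax(x - knots_all[m], 0)^3) /
      (knots_all[m] - knots_all[k])
  }
  cols <- cbind(1, x)
  for (k in seq_len(m - 2L)) cols <- cbind(cols, d(k) - d(m - 1L))
  cols
}

# direct enumeration of the stratum-softmax conditional likelihood
brute_condlik <- function(beta, X, y, strata) {
  sum(vapply(unique(strata), function(s) {
    i <- strata == s
    eta <- drop(X[i, , drop = FALSE] %*% beta)
    sum(y[i] * eta) - sum(y[i]) * log(sum(exp(eta)))
  }, numeric(1)))
}

num_grad <- function(f, beta, eps = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- replace(numeric(length(beta)), j, eps)
    (f(beta + e) - f(beta - e)) / (2 * eps)
  }, numeric(1))
}

num_hess <- function(f, beta, eps = 1e-4) {
  k <- length(beta)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ei <- replace(numeric(k), i, eps)
    ej <- replace(numeric(k), j, eps)
    H[i, j] <- (f(beta + ei + ej) - f(beta + ei - ej) -
                  f(beta - ei + ej) + f(beta - ei - ej)) / (4 * eps^2)
  }
  (H + t(H)) / 2
}
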