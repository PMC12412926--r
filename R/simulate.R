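#' Configuration for the synthetic study generator
#'
#' Describes the synthetic stand-in for a linked birth-registry + climate
#' study: municipality climates (mean level, seasonal amplitude, AR(1)
#' day-to-day noise, dewpoint depression), daily birth volumes, covariate
#' marginals, a rare baseline event rate, calendar (month-level)
#' confounding of the outcome, and a known injected temperature effect.
#' The injected effect is linear in temperature and distributed over lags
#' by `lag_weights`, scaled so that the cumulative log odds ratio of the
#' 95th-vs-50th population-weighted percentile contrast equals
#' `true_cum_logor` exactly (a linear response lies in the span of the
#' natural cubic spline used downstream, so it is the recovery target).
#' The seasonal phase peaks in mid-January (Southern Hemisphere).
#'
#' Defaults describe the study conditions used throughout the package:
#' 10 municipalities, three years, ~274 births/day in total (~300k
#' births), baseline event rate 1.1%, cumulative log-OR 0.2 with lag
#' weights (0.7, 0.3), and mild month-level confounding.
#'
#' @param n_municipalities Number of municipalities.
#' @param population_weights Positive weights (recycled), used for
#'   population-weighted percentiles.
#' @param study_start,study_end Study window (`Date` or string).
#' @param temp_mean Per-municipality mean temperature, degrees C (recycled).
#' @param seasonal_amplitude Seasonal half-range, degrees C (recycled).
#' @param ar1_rho AR(1) autocorrelation of daily temperature, in `[0, 1)`.
#' @param ar1_sigma AR(1) innovation SD, degrees C.
#' @param dewpoint_depression_mean Mean of the (nonnegative, noisy)
#'   air-minus-dewpoint gap, degrees C.
#' @param daily_births_lambda Poisson mean births/day per municipality
#'   (recycled).
#' @param baseline_event_rate Baseline probability of the rare outcome.
#' @param month_effects Length-12 log-odds offsets by calendar month.
#' @param true_cum_logor Injected cumulative log odds ratio for the
#'   95th-vs-50th percentile contrast (0 for a null study).
#' @param lag_weights Nonnegative weights over lags `0..length-1`, summing
#'   to 1, splitting the injected effect across lags.
#' @param covariate_marginals Named list of named probability vectors for
#'   the categorical covariates.
#' @param subcat_probs Probabilities of low-score subcategories 0-2 / 3-5
#'   / 6-7 among events.
#' @param frac_nonlowrisk Fraction of births given a low-risk-violating
#'   field (to exercise the exclusion cascade).
#' @param frac_missing_apgar Fraction of births with missing Apgar score.
#' @param lag_history Days of climate history generated before
#'   `study_start` so all lag structures are computable from day one.
#' @param seed Integer seed; the same config always yields the same study.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_municipalities = 10L,
                       population_weights = NULL,
                       study_start = "2015-01-01",
                       study_end = "2017-12-31",
                       temp_mean = seq(24, 17, length.out = n_municipalities),
                       seasonal_amplitude = 5.5,
                       ar1_rho = 0.65,
                       ar1_sigma = 2.2,
                       dewpoint_depression_mean = 4,
                       daily_births_lambda = NULL,
                       baseline_event_rate = 0.011,
                       month_effects = 0.15 * cos(2 * pi * (1:12 - 1) / 12),
                       true_cum_logor = 0.2,
                       lag_weights = c(0.7, 0.3),
                       covariate_marginals = default_covariate_marginals(),
                       subcat_probs = c("0-2" = 0.107, "3-5" = 0.15, "6-7" = 0.743),
                       frac_nonlowrisk = 0.03,
                       frac_missing_apgar = 0.002,
                       lag_history = 7L,
                       seed = 1L) {
  if (is.null(daily_births_lambda)) {
    daily_births_lambda <- 274 * (n_municipalities:1) / sum(n_municipalities:1)
  }
  if (is.null(population_weights)) population_weights <- daily_births_lambda
  cfg <- list(
    n_municipalities = as.integer(n_municipalities),
    municipality_id = sprintf("M%02d", seq_len(n_municipalities)),
    population_weights = rep_len(population_weights, n_municipalities),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    temp_mean = rep_len(temp_mean, n_municipalities),
    seasonal_amplitude = rep_len(seasonal_amplitude, n_municipalities),
    ar1_rho = ar1_rho, ar1_sigma = ar1_sigma,
    dewpoint_depression_mean = dewpoint_depression_mean,
    daily_births_lambda = rep_len(daily_births_lambda, n_municipalities),
    baseline_event_rate = baseline_event_rate,
    month_effects = rep_len(month_effects, 12L),
    true_cum_logor = true_cum_logor,
    lag_weights = lag_weights,
    covariate_marginals = covariate_marginals,
    subcat_probs = subcat_probs,
    frac_nonlowrisk = frac_nonlowrisk,
    frac_missing_apgar = frac_missing_apgar,
    lag_history = as.integer(lag_history),
    seed = as.integer(seed)
  )
  nums <- c(cfg$population_weights, cfg$temp_mean, cfg$seasonal_amplitude,
            cfg$ar1_rho, cfg$ar1_sigma, cfg$dewpoint_depression_mean,
            cfg$daily_births_lambda, cfg$baseline_event_rate,
            cfg$month_effects, cfg$true_cum_logor, cfg$lag_weights)
  if (any(!is.finite(nums))) stop("non-finite simulation parameters")
  if (any(cfg$population_weights <= 0)) stop("population weights must be positive")
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  if (cfg$baseline_event_rate < 0 || cfg$baseline_event_rate > 1) {
    stop("baseline_event_rate must lie in [0, 1]")
  }
  if (cfg$study_end < cfg$study_start) stop("study_end before study_start")
  if (any(cfg$lag_weights < 0) || abs(sum(cfg$lag_weights) - 1) > 1e-8) {
    stop("lag_weights must be nonnegative and sum to 1")
  }
  structure(cfg, class = "sim_config")
}

#' Covariate category probabilities resembling a low-risk birth cohort
#' @keywords internal
default_covariate_marginals <- function() {
  list(
    maternal_age_cat = c("<20y" = 0.13, "20-34y" = 0.71, ">=35y" = 0.16),
    education_cat = c("<12y" = 0.75, ">=12y" = 0.25),
    race = c(White = 0.57, Brown = 0.36, Black = 0.06, Asian = 0.007,
             Indigenous = 0.003),
    parity_cat = c(nulliparous = 0.46, primiparous = 0.33, multiparous = 0.21),
    prenatal_start = c(first_trimester = 0.86, delayed = 0.14),
    sex = c(male = 0.51, female = 0.49),
    ibp_quintile = c("1" = 0.355, "2" = 0.504, "3" = 0.129, "4" = 0.012),
    koppen = c(Af = 0.043, Aw = 0.064, Cfa = 0.208, Cfb = 0.563,
               Cwa = 0.111, Cwb = 0.011)
  )
}

#' Simulate municipality-level daily climate
#'
#' Per municipality, a complete daily series from `study_start -
#' lag_history` to `study_end`: daily mean temperature is mean level +
#' seasonal sinusoid peaking in mid-January + AR(1) noise; dewpoint is the
#' temperature minus a noisy nonnegative depression; relative humidity is
#' derived via [tetens_rh()] (so RH is in `[0, 100]` by construction).
#'
#' @param config A [sim_config()].
#' @return Climate `data.frame` (`municipality_id`, `date`, `tmean_c`,
#'   `rh_pct`), one row per municipality-day.
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dates <- seq(config$study_start - config$lag_history, config$study_end, by = "1 day")
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1L
  seasonal <- cos(2 * pi * (doy - 15) / 365.25)
  out <- vector("list", config$n_municipalities)
  for (m in seq_len(config$n_municipalities)) {
    if (config$ar1_sigma > 0) {
      innov <- stats::rnorm(n, 0, config$ar1_sigma)
      ar <- as.numeric(stats::filter(innov, config$ar1_rho, method = "recursive"))
    } else ar <- numeric(n)
    tmean <- config$temp_mean[m] + config$seasonal_amplitude[m] * seasonal + ar
    depression <- pmax(0, stats::rnorm(n, config$dewpoint_depression_mean, 1.5))
    td <- tmean - depression
    rh <- tetens_rh(tmean, td)
    out[[m]] <- data.frame(municipality_id = config$municipality_id[m],
                           date = dates, tmean_c = tmean, rh_pct = rh,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate hourly temperatures for one municipality-day series
#'
#' The optional hourly mode: each daily value plus a diurnal sinusoid
#' (peak mid-afternoon) whose hourly values average exactly to the daily
#' mean, for exercising hourly-to-daily aggregation.
#'
#' @param daily `data.frame` with `date` and `value` (daily means).
#' @param diurnal_amplitude Half-range of the diurnal cycle.
#' @return `data.frame` with `timestamp` (POSIXct, UTC) and `value`.
#' @export
simulate_hourly_from_daily <- function(daily, diurnal_amplitude = 4) {
  hours <- 0:23
  cyc <- cos(2 * pi * (hours - 15) / 24)
  cyc <- cyc - mean(cyc) # exact zero-mean so daily means are preserved
  out <- data.frame(
    timestamp = rep(as.POSIXct(daily$date, tz = "UTC"), each = 24L) + hours * 3600,
    value = rep(daily$value, each = 24L) + diurnal_amplitude * rep_len(cyc, 24L * nrow(daily))
  )
  out
}

#' Simulate a linked birth registry over a climate table
#'
#' Daily birth counts are Poisson per municipality; covariates are drawn
#' from the configured marginals; the rare outcome indicator is Bernoulli
#' with log-odds = logit(baseline) + month effect + injected temperature
#' effect (linear in temperature, distributed over lags by the configured
#' weights, scaled to the configured cumulative log-OR for the
#' 95th-vs-50th population-weighted percentile contrast). Low scores are
#' split across subcategories 0-2 / 3-5 / 6-7 by the configured
#' proportions; other births score 8-10. A configured fraction of births
#' receives a low-risk-violating field or a missing Apgar score so the
#' exclusion cascade has work to do; the injected effect applies to all
#' births alike.
#'
#' @param config A [sim_config()].
#' @param climate Climate table covering the study window plus lag
#'   history (defaults to `simulate_climate(config)`).
#' @return Object of class `simulated_study`: list with `climate`,
#'   `births` (registry `data.frame`), and `truth` (realized percentiles,
#'   slope, cumulative and per-lag log-ORs, and the config echo).
#' @export
simulate_births <- function(config, climate = simulate_climate(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L_eff <- length(config$lag_weights) - 1L
  dates <- seq(config$study_start, config$study_end, by = "1 day")
  need <- seq(config$study_start - L_eff, config$study_end, by = "1 day")
  ckey <- paste(climate$municipality_id, climate$date)
  for (m in config$municipality_id) {
    if (!all(paste(m, need) %in% ckey)) {
      stop("climate does not cover lags 0..", L_eff, " for municipality ", m)
    }
  }
  in_window <- climate$date >= config$study_start & climate$date <= config$study_end
  thr <- percentile_thresholds(climate[in_window, , drop = FALSE],
                               stats::setNames(config$population_weights,
                                               config$municipality_id))
  p50 <- unname(thr$p["p50"]); p95 <- unname(thr$p["p95"])
  slope <- if (p95 > p50) config$true_cum_logor / (p95 - p50) else 0
  # per municipality-day linear predictor of the event probability
  grid <- expand.grid(date = dates, municipality_id = config$municipality_id,
                      stringsAsFactors = FALSE)
  tmat <- matrix(NA_real_, nrow(grid), L_eff + 1L)
  for (l in 0:L_eff) {
    tmat[, l + 1L] <- climate$tmean_c[match(paste(grid$municipality_id, grid$date - l), ckey)]
  }
  month <- as.POSIXlt(grid$date)$mon + 1L
  eta <- stats::qlogis(min(max(config$baseline_event_rate, 1e-12), 1 - 1e-12)) +
    config$month_effects[month] +
    drop((tmat - p50) %*% (slope * config$lag_weights))
  p_event <- stats::plogis(eta)
  if (config$baseline_event_rate == 0) p_event[] <- 0
  lambda <- config$daily_births_lambda[match(grid$municipality_id, config$municipality_id)]
  n_births <- stats::rpois(nrow(grid), lambda)
  total <- sum(n_births)
  if (total == 0L) stop("no births simulated; increase daily_births_lambda")
  row_idx <- rep.int(seq_len(nrow(grid)), n_births)
  births <- data.frame(
    birth_date = grid$date[row_idx],
    municipality_id = grid$municipality_id[row_idx],
    stringsAsFactors = FALSE
  )
  event <- stats::rbinom(total, 1L, p_event[row_idx])
  apgar <- integer(total)
  n_ev <- sum(event)
  if (n_ev) {
    sub <- sample(c(1L, 4L, 6L), n_ev, replace = TRUE, prob = config$subcat_probs)
    apgar[event == 1L] <- sub + stats::rbinom(n_ev, 1L, 0.5) # 0-2 -> {1,2}, 3-5 -> {4,5}, 6-7 -> {6,7}
  }
  apgar[event == 0L] <- sample(8:10, total - n_ev, replace = TRUE,
                               prob = c(0.10, 0.45, 0.45))
  births$apgar5 <- apgar
  cm <- config$covariate_marginals
  draw <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
  age_cat <- draw(cm$maternal_age_cat, total)
  births$maternal_age_years <- ifelse(age_cat == "<20y", sample(14:19, total, TRUE),
                               ifelse(age_cat == "20-34y", sample(20:34, total, TRUE),
                                      sample(35:45, total, TRUE)))
  births$education_cat <- draw(cm$education_cat, total)
  births$race <- draw(cm$race, total)
  births$parity_cat <- draw(cm$parity_cat, total)
  births$prenatal_start <- draw(cm$prenatal_start, total)
  births$sex <- draw(cm$sex, total)
  births$ibp_quintile <- as.integer(draw(cm$ibp_quintile, total))
  births$koppen <- draw(cm$koppen, total)
  # low-risk fields: defaults inside range, a configured fraction violates one
  births$plurality <- "singleton"
  births$birthweight_g <- round(stats::rnorm(total, 3250, 280))
  births$birthweight_g <- pmin(pmax(births$birthweight_g, 2500), 4000)
  births$gest_weeks <- sample(37:41, total, replace = TRUE,
                              prob = c(0.08, 0.18, 0.34, 0.30, 0.10))
  births$presentation <- "cephalic"
  births$anomaly <- "no"
  n_bad <- round(config$frac_nonlowrisk * total)
  if (n_bad > 0) {
    bad <- sample.int(total, n_bad)
    kind <- sample(5L, n_bad, replace = TRUE)
    births$birthweight_g[bad[kind == 1L]] <- sample(c(2100, 4300), sum(kind == 1L), replace = TRUE)
    births$gest_weeks[bad[kind == 2L]] <- sample(c(34:36, 42L), sum(kind == 2L), replace = TRUE)
    births$anomaly[bad[kind == 3L]] <- "yes"
    births$presentation[bad[kind == 4L]] <- "other"
    births$plurality[bad[kind == 5L]] <- "multiple"
  }
  n_napg <- round(config$frac_missing_apgar * total)
  if (n_napg > 0) births$apgar5[sample.int(total, n_napg)] <- NA_integer_
  births <- births[, c("birth_date", "municipality_id", "apgar5", "birthweight_g",
                       "gest_weeks", "plurality", "presentation", "anomaly",
                       "maternal_age_years", "education_cat", "race", "parity_cat",
                       "prenatal_start", "sex", "ibp_quintile", "koppen")]
  truth <- list(
    thresholds = thr, slope_per_c = slope,
    cum_logor_95_vs_50 = config$true_cum_logor,
    lag_logor_95_vs_50 = slope * config$lag_weights * (p95 - p50),
    config = config
  )
  structure(list(climate = climate, births = births, truth = truth),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d births, %d municipality-days of climate\n",
              nrow(x$births), nrow(x$climate)))
  cat(sprintf("injected cumulative log-OR (p95 vs p50): %.3f\n",
              x$truth$cum_logor_95_vs_50))
  invisible(x)
}

#' Write a simulated study to CSV + JSON sidecar
#'
#' Registry and climate CSVs in the package schemas, plus `truth.json`
#' recording the injected effect and realized thresholds.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- file.path(dir, "registry.csv")
  cli <- file.path(dir, "climate.csv")
  tr <- file.path(dir, "truth.json")
  utils::write.csv(study$births, reg, row.names = FALSE)
  write_climate(study$climate, cli)
  jsonlite::write_json(list(
    cum_logor_95_vs_50 = study$truth$cum_logor_95_vs_50,
    lag_logor_95_vs_50 = study$truth$lag_logor_95_vs_50,
    slope_per_c = study$truth$slope_per_c,
    thresholds = as.list(study$truth$thresholds$p),
    seed = study$truth$config$seed
  ), tr, auto_unbox = TRUE, digits = NA)
  invisible(c(registry = reg, climate = cli, truth = tr))
}
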