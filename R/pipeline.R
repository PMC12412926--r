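#' Assemble a pipeline run configuration
#'
#' Exactly one of a simulation block or a set of input paths must be
#' given. Model defaults are the "paper-primary" profile: lags 0-1,
#' natural cubic spline with one internal knot in temperature, linear lag
#' term, humidity spline with 3 df, percentiles 5/50/95.
#'
#' @param simulation A [sim_config()], a list of [sim_config()] arguments,
#'   or `NULL`.
#' @param inputs List with paths `registry`, `climate`, `metadata`
#'   (metadata CSV: `municipality_id`, `population`, and optionally
#'   `in_state` 0/1), or `NULL`.
#' @param model List overriding model defaults: `L`, `temp_knots`,
#'   `knot_scan` (candidate percentiles), `lag_kind`, `rh_df`, `probs`.
#' @param subgroups Character vector of covariate columns to stratify by.
#' @param sensitivity Character vector of sensitivity variant names.
#' @param outdir Output directory or `NULL` for no file output.
#' @param seed Seed overriding the simulation block's.
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, inputs = NULL, model = list(),
                       subgroups = character(), sensitivity = character(),
                       outdir = NULL, seed = NULL) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("exactly one of a simulation block or input paths is required")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  if (!is.null(seed) && !is.null(simulation)) simulation$seed <- as.integer(seed)
  defaults <- list(L = 1L, temp_knots = NULL, knot_scan = NULL,
                   lag_kind = "linear", lag_knots = NULL, humidity = TRUE,
                   rh_df = 3L, probs = c(0.05, 0.5, 0.95))
  model <- utils::modifyList(defaults, model)
  if (is.unsorted(model$probs)) stop("percentile probs must be ascending")
  structure(list(simulation = simulation, inputs = inputs, model = model,
                 subgroups = subgroups, sensitivity = sensitivity,
                 outdir = outdir, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

# Stage 1-3: obtain data, thresholds, cohort, exposures
prepare_study <- function(config, lowrisk = TRUE) {
  if (!is.null(config$simulation)) {
    study <- simulate_births(config$simulation)
    climate <- study$climate
    registry <- study$births
    weights <- stats::setNames(config$simulation$population_weights,
                               config$simulation$municipality_id)
    state <- config$simulation$municipality_id
    truth <- study$truth
  } else {
    registry <- read_registry(config$inputs$registry)
    climate <- read_climate(config$inputs$climate)
    meta <- utils::read.csv(config$inputs$metadata, stringsAsFactors = FALSE)
    weights <- stats::setNames(meta$population, meta$municipality_id)
    state <- if ("in_state" %in% names(meta)) {
      meta$municipality_id[meta$in_state == 1]
    } else meta$municipality_id
    truth <- NULL
  }
  window <- range(as.Date(registry$birth_date), na.rm = TRUE)
  in_window <- climate$date >= window[1] & climate$date <= window[2]
  thresholds <- percentile_thresholds(climate[in_window, , drop = FALSE],
                                      weights, probs = config$model$probs)
  filt <- apply_lowrisk_filters(registry, state_municipalities = state)
  cohort <- if (lowrisk) filt$records else {
    # less-restricted sample: singleton, in-state, Apgar present only
    d <- registry
    d <- d[!is.na(d$plurality) & d$plurality == "singleton", , drop = FALSE]
    d <- d[as.character(d$municipality_id) %in% state, , drop = FALSE]
    d <- d[!is.na(d$apgar5), , drop = FALSE]
    d
  }
  outcome <- classify_outcome(cohort$apgar5)
  cohort$outcome_category <- outcome$category
  cohort$low_apgar <- outcome$low
  exposures <- build_lagged_exposures(climate, config$model$L)
  list(climate = climate, registry = registry, cohort = cohort,
       flowchart = filt$flowchart, thresholds = thresholds,
       exposures = exposures, weights = weights, truth = truth)
}

fit_outcome_block <- function(cases, prep, model) {
  if (nrow(cases) == 0L) return("no cases")
  cco_dlnm(cases, prep$exposures, prep$thresholds, L = model$L,
           temp_knots = model$temp_knots, lag_kind = model$lag_kind,
           lag_knots = model$lag_knots, humidity = model$humidity,
           rh_df = model$rh_df)
}

estimates_table <- function(est) {
  if (identical(est, "no cases")) return("no cases")
  do.call(rbind, lapply(names(est), function(nm) {
    e <- est[[nm]]
    data.frame(contrast = nm, label = e$label, log_or = e$log_or, se = e$se,
               or = e$or, ci_low = e$ci95[1], ci_high = e$ci95[2],
               stringsAsFactors = FALSE)
  }))
}

#' Run the primary analysis pipeline end to end
#'
#' Simulate (or read) the study data, compute population-weighted
#' percentile thresholds, apply the low-risk exclusion cascade, build
#' lagged exposures, expand cases into time-stratified strata, and fit the
#' case-crossover DLNM for the primary outcome (score of 7 or below) and
#' each subcategory (6-7, 3-5, 0-2), plus any requested subgroup refits.
#' The same model terms are used for every outcome block.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: thresholds, per-outcome model
#'   objects and estimate tables, subgroup estimates, flowchart, stratum
#'   accounting, the daily case-rate series, and provenance. When
#'   `config$outdir` is set the report is also written to disk by
#'   [write_report()].
#' @export
run_primary <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prep <- prepare_study(config)
  model <- config$model
  cohort <- prep$cohort
  if (!is.null(model$knot_scan)) {
    cases_all <- cohort[cohort$low_apgar, , drop = FALSE]
    if (nrow(cases_all)) {
      ds <- expand_cases(cases_all, prep$exposures, model$L)
      xs <- as.vector(as.matrix(ds[, paste0("x_lag", 0:model$L)]))
      cand <- lapply(model$knot_scan, function(p) stats::quantile(xs, p / 100, names = FALSE))
      scan <- aic_knot_scan(cand, function(kn) {
        cco_dlnm(ds, thresholds = prep$thresholds, L = model$L, temp_knots = kn,
                 lag_kind = model$lag_kind, humidity = model$humidity)$fit
      })
      model$temp_knots <- scan$best
    }
  }
  blocks <- list()
  outcomes <- list(low_apgar = cohort$low_apgar,
                   `6-7` = cohort$outcome_category == "6-7",
                   `3-5` = cohort$outcome_category == "3-5",
                   `0-2` = cohort$outcome_category == "0-2")
  for (nm in names(outcomes)) {
    cases <- cohort[outcomes[[nm]], , drop = FALSE]
    blocks[[nm]] <- fit_outcome_block(cases, prep, model)
  }
  subgroup_est <- list()
  if (length(config$subgroups) && !identical(blocks$low_apgar, "no cases")) {
    main <- blocks$low_apgar
    cases_all <- cohort[cohort$low_apgar, , drop = FALSE]
    ds <- expand_cases(cases_all, prep$exposures, model$L)
    rh_knots <- if (!is.null(main$rh_spec)) main$rh_spec$internal_knots else NULL
    for (sg in config$subgroups) {
      subgroup_est[[sg]] <- fit_subgroups(ds, sg, function(sub) {
        m <- cco_dlnm(sub, thresholds = prep$thresholds, L = model$L,
                      temp_knots = main$cb$temp_spec$internal_knots,
                      lag_kind = model$lag_kind, humidity = model$humidity,
                      rh_knots = rh_knots)
        list(estimates = estimates_table(m$estimates))
      })
    }
  }
  # daily case-rate series for external seasonal plotting
  daily <- stats::aggregate(cbind(n_births = rep(1L, nrow(cohort)),
                                  n_cases = as.integer(cohort$low_apgar)) ~ birth_date,
                            data = cohort, FUN = sum)
  daily$rate_pct <- 100 * daily$n_cases / daily$n_births
  report <- structure(list(
    thresholds = prep$thresholds,
    outcomes = lapply(blocks, function(b) {
      if (identical(b, "no cases")) "no cases" else list(
        estimates = estimates_table(b$estimates),
        n_strata = b$n_strata, n_dropped_strata = b$n_dropped_strata,
        temp_knots = b$cb$temp_spec$internal_knots,
        loglik = b$fit$loglik, k = b$fit$k, converged = b$fit$converged)
    }),
    models = blocks,
    subgroups = subgroup_est,
    flowchart = prep$flowchart,
    daily_rate = daily,
    truth = prep$truth,
    provenance = list(package = "heatcco",
                      version = as.character(utils::packageVersion("heatcco")),
                      r_version = R.version.string,
                      seed = if (!is.null(config$simulation)) config$simulation$seed else NA,
                      date = NA)
  ), class = "run_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Case-crossover DLNM run report\n")
  print(x$thresholds)
  for (nm in names(x$outcomes)) {
    cat("\n[", nm, "]\n", sep = "")
    b <- x$outcomes[[nm]]
    if (identical(b, "no cases")) cat("no cases\n")
    else print(b$estimates[, c("contrast", "or", "ci_low", "ci_high")], digits = 3)
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' `report.json` (thresholds, estimates, flowchart, provenance),
#' `estimates_<outcome>.csv` coefficient-style tables, `flowchart.csv`,
#' and `daily_rate.csv`.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    thresholds = as.list(report$thresholds$p),
    outcomes = lapply(report$outcomes, function(b) {
      if (identical(b, "no cases")) "no cases"
      else list(estimates = b$estimates, n_strata = b$n_strata,
                n_dropped_strata = b$n_dropped_strata,
                temp_knots = b$temp_knots, loglik = b$loglik, k = b$k,
                converged = b$converged)
    }),
    subgroups = report$subgroups,
    flowchart = list(initial = attr(report$flowchart, "initial"),
                     final = attr(report$flowchart, "final"),
                     steps = as.data.frame(report$flowchart)),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (nm in names(report$outcomes)) {
    b <- report$outcomes[[nm]]
    if (!identical(b, "no cases")) {
      utils::write.csv(b$estimates,
                       file.path(dir, paste0("estimates_", gsub("[^0-9A-Za-z]", "", nm), ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(as.data.frame(report$flowchart), file.path(dir, "flowchart.csv"),
                   row.names = FALSE)
  utils::write.csv(report$daily_rate, file.path(dir, "daily_rate.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Aggregate cases into daily counts for the conditional Poisson model
#'
#' Builds the stratum (municipality x year x month x day-of-week) daily
#' count table behind the quasi-Poisson sensitivity model: each stratum
#' holds every same-weekday day of its month, with the number of cases on
#' each day (zero allowed); strata without any case are all-zero and are
#' excluded (their count is the natural analogue of the logistic model
#' never seeing them). Strata with any exposure-incomplete day are dropped
#' whole, matching the logistic completeness policy.
#'
#' @param cases Case records (`birth_date`, `municipality_id`).
#' @param exposures Lagged exposure table.
#' @param L Maximum lag.
#' @return `data.frame` with `stratum`, `date`, `municipality_id`, `y`,
#'   `x_lag0..`, `rh_mean`; attribute `n_dropped_strata`.
#' @export
aggregate_counts <- function(cases, exposures, L = attr(exposures, "L")) {
  if (nrow(cases) == 0L) stop("no cases to aggregate")
  d <- as.Date(cases$birth_date)
  muni <- as.character(cases$municipality_id)
  skey <- paste(muni, format(d, "%Y-%m"), as.POSIXlt(d)$wday, sep = "|")
  ukey <- unique(skey)
  first <- match(ukey, skey)
  rows <- lapply(seq_along(ukey), function(i) {
    cd <- d[first[i]]
    days <- sort(c(cd, referent_days(cd)))
    data.frame(stratum = ukey[i], date = days,
               municipality_id = muni[first[i]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cnt <- table(paste(muni, d))
  out$y <- as.integer(cnt[paste(out$municipality_id, out$date)])
  out$y[is.na(out$y)] <- 0L
  ekey <- paste(as.character(exposures$municipality_id), exposures$date)
  idx <- match(paste(out$municipality_id, out$date), ekey)
  ok <- !is.na(idx) & exposures$complete[pmax(idx, 1L)]
  for (col in c(paste0("x_lag", 0:L), "rh_mean")) {
    out[[col]] <- NA_real_
    out[[col]][!is.na(idx)] <- exposures[[col]][idx[!is.na(idx)]]
  }
  bad <- unique(out$stratum[!ok])
  out <- out[!(out$stratum %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_strata") <- length(bad)
  attr(out, "L") <- as.integer(L)
  out
}

sensitivity_variants <- c("temp_ns2", "no_humidity", "lag0_only", "lag0_6",
                          "conditional_quasipoisson", "unrestricted_sample")

#' Run the sensitivity analyses
#'
#' Respecifies the primary model per variant: `temp_ns2` (two internal
#' temperature knots at the 33.3rd/66.7th exposure percentiles),
#' `no_humidity` (no humidity adjustment), `lag0_only` (lag 0 alone),
#' `lag0_6` (lags 0-6, natural cubic spline with one internal knot in both
#' dimensions), `conditional_quasipoisson` (aggregated daily counts,
#' all-zero strata excluded, Pearson overdispersion), and
#' `unrestricted_sample` (all singleton in-state births with an Apgar
#' score, not just low-risk). Estimate sets are named by the
#' "lag structure - crossbasis - humidity" convention.
#'
#' @param config A [run_config()].
#' @param variants Subset of the variant names above (default: the ones
#'   listed in `config$sensitivity`, or all six if empty).
#' @return Named list of estimate tables (one per variant) of class
#'   `sensitivity_report`.
#' @export
run_sensitivity <- function(config, variants = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(variants)) {
    variants <- if (length(config$sensitivity)) config$sensitivity else sensitivity_variants
  }
  unknown <- setdiff(variants, sensitivity_variants)
  if (length(unknown)) {
    stop("unknown sensitivity variant(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(sensitivity_variants, collapse = ", "))
  }
  prep <- prepare_study(config)
  model <- config$model
  cases <- prep$cohort[prep$cohort$low_apgar, , drop = FALSE]
  if (nrow(cases) == 0L) stop("no cases")
  out <- list()
  for (v in variants) {
    res <- switch(v,
      temp_ns2 = {
        ds <- expand_cases(cases, prep$exposures, model$L)
        xs <- as.vector(as.matrix(ds[, paste0("x_lag", 0:model$L)]))
        kn <- stats::quantile(xs, c(1, 2) / 3, names = FALSE)
        m <- cco_dlnm(ds, thresholds = prep$thresholds, L = model$L,
                      temp_knots = kn, lag_kind = model$lag_kind,
                      humidity = model$humidity)
        list(name = sprintf("Lag0-%d_CBns2-lin_Hns2", model$L),
             estimates = estimates_table(m$estimates))
      },
      no_humidity = {
        m <- cco_dlnm(cases, prep$exposures, prep$thresholds, L = model$L,
                      lag_kind = model$lag_kind, humidity = FALSE)
        list(name = sprintf("Lag0-%d_CBns1-lin_Hnone", model$L),
             estimates = estimates_table(m$estimates))
      },
      lag0_only = {
        exp0 <- build_lagged_exposures(prep$climate, 0L)
        m <- cco_dlnm(cases, exp0, prep$thresholds, L = 0L,
                      lag_kind = "linear", humidity = model$humidity)
        list(name = "Lag0_CBns1_Hns2", estimates = estimates_table(m$estimates))
      },
      lag0_6 = {
        exp6 <- build_lagged_exposures(prep$climate, 6L)
        m <- cco_dlnm(cases, exp6, prep$thresholds, L = 6L,
                      lag_kind = "natural_cubic", lag_knots = 3,
                      humidity = model$humidity)
        list(name = "Lag0-6_CBns1-ns1_Hns2", estimates = estimates_table(m$estimates))
      },
      conditional_quasipoisson = {
        agg <- aggregate_counts(cases, prep$exposures, model$L)
        xl <- as.matrix(agg[, paste0("x_lag", 0:model$L)])
        xs <- as.vector(xl)
        ts <- spline_spec("natural_cubic", stats::median(xs), range(xs))
        ls <- spline_spec("linear", boundary = c(-0.5, max(model$L, 1) + 0.5))
        cb <- build_crossbasis(xl, ts, ls, center = unname(prep$thresholds$p["p50"]))
        design <- cb$W
        if (model$humidity && diff(range(agg$rh_mean)) > 0) {
          rs <- spline_spec("natural_cubic",
                            stats::quantile(agg$rh_mean, c(1, 2) / 3, names = FALSE),
                            range(agg$rh_mean))
          design <- cbind(design, ns_basis(agg$rh_mean, rs))
        }
        fit <- fit_conditional_poisson(agg$y, design, agg$stratum)
        est <- dlnm_estimates(fit, cb, prep$thresholds, seq_len(ncol(cb$W)))
        list(name = sprintf("Lag0-%d_CBns1-lin_Hns2_quasipoisson", model$L),
             estimates = estimates_table(est), dispersion = fit$dispersion,
             n_zero_strata_dropped = fit$n_zero_strata_dropped)
      },
      unrestricted_sample = {
        prep2 <- prepare_study(config, lowrisk = FALSE)
        cases2 <- prep2$cohort[prep2$cohort$low_apgar, , drop = FALSE]
        m <- cco_dlnm(cases2, prep2$exposures, prep2$thresholds, L = model$L,
                      lag_kind = model$lag_kind, humidity = model$humidity)
        list(name = sprintf("Lag0-%d_CBns1-lin_Hns2_unrestricted*", model$L),
             estimates = estimates_table(m$estimates))
      }
    )
    out[[v]] <- res
  }
  class(out) <- "sensitivity_report"
  out
}

#' In-process command-line entry point
#'
#' A thin argv handler over the pipeline: `simulate` writes a synthetic
#' study, `exposure` writes the lagged exposure table, `cohort` writes the
#' exclusion flowchart, `fit` (alias `report`) runs the primary pipeline
#' and writes the report. Flags: `--config <yaml>`, `--seed <int>`,
#' `--out <dir>`. Returns a shell-style exit code (0 success, 1 runtime
#' error, 2 usage error); see `inst/cli/heatcco.R` for the Rscript
#' wrapper.
#'
#' @param argv Character vector of arguments.
#' @return Integer exit code.
#' @export
cco_cli <- function(argv = character()) {
  usage <- function() {
    message("usage: heatcco <simulate|exposure|cohort|fit|report> --config <yaml> [--seed <int>] [--out <dir>]")
    2L
  }
  if (length(argv) < 1L || !argv[1] %in% c("simulate", "exposure", "cohort", "fit", "report")) {
    return(usage())
  }
  cmd <- argv[1]
  args <- argv[-1]
  flag <- function(name) {
    i <- which(args == name)
    if (length(i) != 1L || i == length(args)) return(NULL)
    args[i + 1L]
  }
  known <- c("--config", "--seed", "--out")
  flags_at <- which(args %in% known)
  used <- sort(c(flags_at, flags_at + 1L))
  if (length(setdiff(seq_along(args), used))) return(usage())
  cfg_path <- flag("--config")
  if (is.null(cfg_path)) return(usage())
  tryCatch({
    config <- read_run_config(cfg_path)
    if (!is.null(flag("--seed"))) {
      if (!is.null(config$simulation)) config$simulation$seed <- as.integer(flag("--seed"))
    }
    out <- flag("--out")
    if (!is.null(out)) config$outdir <- out
    switch(cmd,
      simulate = {
        if (is.null(config$simulation)) stop("simulate requires a simulation block")
        write_study(simulate_births(config$simulation),
                    if (is.null(config$outdir)) "." else config$outdir)
      },
      exposure = {
        prep <- prepare_study(config)
        dir.create(config$outdir %||% ".", recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(prep$exposures,
                         file.path(config$outdir %||% ".", "exposures.csv"),
                         row.names = FALSE)
      },
      cohort = {
        prep <- prepare_study(config)
        dir.create(config$outdir %||% ".", recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(as.data.frame(prep$flowchart),
                         file.path(config$outdir %||% ".", "flowchart.csv"),
                         row.names = FALSE)
      },
      fit = invisible(run_primary(config)),
      report = invisible(run_primary(config))
    )
    0L
  }, error = function(e) {
    message("heatcco ", cmd, " failed: ", conditionMessage(e))
    1L
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
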