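registry_required_cols <- c(
  "birth_date", "municipality_id", "apgar5", "birthweight_g", "gest_weeks",
  "plurality", "presentation", "anomaly", "maternal_age_years",
  "education_cat", "race", "parity_cat", "prenatal_start", "sex",
  "ibp_quintile", "koppen"
)

#' Read a birth-registry CSV into a typed record table
#'
#' The schema mirrors the column subset of a national live-birth registry
#' needed for the analysis: delivery date and municipality, the 5-minute
#' Apgar score, the clinical fields of the low-risk definition
#' (birthweight, gestational weeks, plurality, presentation, congenital
#' anomaly), and the socio-demographic covariates used in descriptives and
#' subgroup fits. Sentinel codes for "unknown" are mapped to missing via
#' `missing_codes`; rows whose numeric fields fail to parse are collected
#' and reported.
#'
#' @param file Path to a CSV with (at least) the columns listed above.
#' @param missing_codes Named list mapping a column to the codes to treat
#'   as missing, e.g. `list(apgar5 = 99)`.
#' @param max_bad_frac Hard-fail threshold: if more than this fraction of
#'   rows is malformed the read errors out.
#' @return `data.frame` of typed records; attributes `missingness`
#'   (per-column NA counts) and `bad_rows` (line numbers of malformed rows).
#' @export
read_registry <- function(file, missing_codes = list(apgar5 = 99),
                          max_bad_frac = 0.05) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(registry_required_cols, names(raw))
  if (length(miss)) stop("registry file missing required column(s): ", paste(miss, collapse = ", "))
  for (col in names(missing_codes)) {
    raw[[col]][raw[[col]] %in% as.character(missing_codes[[col]])] <- NA
  }
  num_cols <- c("apgar5", "birthweight_g", "gest_weeks", "maternal_age_years", "ibp_quintile")
  bad <- logical(nrow(raw))
  out <- raw
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- bad | (!is.na(raw[[col]]) & nzchar(raw[[col]]) & is.na(v))
    out[[col]] <- v
  }
  dt <- as.Date(raw$birth_date)
  bad <- bad | is.na(dt)
  out$birth_date <- dt
  out$apgar5[!is.na(out$apgar5) & (out$apgar5 < 0 | out$apgar5 > 10)] <- NA
  for (col in setdiff(registry_required_cols, c(num_cols, "birth_date"))) {
    out[[col]][!nzchar(trimws(as.character(out[[col]])))] <- NA
  }
  if (any(bad)) {
    if (mean(bad) > max_bad_frac) {
      stop(sprintf("%d of %d registry rows malformed (> %.0f%% threshold); first bad lines: %s",
                   sum(bad), nrow(out), 100 * max_bad_frac,
                   paste(utils::head(which(bad) + 1L, 5L), collapse = ", ")))
    }
    message(sprintf("read_registry: dropping %d malformed row(s)", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  missingness <- vapply(out[registry_required_cols], function(x) sum(is.na(x)), integer(1))
  attr(out, "missingness") <- missingness
  attr(out, "bad_rows") <- which(bad) + 1L
  rownames(out) <- NULL
  out
}

#' Low-risk birth exclusion cascade with full accounting
#'
#' Applies the restriction to low-risk births as a sequential cascade:
#' (0) non-singleton plurality, (1) delivery outside the study state,
#' (2) missing 5-minute Apgar score, (3) birthweight below 2500 g or above
#' 4000 g, (4) gestational age below 37 or above 41 completed weeks,
#' (5) congenital anomaly, (6) non-cephalic presentation, (7) missing data
#' on any of the fields in steps 3-6. Boundary values (2500 g, 4000 g,
#' 37 w, 41 w) are retained; each step counts only records still present,
#' so counts always conserve: initial - sum(excluded) = final.
#'
#' @param records Typed registry table ([read_registry()] output or
#'   equivalent).
#' @param state_municipalities Optional character vector of in-state
#'   municipality ids; when `NULL` step 1 excludes nothing.
#' @return List with `records` (retained rows) and `flowchart`, a
#'   `data.frame` (step, label, n_excluded, pct_of_initial) of class
#'   `cco_flowchart` carrying `initial` and `final` attributes.
#' @export
apply_lowrisk_filters <- function(records, state_municipalities = NULL) {
  initial <- nrow(records)
  steps <- list(
    non_singleton = function(d) !is.na(d$plurality) & d$plurality != "singleton",
    outside_state = function(d) {
      if (is.null(state_municipalities)) rep(FALSE, nrow(d))
      else !(as.character(d$municipality_id) %in% state_municipalities)
    },
    missing_apgar5 = function(d) is.na(d$apgar5),
    birthweight_out_of_range = function(d) !is.na(d$birthweight_g) &
      (d$birthweight_g < 2500 | d$birthweight_g > 4000),
    gestation_out_of_range = function(d) !is.na(d$gest_weeks) &
      (d$gest_weeks < 37 | d$gest_weeks > 41),
    congenital_anomaly = function(d) !is.na(d$anomaly) & d$anomaly == "yes",
    non_cephalic = function(d) !is.na(d$presentation) & d$presentation != "cephalic",
    missing_lowrisk_fields = function(d) is.na(d$birthweight_g) | is.na(d$gest_weeks) |
      is.na(d$anomaly) | is.na(d$presentation)
  )
  labels <- c("non-singleton", "outside state", "missing 5-min Apgar",
              "birthweight <2500 or >4000 g", "gestational age <37 or >41 w",
              "congenital anomaly", "non-cephalic presentation",
              "missing low-risk fields")
  # single pass over an alive mask: each step counts only records still present
  alive <- rep(TRUE, initial)
  n_exc <- integer(length(steps))
  for (i in seq_along(steps)) {
    drop <- alive & steps[[i]](records)
    n_exc[i] <- sum(drop)
    alive <- alive & !drop
  }
  keep <- records[alive, , drop = FALSE]
  fc <- data.frame(step = seq_along(steps) - 1L, label = labels,
                   n_excluded = n_exc,
                   pct_of_initial = share_of_initial(n_exc, max(initial, 1L)),
                   stringsAsFactors = FALSE)
  class(fc) <- c("cco_flowchart", "data.frame")
  attr(fc, "initial") <- initial
  attr(fc, "final") <- nrow(keep)
  rownames(keep) <- NULL
  list(records = keep, flowchart = fc)
}

#' @export
print.cco_flowchart <- function(x, ...) {
  cat("Exclusion cascade:", attr(x, "initial"), "->", attr(x, "final"), "records\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Classify the 5-minute Apgar outcome
#'
#' Scores of 7 and below are "low"; low scores are subcategorised as 0-2,
#' 3-5 and 6-7, and 8-10 is "normal".
#'
#' @param apgar5 Integer vector of 5-minute Apgar scores in `[0, 10]`;
#'   missing values are rejected (they must be excluded upstream).
#' @return `data.frame` with `category` (factor `0-2`, `3-5`, `6-7`,
#'   `normal`) and logical `low`.
#' @export
classify_outcome <- function(apgar5) {
  if (any(is.na(apgar5))) stop("missing Apgar scores must be excluded before classification")
  if (any(apgar5 < 0 | apgar5 > 10)) stop("Apgar scores must lie in [0, 10]")
  category <- cut(apgar5, breaks = c(-0.5, 2.5, 5.5, 7.5, 10.5),
                  labels = c("0-2", "3-5", "6-7", "normal"))
  data.frame(category = category, low = apgar5 <= 7)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' The uncorrected Pearson statistic (no Yates continuity correction, also
#' for 2x2 tables), with optional dropping of sparse rows or columns by
#' label before testing (listwise handling of excluded categories).
#'
#' @param tab Matrix of nonnegative counts with dimnames.
#' @param drop_levels Optional character vector of row/column names to
#'   remove before testing.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
pearson_chi_square <- function(tab, drop_levels = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (!is.null(drop_levels)) {
    if (!is.null(rownames(tab))) tab <- tab[!(rownames(tab) %in% drop_levels), , drop = FALSE]
    if (!is.null(colnames(tab))) tab <- tab[, !(colnames(tab) %in% drop_levels), drop = FALSE]
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin after dropping levels")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Percentage of an initial total, rounded half-up to two decimals
#'
#' The convention used for exclusion-cascade percentages: every step is
#' expressed relative to the initial record count, rounded half-up at the
#' second decimal.
#'
#' @param n Count(s).
#' @param initial Initial total, positive.
#' @return `100 * n / initial` rounded half-up to 2 decimal places.
#' @export
share_of_initial <- function(n, initial) {
  if (any(initial <= 0)) stop("initial total must be positive")
  floor(100 * n / initial * 100 + 0.5) / 100
}
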