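#' Time-stratified referent days for a case day
#'
#' Control days share the day-of-week, calendar month and year of the case
#' day; the case day itself is excluded. Every calendar month yields 3 or 4
#' such controls. The scheme is bi-directional: controls may fall after the
#' case day.
#'
#' @param case_date A `Date` (or string coercible to one).
#' @return Ascending `Date` vector of control days.
#' @examples
#' referent_days(as.Date("2015-07-15")) # the other Wednesdays of July 2015
#' @export
referent_days <- function(case_date) {
  d <- as.Date(case_date)
  if (length(d) != 1L || is.na(d)) stop("case_date must be a single valid date")
  first <- as.Date(format(d, "%Y-%m-01"))
  last <- seq(first, by = "1 month", length.out = 2L)[2L] - 1L
  month_days <- seq(first, last, by = "1 day")
  same_dow <- month_days[as.POSIXlt(month_days)$wday == as.POSIXlt(d)$wday]
  sort(same_dow[same_dow != d])
}

#' Expand cases into matched case-crossover strata with lagged exposures
#'
#' One stratum per case (cases sharing a municipality-day form separate,
#' duplicated strata): the case day plus its time-stratified referent days,
#' each row joined to the lagged exposure vector and lag-window mean
#' humidity of its (municipality, date). Strata containing any
#' exposure-incomplete row are dropped whole and counted.
#'
#' @param cases `data.frame` of case records with `birth_date` and
#'   `municipality_id`; any further columns are carried onto every row of
#'   the case's stratum as covariates.
#' @param exposures Lagged exposure table from [build_lagged_exposures()].
#' @param L Maximum lag; defaults to the `L` the exposure table was built
#'   with.
#' @return `data.frame` of class `cco_dataset` with `stratum_id`,
#'   `is_case`, `date`, `municipality_id`, `x_lag0..x_lagL`, `rh_mean` and
#'   carried covariates; attributes `L` and `n_dropped_strata`.
#' @export
expand_cases <- function(cases, exposures, L = attr(exposures, "L")) {
  if (is.null(L)) stop("L not supplied and exposure table carries no L attribute")
  if (nrow(cases) == 0L) stop("no cases to expand")
  stopifnot(all(c("birth_date", "municipality_id") %in% names(cases)))
  xcols <- paste0("x_lag", 0:L)
  if (!all(xcols %in% names(exposures))) {
    stop("exposure table lacks lags 0..", L)
  }
  case_dates <- as.Date(cases$birth_date)
  udates <- unique(case_dates)
  ctrl <- lapply(udates, referent_days)
  names(ctrl) <- as.character(udates)
  ctrl_per_case <- ctrl[as.character(case_dates)]
  n_rows_per_case <- lengths(ctrl_per_case) + 1L
  stratum_id <- rep(seq_len(nrow(cases)), n_rows_per_case)
  dates <- as.Date(unlist(lapply(seq_len(nrow(cases)), function(i) {
    c(case_dates[i], ctrl_per_case[[i]])
  })), origin = "1970-01-01")
  is_case <- unlist(lapply(n_rows_per_case, function(k) c(1L, integer(k - 1L))))
  out <- data.frame(
    stratum_id = stratum_id,
    is_case = is_case,
    date = dates,
    municipality_id = rep(as.character(cases$municipality_id), n_rows_per_case),
    stringsAsFactors = FALSE
  )
  ekey <- paste(as.character(exposures$municipality_id), exposures$date)
  idx <- match(paste(out$municipality_id, out$date), ekey)
  found <- !is.na(idx)
  keep_cols <- c(xcols, "rh_mean")
  for (col in keep_cols) {
    out[[col]] <- NA_real_
    out[[col]][found] <- exposures[[col]][idx[found]]
  }
  complete_row <- found & exposures$complete[pmax(idx, 1L)] & !is.na(out$rh_mean)
  bad_strata <- unique(out$stratum_id[!complete_row])
  n_dropped <- length(bad_strata)
  if (n_dropped) out <- out[!(out$stratum_id %in% bad_strata), , drop = FALSE]
  if (nrow(out) == 0L) stop("no cases with complete exposure coverage")
  covars <- setdiff(names(cases), c("birth_date", "municipality_id"))
  for (col in covars) out[[col]] <- cases[[col]][out$stratum_id]
  rownames(out) <- NULL
  class(out) <- c("cco_dataset", "data.frame")
  attr(out, "L") <- as.integer(L)
  attr(out, "n_dropped_strata") <- n_dropped
  out
}
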