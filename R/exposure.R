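#' Convert temperatures from Kelvin to degrees Celsius
#'
#' Reanalysis products distribute 2-metre air and dewpoint temperature in
#' Kelvin; all downstream exposure work is in degrees Celsius.
#'
#' @param x Numeric vector, matrix or array of temperatures in Kelvin.
#' @return Object of the same shape with `x - 273.15`.
#' @examples
#' kelvin_to_celsius(c(273.15, 300.15))
#' @export
kelvin_to_celsius <- function(x) {
  if (!is.numeric(x)) stop("temperatures must be numeric")
  if (any(!is.finite(x) & !is.na(x))) stop("non-finite temperature values")
  x - 273.15
}

#' Aggregate hourly values to daily arithmetic means
#'
#' Daily mean temperature is the arithmetic average of the hourly values
#' falling on each calendar date. Dates failing the completeness rule are
#' emitted as `NA` rather than silently averaged over fewer hours.
#'
#' @param timestamps `POSIXct` (or `Date`-coercible) timestamps of the hourly
#'   values.
#' @param values Numeric hourly values, same length as `timestamps`.
#' @param min_hours Minimum number of hourly values a date needs for its mean
#'   to be reported; the default 24 requires a complete day.
#' @return `data.frame` with columns `date` and `value` (`NA` where the
#'   completeness rule fails), one row per date present in the input.
#' @export
hourly_to_daily_mean <- function(timestamps, values, min_hours = 24L) {
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have equal length")
  }
  if (length(values) == 0L) {
    return(data.frame(date = as.Date(character()), value = numeric()))
  }
  dates <- as.Date(timestamps)
  n <- tapply(values, dates, length)
  m <- tapply(values, dates, mean)
  out <- data.frame(date = as.Date(names(m)), value = as.numeric(m))
  out$value[n < min_hours] <- NA_real_
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

#' Tetens saturation vapour pressure (unnormalised)
#'
#' `exp(a * t / (t + b))` with `a = 17.27`, `b = 237.3` degrees C. The
#' multiplicative constant of the Tetens formula cancels in the relative
#' humidity ratio and is omitted.
#'
#' @param t_c Temperature in degrees Celsius.
#' @return Saturation vapour pressure up to a constant factor.
#' @keywords internal
tetens_es <- function(t_c) {
  if (any(t_c + 237.3 <= 0, na.rm = TRUE)) {
    stop("temperature at or below -237.3 C: outside the validity of the Tetens formula")
  }
  exp(17.27 * t_c / (t_c + 237.3))
}

#' Relative humidity from air and dewpoint temperature (Tetens equation)
#'
#' RH (%) is 100 times the ratio of actual vapour pressure (saturation
#' pressure at the dewpoint) to saturation vapour pressure at the air
#' temperature, both from the Tetens formula with a = 17.27 and
#' b = 237.3 degrees C. Dewpoints exceeding the air temperature are
#' physically inconsistent (supersaturation); they are clamped to the air
#' temperature with a warning, giving RH = 100.
#'
#' @param t_c Air temperature, degrees Celsius.
#' @param td_c Dewpoint temperature, degrees Celsius; recycled against `t_c`.
#' @return Relative humidity in percent, in `[0, 100]`.
#' @examples
#' tetens_rh(20, 10) # about 52.5
#' @export
tetens_rh <- function(t_c, td_c) {
  n <- max(length(t_c), length(td_c))
  t_c <- rep_len(t_c, n)
  td_c <- rep_len(td_c, n)
  over <- !is.na(td_c) & !is.na(t_c) & td_c > t_c
  if (any(over)) {
    warning(sprintf("%d dewpoint value(s) exceed air temperature; clamped to saturation", sum(over)))
    td_c[over] <- t_c[over]
  }
  rh <- 100 * tetens_es(td_c) / tetens_es(t_c)
  pmin(pmax(rh, 0), 100)
}

#' Average gridded values over the cells of each municipality
#'
#' Municipality-level climate values are the unweighted arithmetic mean,
#' per date, over the grid cells belonging to the municipality. Cell
#' membership is an input; no polygon geometry is computed here.
#'
#' @param grid_values `data.frame` with columns `cell_id`, `date`, `value`.
#' @param membership `data.frame` with columns `municipality_id`, `cell_id`.
#' @return `data.frame` with columns `municipality_id`, `date`, `value`.
#' @export
grid_to_municipality <- function(grid_values, membership) {
  stopifnot(all(c("cell_id", "date", "value") %in% names(grid_values)),
            all(c("municipality_id", "cell_id") %in% names(membership)))
  munis <- unique(as.character(membership$municipality_id))
  merged <- merge(membership, grid_values, by = "cell_id")
  empty <- setdiff(munis, unique(as.character(merged$municipality_id)))
  if (length(empty)) {
    stop("municipality with zero member cells in the grid: ",
         paste(empty, collapse = ", "))
  }
  agg <- stats::aggregate(value ~ municipality_id + date, data = merged, FUN = mean)
  agg <- agg[order(agg$municipality_id, agg$date), c("municipality_id", "date", "value")]
  rownames(agg) <- NULL
  agg
}

#' Weighted quantiles by the midpoint plotting-position rule
#'
#' Sorts values, forms plotting positions p_i = (cum_i - w_i/2) / sum(w),
#' and interpolates linearly between adjacent positions; probabilities
#' below the first or above the last position return the minimum or
#' maximum value. With equal weights this is the standard midpoint-rule
#' sample quantile.
#'
#' @param values Numeric vector.
#' @param weights Strictly positive weights, same length as `values`.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(values, weights = rep(1, length(values)),
                              probs = c(0.05, 0.5, 0.95)) {
  if (length(values) == 0L) stop("empty input to weighted_quantile")
  if (length(values) != length(weights)) stop("values and weights must have equal length")
  if (any(!is.finite(weights)) || any(weights <= 0)) stop("weights must be positive and finite")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord]
  pos <- (cumsum(w) - w / 2) / sum(w)
  vapply(probs, function(p) {
    if (p <= pos[1L]) return(v[1L])
    if (p >= pos[length(pos)]) return(v[length(v)])
    stats::approx(pos, v, xout = p, ties = "ordered")$y
  }, numeric(1))
}

#' Population-weighted temperature percentile thresholds
#'
#' Pools all (municipality, day) daily mean temperatures over the covered
#' span, each weighted by its municipality's population weight, and returns
#' the requested percentiles (by default the 5th, 50th and 95th, the low /
#' moderate / high reference temperatures of the analysis).
#'
#' @param climate Climate table as returned by [simulate_climate()] or
#'   [read_climate()]: columns `municipality_id`, `date`, `tmean_c`, `rh_pct`.
#' @param population Named numeric vector of population weights, names are
#'   municipality ids. Unnamed scalar weights are recycled (unweighted pool).
#' @param probs Percentile probabilities, ascending; default `c(.05, .5, .95)`.
#' @param domain Label describing the pool (e.g. `"state-wide"`, a Koppen
#'   group) carried into the result.
#' @return Object of class `percentile_thresholds`: list with `p` (named
#'   vector of thresholds), `probs`, `domain`, `n`.
#' @export
percentile_thresholds <- function(climate, population = NULL,
                                  probs = c(0.05, 0.5, 0.95),
                                  domain = "state-wide") {
  stopifnot(all(c("municipality_id", "date", "tmean_c") %in% names(climate)))
  if (is.unsorted(probs)) stop("probs must be ascending")
  if (is.null(population)) {
    w <- rep(1, nrow(climate))
  } else {
    if (is.null(names(population))) stop("population weights must be named by municipality id")
    w <- population[as.character(climate$municipality_id)]
    if (any(is.na(w))) stop("population weight missing for some municipality")
  }
  q <- weighted_quantile(climate$tmean_c, w, probs)
  names(q) <- paste0("p", formatC(100 * probs, format = "fg"))
  structure(list(p = q, probs = probs, domain = domain, n = nrow(climate)),
            class = "percentile_thresholds")
}

#' @export
print.percentile_thresholds <- function(x, ...) {
  cat("Population-weighted temperature percentiles (", x$domain, ", n = ",
      x$n, " municipality-days)\n", sep = "")
  print(round(x$p, 2))
  invisible(x)
}

#' Build lagged temperature exposures and lag-window mean humidity
#'
#' For every (municipality, date) the exposure vector holds the daily mean
#' temperature on the date itself (lag 0) back to `L` days before
#' (lag `L`), and `rh_mean` is the mean relative humidity over the same
#' lag window. Rows whose lag window reaches before the start of the
#' municipality's series are flagged incomplete rather than dropped.
#'
#' @param climate Climate table (`municipality_id`, `date`, `tmean_c`,
#'   `rh_pct`), one row per municipality-day, dates contiguous within
#'   municipality.
#' @param L Maximum lag in days (`L >= 0`).
#' @return `data.frame` with `municipality_id`, `date`, columns
#'   `x_lag0 ... x_lagL`, `rh_mean`, and logical `complete`.
#' @export
build_lagged_exposures <- function(climate, L = 1L) {
  stopifnot(L >= 0, all(c("municipality_id", "date", "tmean_c", "rh_pct") %in% names(climate)))
  climate <- climate[order(climate$municipality_id, climate$date), , drop = FALSE]
  key <- as.character(climate$municipality_id)
  if (anyDuplicated(paste(key, climate$date))) {
    stop("climate table has duplicate (municipality, date) rows")
  }
  pieces <- lapply(split(seq_len(nrow(climate)), key), function(idx) {
    d <- climate[idx, , drop = FALSE]
    if (nrow(d) > 1L && any(diff(as.integer(d$date)) != 1L)) {
      stop("dates not contiguous for municipality ", d$municipality_id[1L])
    }
    n <- nrow(d)
    xl <- matrix(NA_real_, n, L + 1L)
    rl <- matrix(NA_real_, n, L + 1L)
    for (l in 0:L) {
      if (l < n) {
        xl[(l + 1L):n, l + 1L] <- d$tmean_c[1:(n - l)]
        rl[(l + 1L):n, l + 1L] <- d$rh_pct[1:(n - l)]
      }
    }
    colnames(xl) <- paste0("x_lag", 0:L)
    out <- data.frame(municipality_id = d$municipality_id,
                      date = d$date, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(xl))
    out$rh_mean <- rowMeans(rl)
    out$complete <- stats::complete.cases(xl)
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  attr(res, "L") <- as.integer(L)
  res
}

#' Read / write a municipality-day climate table
#'
#' CSV schema: `municipality_id`, `date` (ISO-8601), `tmean_c`, `rh_pct`.
#'
#' @param file Path to a CSV file.
#' @return `read_climate`: a climate `data.frame` with `Date` dates.
#' @export
read_climate <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("municipality_id", "date", "tmean_c", "rh_pct")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("climate file missing column(s): ", paste(miss, collapse = ", "))
  x$date <- as.Date(x$date)
  x$municipality_id <- as.character(x$municipality_id)
  if (any(x$rh_pct < 0 | x$rh_pct > 100, na.rm = TRUE)) {
    stop("rh_pct outside [0, 100]")
  }
  x
}

#' @rdname read_climate
#' @param climate Climate table to write.
#' @export
write_climate <- function(climate, file) {
  utils::write.csv(climate[, c("municipality_id", "date", "tmean_c", "rh_pct")],
                   file, row.names = FALSE)
  invisible(file)
}
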