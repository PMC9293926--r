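# Hourly-to-daily/monthly aggregation under a completeness threshold, and
# pairing of air with water means.

period_labels <- function(timestamp, unit) {
  lt <- as.POSIXlt(timestamp)
  if (unit == "day") format(timestamp, "%Y-%m-%d", tz = "UTC")
  else format(timestamp, "%Y-%m", tz = "UTC")
}

expected_hours <- function(period, unit) {
  if (unit == "day") rep(24L, length(period))
  else {
    yr <- as.integer(substr(period, 1, 4))
    mo <- as.integer(substr(period, 6, 7))
    mapply(days_in_month, yr, mo) * 24L
  }
}

#' Aggregate an hourly logger series to daily or monthly means
#'
#' A calendar unit's mean is computed from the hourly values present in it
#' if at least `threshold` of the unit's hours are available (inclusive
#' comparison, 24 hours per day and `24 * days-in-month` per month,
#' leap-aware); otherwise the unit is a missing observation. Monthly means
#' are computed directly from the hourly data with the monthly
#' expected-hour count, never as means of daily means. Air and water
#' channels are thresholded independently.
#'
#' @param series `data.frame(site_id, timestamp, air, water)` with `POSIXct`
#'   on-the-hour timestamps; missing hours may be `NA` values or absent rows.
#' @param unit `"day"` or `"month"`.
#' @param threshold completeness fraction in `(0, 1]`; default 0.75.
#' @return `data.frame(site_id, period, unit, mean_air, mean_water, n_air,
#'   n_water, n_expected)`, one row per observed (site, period).
#' @export
aggregate_hourly <- function(series, unit = c("day", "month"),
                             threshold = 0.75) {
  unit <- match.arg(unit)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  if (!inherits(series$timestamp, "POSIXct"))
    stop("`timestamp` must be POSIXct", call. = FALSE)
  secs <- as.numeric(series$timestamp)
  if (any(secs %% 3600 != 0))
    stop("timestamps must fall exactly on the hour", call. = FALSE)
  key <- paste(series$site_id, secs)
  if (anyDuplicated(key))
    stop("duplicated (site, timestamp) records", call. = FALSE)

  period <- period_labels(series$timestamp, unit)
  g <- paste(series$site_id, period, sep = "\r")
  gf <- factor(g, levels = unique(g))
  sum_na <- function(x) {
    ok <- !is.na(x)
    cbind(sum = rowsum(ifelse(ok, x, 0), gf), n = rowsum(as.numeric(ok), gf))
  }
  a <- sum_na(series$air); w <- sum_na(series$water)
  lev <- levels(gf)
  site_id <- sub("\r.*$", "", lev)
  per <- sub("^.*\r", "", lev)
  n_exp <- expected_hours(per, unit)
  mean_if <- function(s, n) ifelse(n / n_exp >= threshold, s / n, NA_real_)
  out <- data.frame(
    site_id = site_id, period = per, unit = unit,
    mean_air = mean_if(a[, 1], a[, 2]),
    mean_water = mean_if(w[, 1], w[, 2]),
    n_air = as.integer(a[, 2]), n_water = as.integer(w[, 2]),
    n_expected = as.integer(n_exp),
    stringsAsFactors = FALSE
  )
  out[order(out$site_id, out$period), , drop = FALSE]
}

# Numeric time covariate, in units of the timescale, for a period label.
period_time <- function(period, unit) {
  if (unit == "day") as.numeric(as.Date(period))
  else as.integer(substr(period, 1, 4)) * 12 +
    as.integer(substr(period, 6, 7))
}

#' Pair aggregated air and water means into model observations
#'
#' Keeps the intersection of periods where both means are present; sorted
#' by time within site. Half-missing periods are dropped, not imputed.
#'
#' @param air_agg an [aggregate_hourly()] table; if `water_agg` is `NULL`
#'   its own `mean_air`/`mean_water` columns are paired, otherwise
#'   `air_agg$mean_air` is matched with `water_agg$mean_water` by
#'   (site, period).
#' @param water_agg optional second aggregated table (same unit).
#' @return `data.frame(site_id, period, t, Ta, Tw)` where `t` is numeric
#'   time in timescale units (days since epoch, or calendar month index).
#' @export
pair_observations <- function(air_agg, water_agg = NULL) {
  if (!is.null(water_agg)) {
    if (!identical(unique(air_agg$unit), unique(water_agg$unit)))
      stop("air and water tables must share the same unit", call. = FALSE)
    m <- merge(air_agg[, c("site_id", "period", "unit", "mean_air")],
               water_agg[, c("site_id", "period", "mean_water")],
               by = c("site_id", "period"))
  } else m <- air_agg
  keep <- !is.na(m$mean_air) & !is.na(m$mean_water)
  m <- m[keep, , drop = FALSE]
  unit <- if (nrow(m)) m$unit[1] else "day"
  out <- data.frame(site_id = m$site_id, period = m$period,
                    t = period_time(m$period, unit),
                    Ta = m$mean_air, Tw = m$mean_water,
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_id, out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag suspected air-exposure periods of a water logger
#'
#' Screening heuristic for stranded water loggers: a window is flagged when
#' the water channel's diel range exceeds `range_ratio` times the series'
#' median diel range AND the water tracks air within `track_tol` degC on
#' average over the window. Flagged periods can be masked downstream.
#'
#' @param series hourly `data.frame(site_id, timestamp, air, water)`.
#' @param window window length in hours; must be a multiple of 24, >= 24.
#' @param range_ratio multiplier on the median diel range.
#' @param track_tol mean absolute air-water gap (degC) below which the
#'   water channel is considered to be tracking air.
#' @return character vector of flagged day labels (`YYYY-MM-DD`).
#' @export
flag_air_exposure <- function(series, window = 24, range_ratio = 3,
                              track_tol = 1) {
  if (!is.numeric(window) || window < 24)
    stop("`window` must be at least 24 hours", call. = FALSE)
  if (window %% 24 != 0)
    stop("`window` must be a whole number of days", call. = FALSE)
  day <- period_labels(series$timestamp, "day")
  rng <- tapply(series$water, day, function(x)
    if (all(is.na(x))) NA_real_ else diff(range(x, na.rm = TRUE)))
  gap <- tapply(abs(series$water - series$air), day, mean, na.rm = TRUE)
  med <- stats::median(rng, na.rm = TRUE)
  if (!is.finite(med) || med == 0) return(character(0))
  days <- names(rng)
  k <- as.integer(window / 24)
  grp <- rep(seq_along(days), each = k, length.out = length(days))
  flagged <- logical(length(days))
  for (gidx in unique(grp)) {
    i <- which(grp == gidx)
    r <- mean(rng[i], na.rm = TRUE); gp <- mean(gap[i], na.rm = TRUE)
    if (is.finite(r) && is.finite(gp) && r > range_ratio * med &&
        gp < track_tol)
      flagged[i] <- TRUE
  }
  days[flagged]
}
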