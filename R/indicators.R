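#' Indicator time-series container
#'
#' A daily time-series for one fleet or environmental indicator, stored as
#' a data.frame (date, value) on a complete daily axis with metadata
#' attributes.
#'
#' @param date Date vector.
#' @param value numeric vector.
#' @param name indicator name (e.g. "vms_y", "ssta").
#' @param units value units.
#' @param is_anomaly whether values are climatology anomalies.
#' @param smoothed whether values have been rolling-mean smoothed.
#' @return data.frame of class \code{indicator_series}.
#' @export
indicator_series <- function(date, value, name, units = "",
                             is_anomaly = FALSE, smoothed = FALSE) {
  stopifnot(inherits(date, "Date"), length(date) == length(value))
  o <- order(date)
  df <- complete_daily(data.frame(date = date[o], value = as.numeric(value)[o]))
  if (anyDuplicated(date)) stop("indicator_series: duplicate dates")
  structure(df, class = c("indicator_series", "data.frame"),
            name = name, units = units, is_anomaly = is_anomaly,
            smoothed = smoothed)
}

# internal: rebuild metadata after transforming values
update_series <- function(series, value, ...) {
  dots <- list(...)
  out <- series
  out$value <- value
  for (nm in names(dots)) attr(out, nm) <- dots[[nm]]
  out
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("<indicator_series '%s'> %d days (%s to %s)%s%s\n",
              attr(x, "name"), nrow(x), min(x$date), max(x$date),
              if (isTRUE(attr(x, "is_anomaly"))) ", anomaly" else "",
              if (isTRUE(attr(x, "smoothed"))) ", smoothed" else ""))
  n_ok <- sum(!is.na(x$value))
  cat(sprintf("  %d non-missing; mean %.4g%s\n", n_ok,
              mean(x$value, na.rm = TRUE),
              if (nzchar(attr(x, "units"))) paste0(" ", attr(x, "units")) else ""))
  invisible(x)
}

#' @export
plot.indicator_series <- function(x, ...) {
  graphics::plot(x$date, x$value, type = "l", xlab = "date",
                 ylab = paste0(attr(x, "name"),
                               if (nzchar(attr(x, "units")))
                                 paste0(" (", attr(x, "units"), ")") else ""),
                 ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# internal: daily weighted aggregate of linked pings
daily_weighted <- function(linked, x, w, name, units) {
  day <- as.Date(linked$timestamp, tz = "UTC")
  num <- tapply(x * w, day, sum)
  den <- tapply(w, day, sum)
  val <- ifelse(den > 0, num / den, NA_real_)
  indicator_series(as.Date(names(val)), as.numeric(val), name, units)
}

#' Daily pounds-weighted fleet latitude centroid
#'
#' Latitude of the daily albacore-pounds-weighted mean position of fishing
#' pings (the "Y centroid", tracking north/south fleet movement). Days with
#' zero total allocated pounds are missing.
#'
#' @param linked \code{linked_pings} from \code{\link{link_vms_landings}}.
#' @return \code{indicator_series} named \code{vms_y} (degrees latitude).
#' @export
daily_effort_centroid <- function(linked) {
  daily_weighted(linked, linked$lat, linked$allocated_pounds,
                 "vms_y", "deg lat")
}

#' Daily pounds-weighted mean distance to shore
#'
#' Great-circle distance (km) of each fishing ping to the nearest point on
#' the coastline, averaged per day with albacore-pounds weights (tracking
#' inshore/offshore fleet movement).
#'
#' @param linked \code{linked_pings}.
#' @param coastline coastline polyline matrix (lon, lat).
#' @return \code{indicator_series} named \code{vms_shore} (km).
#' @export
daily_distance_to_shore <- function(linked, coastline) {
  d <- dist_to_coast(linked$lon, linked$lat, coastline)
  daily_weighted(linked, d, linked$allocated_pounds, "vms_shore", "km")
}

#' Daily catch per unit effort
#'
#' Daily sum of allocated albacore pounds divided by the daily sum of
#' time-forward minutes of fishing pings, in pounds per minute. Days with
#' no fishing minutes are missing.
#'
#' @param linked \code{linked_pings}.
#' @return \code{indicator_series} named \code{vms_cpue} (lbs/min).
#' @export
daily_cpue <- function(linked) {
  if (any(linked$allocated_pounds < 0)) stop("daily_cpue: negative pounds")
  if (any(linked$time_forward < 0)) stop("daily_cpue: negative time_forward")
  day <- as.Date(linked$timestamp, tz = "UTC")
  lbs <- tapply(linked$allocated_pounds, day, sum)
  mins <- tapply(linked$time_forward, day, sum)
  val <- ifelse(mins > 0, lbs / mins, NA_real_)
  indicator_series(as.Date(names(val)), as.numeric(val), "vms_cpue", "lbs/min")
}

#' Monthly-climatology anomalies
#'
#' Subtracts from each day the mean of its calendar month over the
#' climatology period (all days of that month across the reference years).
#' A monthly rather than daily climatology is used because a short record
#' gives each calendar day only a handful of values. Months with no
#' observations in the reference period yield missing anomalies.
#'
#' @param series an \code{indicator_series} of raw values.
#' @param clim_years years defining the climatology period (default: all
#'   years present in the series).
#' @return anomaly \code{indicator_series} with attribute
#'   \code{climatology} (data.frame month, mean_value, n_days).
#' @export
anomalize <- function(series, clim_years = NULL) {
  yr <- as.integer(format(series$date, "%Y"))
  mo <- as.integer(format(series$date, "%m"))
  if (is.null(clim_years)) clim_years <- unique(yr)
  ref <- yr %in% clim_years & !is.na(series$value)
  mean_m <- tapply(series$value[ref], mo[ref], mean)
  n_m <- tapply(rep(1, sum(ref)), mo[ref], sum)
  clim <- data.frame(month = 1:12,
                     mean_value = as.numeric(mean_m[as.character(1:12)]),
                     n_days = as.integer(ifelse(is.na(n_m[as.character(1:12)]),
                                                0L, n_m[as.character(1:12)])))
  anom <- series$value - clim$mean_value[mo]
  update_series(series, anom, is_anomaly = TRUE, climatology = clim)
}

#' Right-aligned rolling-mean smoothing
#'
#' The value at day t is the mean of the available values over the window
#' [t - window + 1, t]. A smoothed value is only emitted when at least
#' \code{min_coverage} of the window days are present, so sparse stretches
#' stay missing rather than being represented by a handful of days.
#'
#' @param series an \code{indicator_series} (daily axis; gaps allowed).
#' @param window window length in days, default 30.
#' @param min_coverage minimum non-missing days in the window, default half
#'   the window.
#' @return smoothed \code{indicator_series}.
#' @export
smooth_series <- function(series, window = 30, min_coverage = ceiling(window / 2)) {
  if (window < 1) stop("smooth_series: window must be >= 1")
  v <- series$value
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  cs <- cumsum(v0); cn <- cumsum(ok)
  n <- length(v)
  lag <- function(x) c(rep(0, min(window, n)), x)[seq_len(n)]
  run_sum <- cs - lag(cs)
  run_n <- cn - lag(cn)
  out <- ifelse(run_n >= min_coverage, run_sum / pmax(run_n, 1L), NA_real_)
  update_series(series, out, smoothed = TRUE)
}

#' Restrict a series to the fishing season
#'
#' Keeps only days whose calendar month falls in the season (default
#' July-October, the peak albacore fishing season). Applied after
#' smoothing, so season-edge values still integrate the preceding window.
#'
#' @param series an \code{indicator_series}.
#' @param months months retained, default 7:10.
#' @return season-restricted series (no longer on a complete daily axis).
#' @export
restrict_season <- function(series, months = 7:10) {
  keep <- as.integer(format(series$date, "%m")) %in% months
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("name", "units", "is_anomaly", "smoothed", "climatology"))
    attr(out, a) <- attr(series, a)
  class(out) <- class(series)
  out
}

#' Standard indicator processing chain
#'
#' Applies the fixed processing order used for every indicator: monthly
#' climatology anomalies, then 30-day right-aligned smoothing, then
#' (optionally) restriction to the July-October fishing season.
#'
#' @param series raw \code{indicator_series}.
#' @param clim_years climatology reference years (default: all).
#' @param window smoothing window, days.
#' @param season months retained, or \code{NULL} to skip restriction.
#' @return processed \code{indicator_series}.
#' @export
process_indicator <- function(series, clim_years = NULL, window = 30,
                              season = 7:10) {
  out <- smooth_series(anomalize(series, clim_years), window)
  if (!is.null(season)) out <- restrict_season(out, season)
  out
}

#' Annual fishing-season CPUE
#'
#' Per-year mean of daily July-October CPUE, with anomalies relative to the
#' across-year mean of the annual values. This is the annual availability
#' index whose collapse flags a poor season.
#'
#' @param series_cpue raw daily \code{vms_cpue} series (not anomalized).
#' @param months season months, default 7:10.
#' @return data.frame (year, value, anomaly) of class \code{annual_series}.
#' @export
annual_cpue <- function(series_cpue, months = 7:10) {
  mo <- as.integer(format(series_cpue$date, "%m"))
  yr <- as.integer(format(series_cpue$date, "%Y"))
  keep <- mo %in% months
  val <- tapply(series_cpue$value[keep], yr[keep], mean, na.rm = TRUE)
  val[is.nan(val)] <- NA_real_
  out <- data.frame(year = as.integer(names(val)), value = as.numeric(val))
  out$anomaly <- out$value - mean(out$value, na.rm = TRUE)
  structure(out, class = c("annual_series", "data.frame"),
            name = attr(series_cpue, "name"), units = attr(series_cpue, "units"))
}

#' Confidentiality-aware gridded effort map
#'
#' Sums fishing time (hours of time-forward) on a regular lon/lat grid and
#' suppresses cells visited by fewer than \code{min_vessels} distinct
#' vessels, the standard confidentiality rule for vessel-level data. The
#' share of effort-hours and of pings lost to suppression is reported.
#'
#' @param linked \code{linked_pings}.
#' @param resolution cell size in degrees, default 0.1.
#' @param min_vessels minimum distinct vessels per retained cell, default 4
#'   (cells with fewer are suppressed; exactly 4 is retained).
#' @return data.frame (lon, lat of cell centres, hours, n_vessels,
#'   suppressed) with attribute \code{suppressed_share} (named: hours,
#'   pings).
#' @export
grid_effort <- function(linked, resolution = 0.1, min_vessels = 4) {
  cx <- floor(linked$lon / resolution)
  cy <- floor(linked$lat / resolution)
  cell <- paste(cx, cy, sep = ":")
  hours <- tapply(linked$time_forward / 60, cell, sum)
  nves <- tapply(linked$vessel_id, cell, function(v) length(unique(v)))
  npings <- tapply(rep(1L, length(cell)), cell, sum)
  parts <- do.call(rbind, strsplit(names(hours), ":", fixed = TRUE))
  out <- data.frame(
    lon = (as.numeric(parts[, 1]) + 0.5) * resolution,
    lat = (as.numeric(parts[, 2]) + 0.5) * resolution,
    hours = as.numeric(hours),
    n_vessels = as.integer(nves),
    n_pings = as.integer(npings))
  out$suppressed <- out$n_vessels < min_vessels
  attr(out, "suppressed_share") <- c(
    hours = sum(out$hours[out$suppressed]) / sum(out$hours),
    pings = sum(out$n_pings[out$suppressed]) / sum(out$n_pings))
  out
}
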