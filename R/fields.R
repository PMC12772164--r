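#' Daily gridded field
#'
#' Lightweight container for a daily rectilinear lat/lon field (sea-surface
#' temperature, habitat suitability). Values are stored as an array with
#' dimensions (lat, lon, time); the time axis is a contiguous sequence of
#' calendar days (UTC).
#'
#' @param lat,lon cell-centre coordinate vectors, strictly increasing.
#' @param dates Date vector, one entry per time slice, strictly increasing
#'   by one day.
#' @param values array of dim (length(lat), length(lon), length(dates)).
#' @param name field name, e.g. "sst" or "habitat_albacore".
#' @param units value units.
#' @return object of class \code{daily_field}.
#' @export
daily_field <- function(lat, lon, dates, values, name = "field", units = "") {
  stopifnot(is.numeric(lat), is.numeric(lon), inherits(dates, "Date"))
  if (!identical(dim(values), c(length(lat), length(lon), length(dates))))
    stop("daily_field: values must have dim (n_lat, n_lon, n_days)")
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0))
    stop("daily_field: lat and lon must be strictly increasing")
  structure(list(lat = lat, lon = lon, dates = dates, values = values,
                 name = name, units = units),
            class = "daily_field")
}

#' @export
print.daily_field <- function(x, ...) {
  cat(sprintf("<daily_field '%s'> %d lat x %d lon x %d days (%s to %s)\n",
              x$name, length(x$lat), length(x$lon), length(x$dates),
              min(x$dates), max(x$dates)))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f%s\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

# internal: matrix slice for one day (lat x lon), NULL if absent
field_day <- function(field, date) {
  i <- match(date, field$dates)
  if (is.na(i)) return(NULL)
  field$values[, , i, drop = TRUE]
}

# internal: cell-centre coordinate grids as vectors (row-major lat-fastest,
# matching as.vector of a (lat x lon) slice)
field_cells <- function(field) {
  list(lat = rep(field$lat, times = length(field$lon)),
       lon = rep(field$lon, each = length(field$lat)))
}

#' Write / read a daily field as plain-text CSV
#'
#' Long-format interchange (date, lat, lon, value) so that gridded inputs
#' can be shipped and diffed as text.
#'
#' @param field a \code{daily_field}.
#' @param path CSV file path.
#' @return \code{read_field} returns a \code{daily_field}.
#' @export
write_field <- function(field, path) {
  cells <- field_cells(field)
  n_cell <- length(cells$lat)
  df <- data.frame(
    date = rep(field$dates, each = n_cell),
    lat = rep(cells$lat, times = length(field$dates)),
    lon = rep(cells$lon, times = length(field$dates)),
    value = as.vector(field$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @param name,units passed to \code{daily_field}.
#' @export
read_field <- function(path, name = "field", units = "") {
  df <- utils::read.csv(path, colClasses = c(date = "Date"))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  dates <- sort(unique(df$date))
  arr <- array(NA_real_, c(length(lat), length(lon), length(dates)))
  arr[cbind(match(df$lat, lat), match(df$lon, lon), match(df$date, dates))] <-
    df$value
  daily_field(lat, lon, dates, arr, name = name, units = units)
}
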