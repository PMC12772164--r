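#' Nearest-rank empirical quantile
#'
#' Inverse empirical CDF (type-1) quantile: the value at rank
#' \code{ceiling(p * n)} of the sorted non-missing values. This single
#' percentile definition is used everywhere in the package (trip-length cap,
#' core-habitat threshold, extreme-event thresholds) so that thresholds are
#' always attained sample values.
#'
#' @param x numeric vector; missing values are dropped.
#' @param p probability in (0, 1].
#' @return the nearest-rank quantile of \code{x}.
#' @examples
#' nearest_rank_quantile(1:100, 0.90)  # 90
#' nearest_rank_quantile(c(2, 4, 6, 20), 0.75)  # 6
#' @export
nearest_rank_quantile <- function(x, p) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("nearest_rank_quantile: no non-missing values")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("nearest_rank_quantile: 'p' must be a single probability in (0, 1]")
  sort(x)[max(1L, ceiling(p * n))]
}

# internal: check a scalar field of a config, error naming the field
check_scalar <- function(value, field, lower = -Inf, upper = Inf,
                         integerish = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value))
    stop(sprintf("scenario_config: '%s' must be a single finite number", field),
         call. = FALSE)
  if (value < lower || value > upper)
    stop(sprintf("scenario_config: '%s' must be in [%s, %s]",
                 field, format(lower), format(upper)), call. = FALSE)
  if (integerish && value != round(value))
    stop(sprintf("scenario_config: '%s' must be an integer", field),
         call. = FALSE)
  invisible(TRUE)
}

# internal: days between two POSIXct/Date vectors
days_between <- function(t0, t1) {
  as.numeric(difftime(t1, t0, units = "days"))
}

# internal: complete daily axis between first and last date of a data.frame
complete_daily <- function(df) {
  stopifnot(inherits(df$date, "Date"))
  if (nrow(df) == 0L) return(df)
  axis <- seq(min(df$date), max(df$date), by = "day")
  out <- df[match(axis, df$date), , drop = FALSE]
  out$date <- axis
  rownames(out) <- NULL
  out
}
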