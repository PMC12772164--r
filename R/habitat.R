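#' SST anomaly series inside the effort kernel
#'
#' Daily area-mean sea-surface temperature over the cells of the fleet's
#' 75th-percentile utilization kernel, turned into a smoothed
#' monthly-climatology anomaly (same chain as the fleet indicators). The
#' masking restricts the environmental signal to where fishing actually
#' happens. Climatology is computed after area-averaging.
#'
#' @param sst_field a \code{daily_field} of SST.
#' @param mask an \code{\link{effort_kernel_mask}} aligned to the SST grid.
#' @param clim_years climatology reference years (default: all).
#' @param window smoothing window in days.
#' @param process apply anomalize + smoothing (default TRUE); if FALSE the
#'   raw masked daily mean is returned.
#' @return \code{indicator_series} named \code{ssta} (degrees C).
#' @export
ssta_series <- function(sst_field, mask, clim_years = NULL, window = 30,
                        process = TRUE) {
  if (!any(mask$in_kernel)) stop("ssta_series: empty kernel mask")
  if (!identical(mask$lat, sst_field$lat) || !identical(mask$lon, sst_field$lon))
    stop("ssta_series: mask grid does not match the SST grid")
  sel <- which(mask$in_kernel)  # indices into a (lat x lon) slice
  nt <- length(sst_field$dates)
  ncell <- length(sst_field$lat) * length(sst_field$lon)
  vals <- matrix(sst_field$values, nrow = ncell, ncol = nt)
  daily <- colMeans(vals[sel, , drop = FALSE], na.rm = TRUE)
  raw <- indicator_series(sst_field$dates, daily, "ssta", "degC")
  if (!process) return(raw)
  smooth_series(anomalize(raw, clim_years), window)
}

#' Core-habitat distribution indicators
#'
#' Per species and day: the habitat-suitability field is masked to the EEZ
#' polygon, the day's 75th-percentile (nearest-rank) suitability over the
#' masked cells defines the core-habitat threshold, cells strictly above
#' the threshold form the core, and the suitability-weighted latitude
#' centroid and suitability-weighted mean distance to shore of the core
#' cells are computed. The two raw series are then anomalized and smoothed
#' like the fleet indicators. Days whose core is empty (e.g. a uniform
#' field under the strict threshold) are missing.
#'
#' @param habitat_field a \code{daily_field} of suitability in [0, 1].
#' @param eez EEZ polygon matrix (lon, lat).
#' @param coastline coastline polyline matrix (lon, lat).
#' @param core_percentile core-habitat threshold percentile, default 0.75.
#' @param clim_years climatology reference years (default: all).
#' @param window smoothing window in days.
#' @param process apply anomalize + smoothing (default TRUE).
#' @return named list of two \code{indicator_series}: \code{y} (degrees
#'   latitude) and \code{shore} (km).
#' @export
habitat_indicators <- function(habitat_field, eez, coastline,
                               core_percentile = 0.75, clim_years = NULL,
                               window = 30, process = TRUE) {
  cells <- field_cells(habitat_field)
  in_eez <- point_in_polygon(cells$lon, cells$lat, eez)
  if (!any(in_eez)) stop("habitat_indicators: EEZ polygon does not overlap grid")
  shore_km <- dist_to_coast(cells$lon[in_eez], cells$lat[in_eez], coastline)
  lat_eez <- cells$lat[in_eez]
  nt <- length(habitat_field$dates)
  ncell <- length(cells$lat)
  vals <- matrix(habitat_field$values, nrow = ncell, ncol = nt)[in_eez, , drop = FALSE]
  y <- numeric(nt); sh <- numeric(nt)
  for (t in seq_len(nt)) {
    v <- vals[, t]
    thr <- nearest_rank_quantile(v, core_percentile)
    core <- !is.na(v) & v > thr
    if (!any(core)) { y[t] <- NA_real_; sh[t] <- NA_real_; next }
    wv <- v[core]
    y[t] <- sum(lat_eez[core] * wv) / sum(wv)
    sh[t] <- sum(shore_km[core] * wv) / sum(wv)
  }
  sp <- sub("^habitat_", "", habitat_field$name)
  ys <- indicator_series(habitat_field$dates, y,
                         paste0("habitat_y_", sp), "deg lat")
  ss <- indicator_series(habitat_field$dates, sh,
                         paste0("habitat_shore_", sp), "km")
  if (process) {
    ys <- smooth_series(anomalize(ys, clim_years), window)
    ss <- smooth_series(anomalize(ss, clim_years), window)
  }
  list(y = ys, shore = ss)
}
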