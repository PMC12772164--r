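#' Build the full indicator set from a scenario bundle
#'
#' End-to-end pipeline from raw pings, receipts, gridded fields and driver
#' series to the season-restricted smoothed anomaly series used for skill
#' scoring and driver attribution: links VMS to landings, builds the three
#' fleet series (Y centroid, distance to shore, CPUE), estimates the
#' pooled effort kernel and the masked SSTa series, computes core-habitat
#' centroid and distance series per species, and processes the driver
#' series through the same chain (gap interpolation, monthly-climatology
#' anomalies, 30-day smoothing, July-October restriction).
#'
#' @param bundle a \code{scenario_bundle} from \code{\link{gen_scenario}},
#'   or any list with the same elements.
#' @param kernel_percentile utilization percentile of the effort kernel.
#' @param core_percentile core-habitat threshold percentile.
#' @param window smoothing window in days.
#' @param season months retained, default 7:10.
#' @param trip_cap \code{"auto"} or days, passed to the linkage.
#' @return object of class \code{indicator_set}: named list of
#'   season-restricted smoothed anomaly \code{indicator_series} (vms_y,
#'   vms_shore, vms_cpue, ssta, habitat_y_*, habitat_shore_*, fuel,
#'   alerts, price), with attributes \code{linked} (the linked pings),
#'   \code{kernel} (the effort kernel) and \code{raw} (raw daily series).
#' @export
build_indicator_set <- function(bundle, kernel_percentile = 0.75,
                                core_percentile = 0.75, window = 30,
                                season = 7:10, trip_cap = "auto") {
  linked <- link_vms_landings(bundle$pings, bundle$receipts,
                              trip_cap = trip_cap)
  raw <- list(
    vms_y = daily_effort_centroid(linked),
    vms_shore = daily_distance_to_shore(linked, bundle$coastline),
    vms_cpue = daily_cpue(linked))
  out <- lapply(raw, process_indicator, window = window, season = season)

  kern <- effort_kernel_mask(linked, bundle$sst,
                             percentile = kernel_percentile)
  ssta_sm <- ssta_series(bundle$sst, kern, window = window)
  raw$ssta <- ssta_series(bundle$sst, kern, process = FALSE)
  out$ssta <- restrict_season(ssta_sm, season)

  for (sp in names(bundle$habitat)) {
    hi <- habitat_indicators(bundle$habitat[[sp]], bundle$eez,
                             bundle$coastline,
                             core_percentile = core_percentile,
                             window = window)
    out[[paste0("habitat_y_", sp)]] <- restrict_season(hi$y, season)
    out[[paste0("habitat_shore_", sp)]] <- restrict_season(hi$shore, season)
  }

  drv <- bundle$drivers
  drv_cols <- c(fuel = "fuel_price", alerts = "alert_area",
                price = "price_per_pound")
  for (nm in names(drv_cols)) {
    filled <- interpolate_gaps(drv[[drv_cols[[nm]]]])
    s <- indicator_series(drv$date, filled, nm)
    out[[nm]] <- process_indicator(s, window = window, season = season)
  }

  structure(out, class = "indicator_set", linked = linked, kernel = kern,
            raw = raw)
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("<indicator_set> %d series: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  n_days <- vapply(x, function(s) sum(!is.na(s$value)), integer(1))
  cat("  non-missing season days per series:\n")
  print(n_days)
  invisible(x)
}

#' Standard driver-attribution models
#'
#' Fits the two standard regressions: the fleet's latitudinal shifts
#' (vms_y) and inshore/offshore shifts (vms_shore), each on the same-axis
#' habitat shift of the target species, SSTa, fuel price, weather-alert
#' area and price per pound.
#'
#' @param indicators an \code{indicator_set}.
#' @param species target species name used for the habitat predictors.
#' @param robust passed to \code{\link{fit_driver_model}}.
#' @return named list of two \code{driver_fit} objects (\code{vms_y},
#'   \code{vms_shore}).
#' @export
fit_driver_models <- function(indicators, species = "albacore",
                              robust = FALSE) {
  frame <- indicator_frame(indicators)
  common <- c("ssta", "fuel", "alerts", "price")
  list(
    vms_y = fit_driver_model(frame, "vms_y",
                             c(paste0("habitat_y_", species), common),
                             robust = robust),
    vms_shore = fit_driver_model(frame, "vms_shore",
                                 c(paste0("habitat_shore_", species), common),
                                 robust = robust))
}
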