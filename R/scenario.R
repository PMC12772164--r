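#' Scenario configuration for the synthetic fishery
#'
#' Parameters of the synthetic study system: a multi-year albacore troll
#' fishery on a West-Coast-like domain (about 131-124.5 degrees W, 38-49
#' degrees N) with hourly vessel-monitoring pings, shoreside landings
#' receipts, daily gridded SST and habitat-suitability fields, and daily
#' economic driver series. Heatwave years add a warm SST anomaly over the
#' July-October fishing season and shift the habitat field northward and
#' inshore; the fleet follows the habitat shift with mixing weight
#' \code{effort_tracking}.
#'
#' @param years inclusive vector of calendar years simulated.
#' @param n_vessels number of vessels in the fleet.
#' @param ping_interval nominal minutes between pings.
#' @param heatwave_years subset of \code{years} with heatwave conditions.
#' @param ssta_amplitude degrees C added to SST in heatwave fishing seasons.
#' @param habitat_shift_lat degrees of northward habitat-centroid shift in
#'   heatwave fishing seasons.
#' @param habitat_shift_shore km of inshore habitat shift in heatwave
#'   fishing seasons.
#' @param effort_tracking fraction in [0,1] of trips whose fishing grounds
#'   follow the (possibly shifted) habitat centre; the remainder are placed
#'   uniformly at random.
#' @param cpue_base pounds of albacore landed per minute of fishing time.
#' @param cpue_heatwave_factor multiplier in (0,1] applied to CPUE in
#'   heatwave years.
#' @param grid_resolution grid cell size in degrees for SST/habitat fields.
#' @param seed integer random seed; the whole bundle is deterministic in it.
#' @param species species with habitat fields; first is the landed target.
#' @param trips_per_season fishing trips per vessel per season.
#' @param trip_days_mean mean trip duration in days.
#' @param gap_fraction fraction of at-sea pings starting a transmission gap
#'   longer than two ping intervals.
#' @param flag_fraction fraction of pings carrying the GIS quality flag.
#' @param mixed_receipt_fraction fraction of receipts whose albacore share
#'   of landed weight falls below 90 percent.
#' @param driver_effects optional named vector of true standardized effects
#'   (names among "fuel", "alerts", "price") wired into the driver series'
#'   synthetic response column; see \code{\link{gen_drivers}}.
#' @return validated list of class \code{scenario_config}.
#' @seealso \code{\link{gen_scenario}}
#' @export
scenario_config <- function(years = 2010:2024,
                            n_vessels = 20,
                            ping_interval = 60,
                            heatwave_years = 2014:2016,
                            ssta_amplitude = 2,
                            habitat_shift_lat = 1.5,
                            habitat_shift_shore = 30,
                            effort_tracking = 0.8,
                            cpue_base = 7.8,
                            cpue_heatwave_factor = 0.54,
                            grid_resolution = 0.5,
                            seed = 1,
                            species = "albacore",
                            trips_per_season = 4,
                            trip_days_mean = 8,
                            gap_fraction = 0.02,
                            flag_fraction = 0.01,
                            mixed_receipt_fraction = 0.1,
                            driver_effects = NULL) {
  if (length(years) < 1L || any(years != round(years)))
    stop("scenario_config: 'years' must be integer years")
  if (!all(heatwave_years %in% years))
    stop("scenario_config: 'heatwave_years' must be a subset of 'years'")
  check_scalar(n_vessels, "n_vessels", lower = 1, integerish = TRUE)
  check_scalar(ping_interval, "ping_interval", lower = 1)
  check_scalar(ssta_amplitude, "ssta_amplitude", lower = 0)
  check_scalar(habitat_shift_lat, "habitat_shift_lat", lower = -5, upper = 5)
  check_scalar(habitat_shift_shore, "habitat_shift_shore", lower = -200, upper = 200)
  check_scalar(effort_tracking, "effort_tracking", lower = 0, upper = 1)
  check_scalar(cpue_base, "cpue_base", lower = 0)
  check_scalar(cpue_heatwave_factor, "cpue_heatwave_factor", lower = 1e-6, upper = 1)
  check_scalar(grid_resolution, "grid_resolution", lower = 1e-3)
  check_scalar(seed, "seed", integerish = TRUE)
  check_scalar(trips_per_season, "trips_per_season", lower = 1, integerish = TRUE)
  check_scalar(trip_days_mean, "trip_days_mean", lower = 2)
  check_scalar(gap_fraction, "gap_fraction", lower = 0, upper = 0.5)
  check_scalar(flag_fraction, "flag_fraction", lower = 0, upper = 0.5)
  check_scalar(mixed_receipt_fraction, "mixed_receipt_fraction", lower = 0, upper = 1)
  if (!is.null(driver_effects)) {
    if (is.null(names(driver_effects)) ||
        !all(names(driver_effects) %in% c("fuel", "alerts", "price")))
      stop("scenario_config: 'driver_effects' names must be among fuel, alerts, price")
  }
  structure(list(
    years = sort(unique(as.integer(years))),
    n_vessels = as.integer(n_vessels),
    ping_interval = ping_interval,
    heatwave_years = sort(unique(as.integer(heatwave_years))),
    ssta_amplitude = ssta_amplitude,
    habitat_shift_lat = habitat_shift_lat,
    habitat_shift_shore = habitat_shift_shore,
    effort_tracking = effort_tracking,
    cpue_base = cpue_base,
    cpue_heatwave_factor = cpue_heatwave_factor,
    grid_resolution = grid_resolution,
    seed = as.integer(seed),
    species = species,
    trips_per_season = as.integer(trips_per_season),
    trip_days_mean = trip_days_mean,
    gap_fraction = gap_fraction,
    flag_fraction = flag_fraction,
    mixed_receipt_fraction = mixed_receipt_fraction,
    driver_effects = driver_effects,
    # fixed domain geometry
    lon_range = c(-131, -124.5), lat_range = c(38, 49), coast_lon = -124.5,
    season_months = 7:10),
    class = "scenario_config")
}

# deterministic habitat centre (no daily noise): seasonal cycle peaking in
# mid-August plus the heatwave-season shift; this is the component the fleet
# can anticipate and track
habitat_centre <- function(config, dates, shifted = TRUE) {
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  hw <- (yr %in% config$heatwave_years) & (mo %in% config$season_months)
  clat <- 42.5 + 0.9 * cos(2 * pi * (doy - 227) / 365.25)
  clon <- rep(-127.2, length(dates))
  if (shifted) {
    clat <- clat + ifelse(hw, config$habitat_shift_lat, 0)
    dlon <- config$habitat_shift_shore / (111.320 * cos(clat * pi / 180))
    clon <- clon + ifelse(hw, dlon, 0)  # eastward = inshore
  }
  list(lat = clat, lon = clon, heatwave = hw)
}

# AR(1) series helper
ar1 <- function(n, rho, sd) {
  as.numeric(stats::arima.sim(model = list(ar = rho), n = n,
                              sd = sd * sqrt(1 - rho^2)))
}

#' Generate a complete synthetic scenario bundle
#'
#' Simulates the full study system under a \code{\link{scenario_config}}:
#' per-vessel fishing trips emitting hourly pings (port departure, fast
#' transit, slow fishing near the habitat centre, return) with injected
#' signal gaps and quality flags; one multi-species landings receipt per
#' trip whose albacore pounds equal the trip's fishing minutes times the
#' CPUE rate (exact by construction); daily gridded SST and habitat
#' suitability sharing one grid and time axis; daily driver series; and the
#' synthetic coastline and EEZ polygons. Fully deterministic given
#' \code{config$seed}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return list of class \code{scenario_bundle} with elements \code{pings},
#'   \code{receipts}, \code{sst}, \code{habitat} (named list of
#'   \code{daily_field}), \code{drivers}, \code{coastline}, \code{eez},
#'   \code{truth} (the config) and \code{ping_truth} (logical ground-truth
#'   fishing classification, one entry per ping row).
#' @export
gen_scenario <- function(config) {
  if (!inherits(config, "scenario_config"))
    config <- do.call(scenario_config, config)
  set.seed(config$seed)

  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  nt <- length(dates)
  res <- config$grid_resolution
  glat <- seq(config$lat_range[1] + res / 2, config$lat_range[2] - res / 2, by = res)
  glon <- seq(config$lon_range[1] + res / 2, config$lon_range[2] - res / 2, by = res)
  nlat <- length(glat); nlon <- length(glon)

  doy <- as.integer(format(dates, "%j"))
  ctr <- habitat_centre(config, dates, shifted = TRUE)
  hw <- ctr$heatwave

  ## --- SST field: latitudinal gradient + seasonal cycle + heatwave bump +
  ##     autocorrelated basin noise + iid cell noise
  seasonal <- 3 * cos(2 * pi * (doy - 227) / 365.25)
  basin <- ar1(nt, rho = 0.8, sd = 0.25)
  sst_base <- outer(18 - 0.45 * (glat - 38), rep(1, nlon))  # nlat x nlon
  sst <- array(rep(sst_base, nt), c(nlat, nlon, nt))
  bump <- seasonal + config$ssta_amplitude * hw + basin
  sst <- sst + rep(bump, each = nlat * nlon)
  sst <- sst + array(stats::rnorm(nlat * nlon * nt, sd = 0.15), c(nlat, nlon, nt))
  sst_field <- daily_field(glat, glon, dates, sst, name = "sst", units = "degC")

  ## --- habitat suitability fields: Gaussian hotspot around the (noisy)
  ##     habitat centre; daily centre = deterministic centre + AR(1) wander
  habitat <- list()
  for (k in seq_along(config$species)) {
    sp <- config$species[k]
    off <- (k - 1) * -1.0       # additional species sit further south
    clat_t <- ctr$lat + off + ar1(nt, rho = 0.9, sd = 0.15)
    clon_t <- ctr$lon + ar1(nt, rho = 0.9, sd = 0.10)
    sl <- 1.5; so <- 1.2
    A <- exp(-0.5 * (outer(glat, clat_t, "-") / sl)^2)   # nlat x nt
    B <- exp(-0.5 * (outer(glon, clon_t, "-") / so)^2)   # nlon x nt
    vals <- array(0, c(nlat, nlon, nt))
    for (t in seq_len(nt)) vals[, , t] <- A[, t] %o% B[, t]
    habitat[[sp]] <- daily_field(glat, glon, dates, vals,
                                 name = paste0("habitat_", sp), units = "suitability")
  }

  ## --- fleet simulation: trips -> pings + receipts
  interval_min <- config$ping_interval
  season_start_doy <- 166   # mid June
  season_len <- 132         # through late October
  window <- season_len / config$trips_per_season

  ping_list <- list(); receipt_list <- list(); truth_list <- list()
  ticket_no <- 0L
  port_lat <- pmin(48.5, pmax(39, stats::rnorm(config$n_vessels, 46, 1.8)))

  for (v in seq_len(config$n_vessels)) {
    vid <- sprintf("V%03d", v)
    for (yr in config$years) {
      year_start <- as.Date(sprintf("%d-01-01", yr))
      for (tr in seq_len(config$trips_per_season)) {
        start_day <- season_start_doy + (tr - 1) * window + stats::runif(1, 0, 8)
        dur_days <- min(window - 6, max(3, stats::rnorm(1, config$trip_days_mean, 2)))
        t0 <- as.POSIXct(year_start, tz = "UTC") +
          (start_day - 1) * 86400 + stats::runif(1, 5, 9) * 3600

        mid_date <- year_start + floor(start_day + dur_days / 2)
        mid_i <- as.integer(mid_date - dates[1]) + 1L
        if (stats::runif(1) < config$effort_tracking) {
          fc_lat <- ctr$lat[mid_i] + stats::rnorm(1, 0, 0.35)
          fc_lon <- ctr$lon[mid_i] + stats::rnorm(1, 0, 0.30)
        } else {
          fc_lat <- stats::runif(1, config$lat_range[1] + 0.5, config$lat_range[2] - 0.5)
          fc_lon <- stats::runif(1, config$lon_range[1] + 0.5, config$coast_lon - 0.7)
        }
        fc_lat <- min(config$lat_range[2] - 0.3, max(config$lat_range[1] + 0.3, fc_lat))
        fc_lon <- min(config$coast_lon - 0.5, max(config$lon_range[1] + 0.3, fc_lon))

        n_ping <- max(12L, as.integer(round(dur_days * 1440 / interval_min)))
        times <- t0 + (seq_len(n_ping) - 1L) * interval_min * 60

        # transit legs sized by distance at ~8.5 kn
        p_lon <- config$coast_lon; p_lat <- port_lat[v]
        d_km <- geosphere::distHaversine(c(p_lon, p_lat), c(fc_lon, fc_lat)) / 1000
        leg_h <- d_km / (8.5 * 1.852)
        n_leg <- min(as.integer(ceiling(leg_h * 60 / interval_min)) + 1L,
                     as.integer(n_ping * 0.3))
        n_leg <- max(2L, n_leg)
        i_out <- seq_len(n_leg)
        i_back <- seq(n_ping - n_leg + 1L, n_ping)
        i_fish <- setdiff(seq_len(n_ping), c(i_out, i_back))
        if (length(i_fish) < 4L) { i_fish <- (n_leg + 1L):(n_ping - n_leg) }

        lat <- numeric(n_ping); lon <- numeric(n_ping)
        frac_out <- (i_out - 1) / max(1, n_leg - 1)
        lat[i_out] <- p_lat + frac_out * (fc_lat - p_lat)
        lon[i_out] <- p_lon + frac_out * (fc_lon - p_lon)
        frac_back <- (seq_along(i_back) - 1) / max(1, n_leg - 1)
        lat[i_back] <- fc_lat + frac_back * (p_lat - fc_lat)
        lon[i_back] <- fc_lon + frac_back * (p_lon - fc_lon)
        lat[i_fish] <- fc_lat + stats::rnorm(length(i_fish), 0, 0.12)
        lon[i_fish] <- fc_lon + stats::rnorm(length(i_fish), 0, 0.12)
        lon <- pmin(config$coast_lon - 0.05, pmax(config$lon_range[1] + 0.05, lon))
        lat <- pmin(config$lat_range[2] - 0.05, pmax(config$lat_range[1] + 0.05, lat))

        speed <- numeric(n_ping)
        speed[c(i_out, i_back)] <- stats::runif(2 * n_leg, 7, 10)
        speed[i_fish] <- stats::runif(length(i_fish), 0.5, 3.2)
        is_fish <- logical(n_ping); is_fish[i_fish] <- TRUE

        event <- rep("at_sea", n_ping)
        event[1] <- "departing_port"; event[n_ping] <- "in_port"
        speed[c(1, n_ping)] <- stats::runif(2, 0, 0.5)
        lat[c(1, n_ping)] <- p_lat; lon[c(1, n_ping)] <- p_lon
        is_fish[c(1, n_ping)] <- FALSE

        # transmission gaps: drop short runs of pings so the preceding
        # ping's time-forward exceeds two intervals
        keep <- rep(TRUE, n_ping)
        gap_starts <- which(stats::runif(n_ping) < config$gap_fraction)
        for (g in gap_starts) {
          k <- sample(2:4, 1)
          drop <- seq(g + 1L, min(n_ping - 1L, g + k))
          if (length(drop)) keep[drop] <- FALSE
        }
        keep[c(1, n_ping)] <- TRUE
        times <- times[keep]; lat <- lat[keep]; lon <- lon[keep]
        speed <- speed[keep]; event <- event[keep]; is_fish <- is_fish[keep]
        m <- length(times)
        tf <- c(as.numeric(diff(times), units = "mins"), interval_min)
        flag <- stats::runif(m) < config$flag_fraction

        ping_list[[length(ping_list) + 1L]] <- data.frame(
          timestamp = times, vessel_id = vid, lat = lat, lon = lon,
          event_type = event, time_forward = tf, speed = speed,
          gis_flag = flag, stringsAsFactors = FALSE)
        truth_list[[length(truth_list) + 1L]] <- is_fish

        # receipt: albacore pounds = CPUE rate x true fishing minutes
        ticket_no <- ticket_no + 1L
        tid <- sprintf("T%06d", ticket_no)
        rate <- config$cpue_base *
          (if (yr %in% config$heatwave_years) config$cpue_heatwave_factor else 1) *
          exp(stats::rnorm(1, 0, 0.1))
        alb_lbs <- rate * sum(tf[is_fish])
        if (stats::runif(1) < config$mixed_receipt_fraction) {
          alb_frac <- stats::runif(1, 0.5, 0.88)
        } else {
          alb_frac <- stats::runif(1, 0.92, 1)
        }
        other_lbs <- alb_lbs * (1 - alb_frac) / alb_frac
        r_time <- times[m] + stats::runif(1, 1, 5) * 3600
        rec <- data.frame(
          ticket_id = tid, vessel_id = vid, timestamp = r_time,
          species = c("albacore", "other"),
          pounds = c(alb_lbs, other_lbs),
          price_per_pound = c(stats::rnorm(1, 2, 0.2), stats::rnorm(1, 1, 0.2)),
          stringsAsFactors = FALSE)
        receipt_list[[length(receipt_list) + 1L]] <-
          rec[rec$pounds > 0 | rec$species == "albacore", , drop = FALSE]
      }
    }
  }

  pings <- do.call(rbind, ping_list)
  receipts <- do.call(rbind, receipt_list)
  rownames(pings) <- rownames(receipts) <- NULL
  drivers <- gen_drivers(config)

  structure(list(
    pings = pings,
    receipts = receipts,
    sst = sst_field,
    habitat = habitat,
    drivers = drivers,
    coastline = synthetic_coastline(config$coast_lon, config$lat_range),
    eez = synthetic_eez(config$coast_lon, config$lon_range[1] + 0.5,
                        config$lat_range + c(0.5, -0.5)),
    truth = config,
    ping_truth = unlist(truth_list)),
    class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("<scenario_bundle> %d pings, %d receipts, %d vessels, years %d-%d\n",
              nrow(x$pings), length(unique(x$receipts$ticket_id)),
              length(unique(x$pings$vessel_id)),
              min(x$truth$years), max(x$truth$years)))
  cat(sprintf("  heatwave years: %s; species: %s\n",
              paste(x$truth$heatwave_years, collapse = ", "),
              paste(x$truth$species, collapse = ", ")))
  invisible(x)
}

#' Generate daily driver series
#'
#' Daily marine fuel price (USD/gallon), weather-alert area (km2) and
#' ex-vessel albacore price per pound (USD) as autocorrelated series with
#' injected missing-day runs (fuel and price are irregularly collected in
#' real data). If \code{config$driver_effects} is set, a standardized
#' synthetic response column with those true effects (plus unit-variance
#' noise) is attached together with a \code{"true_betas"} attribute, for
#' regression-recovery testing.
#'
#' @param config a \code{\link{scenario_config}}.
#' @return data.frame with columns \code{date}, \code{fuel_price},
#'   \code{alert_area}, \code{price_per_pound} and optionally
#'   \code{response}.
#' @export
gen_drivers <- function(config) {
  if (!inherits(config, "scenario_config"))
    config <- do.call(scenario_config, config)
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  nt <- length(dates)
  doy <- as.integer(format(dates, "%j"))

  fuel <- 3 + 0.6 * ar1(nt, 0.995, 1)
  alerts <- pmax(0, 4000 + 3000 * cos(2 * pi * (doy - 15) / 365.25) +
                   2500 * ar1(nt, 0.7, 1))
  price <- pmax(0.5, 2 + 0.35 * ar1(nt, 0.99, 1))

  gap_runs <- function(x, n_runs, max_len) {
    starts <- sample(seq_len(nt - max_len), n_runs)
    for (s in starts) x[s:(s + sample(max_len, 1) - 1L)] <- NA_real_
    x
  }
  fuel <- gap_runs(fuel, max(1L, nt %/% 120L), 4L)
  price <- gap_runs(price, max(1L, nt %/% 150L), 4L)

  out <- data.frame(date = dates, fuel_price = fuel, alert_area = alerts,
                    price_per_pound = price)
  if (!is.null(config$driver_effects)) {
    be <- config$driver_effects
    z <- function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); (x - mean(x)) / stats::sd(x) }
    cols <- c(fuel = "fuel_price", alerts = "alert_area", price = "price_per_pound")
    lin <- rep(0, nt)
    for (nm in names(be)) lin <- lin + be[[nm]] * z(out[[cols[[nm]]]])
    noise_sd <- sqrt(max(0.05, 1 - sum(unlist(be)^2)))
    out$response <- lin + stats::rnorm(nt, 0, noise_sd)
    attr(out, "true_betas") <- be
  }
  out
}
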