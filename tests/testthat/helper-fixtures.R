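# shared fixtures, memoized so expensive scenarios are built once per run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small 6-year scenario exercising every pipeline stage
small_bundle <- function() {
  cached("small_bundle", function() {
    gen_scenario(scenario_config(years = 2010:2015, n_vessels = 8,
                                 heatwave_years = 2014, seed = 42))
  })
}

small_linked <- function() {
  cached("small_linked", function() {
    b <- small_bundle()
    link_vms_landings(b$pings, b$receipts)
  })
}

small_indicator_set <- function() {
  cached("small_iset", function() build_indicator_set(small_bundle()))
}

# full study-scale scenario (15 years) and its null counterpart
study_bundle <- function() {
  cached("study_bundle", function() gen_scenario(scenario_config(seed = 2024)))
}

null_bundle <- function() {
  cached("null_bundle", function() {
    gen_scenario(scenario_config(seed = 2024, ssta_amplitude = 0,
                                 habitat_shift_lat = 0,
                                 habitat_shift_shore = 0,
                                 cpue_heatwave_factor = 1))
  })
}

study_indicator_set <- function() {
  cached("study_iset", function() build_indicator_set(study_bundle()))
}

null_indicator_set <- function() {
  cached("null_iset", function() build_indicator_set(null_bundle()))
}

# hand-built ping rows for linkage unit tests
make_ping <- function(timestamp, vessel_id = "V001", lat = 44, lon = -126,
                      event_type = "at_sea", time_forward = 60, speed = 2,
                      gis_flag = FALSE) {
  data.frame(timestamp = as.POSIXct(timestamp, tz = "UTC"),
             vessel_id = vessel_id, lat = lat, lon = lon,
             event_type = event_type, time_forward = time_forward,
             speed = speed, gis_flag = gis_flag, stringsAsFactors = FALSE)
}

make_receipt <- function(timestamp, ticket_id, vessel_id = "V001",
                         albacore = 1000, other = 0) {
  df <- data.frame(ticket_id = ticket_id, vessel_id = vessel_id,
                   timestamp = as.POSIXct(timestamp, tz = "UTC"),
                   species = c("albacore", "other"),
                   pounds = c(albacore, other),
                   price_per_pound = c(2, 1), stringsAsFactors = FALSE)
  df[df$pounds > 0 | df$species == "albacore", , drop = FALSE]
}

# independent literal evaluation of the SEDI formula, used as the oracle
sedi_oracle <- function(tp, fp, fn, tn, eps = 1e-9) {
  H <- tp / (tp + fn); F <- fp / (fp + tn)
  H <- pmin(pmax(H, eps), 1 - eps)
  F <- pmin(pmax(F, eps), 1 - eps)
  (log(F) - log(H) - log(1 - F) + log(1 - H)) /
    (log(F) + log(H) + log(1 - F) + log(1 - H))
}

# daily indicator series from a plain numeric vector starting at a date
series_from <- function(values, start = "2015-01-01", name = "x") {
  indicator_series(seq(as.Date(start), by = "day",
                       length.out = length(values)),
                   values, name)
}
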