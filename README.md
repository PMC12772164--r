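# fleetsentinel

Commercial fishing fleets concentrate where their target species are, and
they report where they fish (satellite vessel-monitoring-system pings) and
what they land (landings receipts) at near-real-time cadence. That makes a
fleet a candidate *ecosystem sentinel*: an observing system whose behaviour
reveals climate-driven shifts in species distributions long before surveys
or stock assessments do. `fleetsentinel` implements the full analysis
needed to evaluate that idea for a West-Coast-style albacore troll fishery:

1. **Linkage** — join VMS pings to landings receipts (trip windows capped
   at the 75th percentile of trip lengths), isolate fishing activity with
   quality, at-sea, signal-gap (`time_forward` > 121 min) and speed
   (< 3.74 kn) filters, and distribute each receipt's albacore pounds over
   its fishing pings proportionally to ping duration.
2. **Indicators** — daily pounds-weighted fleet latitude centroid,
   distance to shore, and CPUE (lbs/min); SST anomalies masked to the
   fleet's 75% kernel-density utilization footprint; core-habitat
   (above the daily 75th-percentile suitability) centroid and
   distance-to-shore series per species. Every series is processed the
   same way: monthly-climatology anomalies → 30-day right-aligned rolling
   mean → July–October fishing season.
3. **Skill** — extreme shifts are defined by pooled percentile thresholds
   (70th–95th, six levels) and predictor skill is scored with the
   Symmetric Extremal Dependence Index from the 2×2 contingency table of
   predicted vs. observed extremes,

   ```
   SEDI = [log F − log H − log(1−F) + log(1−H)] /
          [log F + log H + log(1−F) + log(1−H)]
   ```

   with hit ratio `H = TP/(TP+FN)` and false-alarm rate `F = FP/(FP+TN)`.
   SEDI ∈ [−1, 1]; 0 is random, 1 perfect, and it stays stable as events
   become rare. Year-block bootstrap intervals quantify uncertainty.
4. **Drivers** — standardized-coefficient multiple regression attributes
   fleet shifts to ecological drivers (same-axis habitat shift, SSTa)
   versus economic ones (fuel price, weather-alert area, price per pound).

Because real vessel-level VMS and landings data are confidential, the
package ships a synthetic-data generator (`gen_scenario()`) with known
ground truth — heatwave years with warm SST anomalies, northward/inshore
habitat shifts, a fleet that follows habitat with configurable fidelity,
and CPUE collapse — so every stage is testable end to end.

## Worked example

```r
library(fleetsentinel)

cfg <- scenario_config(years = 2010:2015, n_vessels = 8,
                       heatwave_years = 2014, seed = 42)
bundle <- gen_scenario(cfg)
linked <- link_vms_landings(bundle$pings, bundle$receipts)
linked
#> <linked_pings> 24924 fishing pings, 179 receipts, 8 vessels
#>   total allocated: 11248782 lbs; trip cap: 63.9 days

indicators <- build_indicator_set(bundle)
skill <- sedi_grid(indicators, predictors = c("vms_y", "ssta"),
                   responses = "habitat_y_albacore")
skill
#> <sedi_grid> 2 predictor(s) x 1 response(s) x 6 percentile(s)
#>  predictor           response percentile  sedi  tp fp fn  tn degenerate
#>      vms_y habitat_y_albacore       0.70 0.741  38 12 18 100      FALSE
#>      vms_y habitat_y_albacore       0.75 0.826  34  2 20 112      FALSE
#>      vms_y habitat_y_albacore       0.80 0.961  33  0 18 117       TRUE
#>      vms_y habitat_y_albacore       0.85 0.937  17  0 17 134       TRUE
#>      vms_y habitat_y_albacore       0.90 0.980  16  0  4 148       TRUE
#>      vms_y habitat_y_albacore       0.95 0.000   0  0 16 152       TRUE
#>       ssta habitat_y_albacore       0.70 0.661 143 78 78 439      FALSE
#>       ...
```

The fleet's northward shifts (`vms_y`) predict extreme northward habitat
shifts well above random (SEDI 0.74–0.98 across the 70th–90th
percentiles); at the 95th percentile the record contains too few joint
extremes and skill collapses to the degenerate limit — exactly the
caution short records demand of rare-event scores.

```r
annual_cpue(attr(indicators, "raw")$vms_cpue)
#>   year value anomaly
#> 1 2010  7.15   -0.34
#> ...
#> 5 2014  4.40   -3.10
#> 6 2015  8.17    0.67
```

The heatwave year (2014) shows the CPUE collapse the generator injected
(−3.1 lbs/min against an ~8 lbs/min baseline), the annual signal a
disaster-declaration request would rest on.

```r
fit_driver_models(indicators)$vms_y
#> <driver_fit> response: vms_y (n = 168 days, R^2 = 0.823)
#>           predictor   beta    se p_value rank
#>  habitat_y_albacore  0.945 0.222 3.5e-05    1
#>                fuel  0.592 0.071 2.5e-14    2
#>  ...
```

Habitat shift carries the largest standardized effect on fleet latitude,
with economic drivers secondary — the signal-to-noise pattern that makes
a fleet a usable sentinel.

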