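# Shared fixtures: a single north-south freeway through the origin and a
# short receptor transect either side of it.

test_road <- function() {
  road_segments(tibble::tibble(
    id = "R1", x1_m = 0, y1_m = -1000, x2_m = 0, y2_m = 1000,
    lanes = 6, sff_mph = 60, cap_vphpl = 2000, alpha = 0.1226,
    beta = 4.688, road_type = "freeway"
  ))
}

test_transect <- function(xs = c(-150, -60, -15, 15, 60, 150)) {
  tibble::tibble(id = sprintf("x%+04d", xs), x_m = xs, y_m = 0)
}

# Run a scenario (config + roads + receptors) through the whole chain and
# return the hourly predictions.
run_scenario <- function(config, roads = test_road(),
                         receptors = test_transect(),
                         pollutant = "CO", units = "ppm") {
  met <- generate_met(config)
  tr <- generate_traffic(config)
  ef <- generate_emission_table(config)
  traffic <- build_hourly_traffic(
    tr$weekday_profile, roads, unique(met$date), tr$mix, tr$f1, tr$f3
  )
  emissions <- segment_emissions(traffic, roads, ef, pollutant)
  predict_hourly(roads, receptors, met, emissions, units = units)
}
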