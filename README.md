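# nearroad

Fast reduced-form modelling of traffic-related air pollution near roads.

`nearroad` predicts hourly pollutant concentrations (CO, NOx, HC, PM2.5)
at receptors near straight road segments using a 13-parameter
multiplicative surrogate of a fleet emission model and a Gaussian
line-source dispersion model. Each prediction is a closed-form product
of four terms — fleet emission strength, a traffic-volume dispersion
factor, a wind-speed power law, and a wind-sector distance profile — so
a full year over hundreds of receptors runs in seconds. That makes it
practical for exposure studies that need long concentration time series
at many locations, where running a full dispersion model hour by hour is
prohibitive.

The package covers the whole chain:

* **Traffic and emissions** — Bureau of Public Roads volume-delay
  speeds, eight vehicle classes, day-type (weekend/holiday) volume and
  mix adjustment, seasonal speed-binned emission-factor lookups, segment
  emission rates.
* **Geometry** — road alignment, receptor distance and side, the wind
  angle θ between wind and the road/receptor normal, folded onto 19
  coefficient sectors (upwind sectors are identically zero).
* **Dispersion** — sector-specific double-exponential distance decay
  (valid 15–300 m), wind-speed factor `2.81·U^-0.739`, traffic-volume
  turbulence factor (0.89–1.29 over the fitted window), ppm or µg/m³
  output, honest calm handling (missing, never zero).
* **Exposure analytics** — daily averages with completeness rules,
  percentile fields, worst/best-day selection, running means,
  cross-receptor correlation, monitoring-campaign error versus the
  annual mean, factor-of-two evaluation statistics, ggplot helpers.
* **Synthetic data** — deterministic generators for meteorology (wind
  rose with day-scale persistence and early-morning calms), traffic
  profiles, vehicle mix and emission-factor tables emulating a Great
  Lakes urban setting, so everything runs without external data.

## A year in a few lines

One north–south freeway, three receptors, a synthetic year of weather
and traffic:

```r
library(nearroad)
library(dplyr)

cfg <- scenario_config(seed = 1) # 365 days, Great Lakes urban defaults
met <- generate_met(cfg)
traffic_in <- generate_traffic(cfg)
ef <- generate_emission_table(cfg)

roads <- road_segments(data.frame(
  id = "F1", x1_m = 0, y1_m = -1000, x2_m = 0, y2_m = 1000,
  lanes = 6, sff_mph = 60, cap_vphpl = 2000,
  alpha = 0.1226, beta = 4.688
))
receptors <- data.frame(
  id = c("west_060", "east_060", "east_150"),
  x_m = c(-60, 60, 150), y_m = 0
)

traffic <- build_hourly_traffic(
  traffic_in$weekday_profile, roads, unique(met$date),
  traffic_in$mix, traffic_in$f1, traffic_in$f3
)
emissions <- segment_emissions(traffic, roads, ef, "CO")
hourly <- predict_hourly(roads, receptors, met, emissions)
daily <- daily_average(hourly)

field_summary(daily, receptors)
#> # A tibble: 3 × 8
#>   receptor_id   mean   max n_days    p50   p98   x_m   y_m
#>   <chr>        <dbl> <dbl>  <int>  <dbl> <dbl> <dbl> <dbl>
#> 1 east_060    0.187  0.482    365 0.203  0.388    60     0
#> 2 east_150    0.0880 0.225    365 0.0948 0.182   150     0
#> 3 west_060    0.0928 0.423    365 0.0327 0.350   -60     0
```

The westerly-dominated wind rose makes the east side the usual downwind
side: twice the annual mean of the west receptor at the same distance.
And because any hour is downwind on only one side, the two sides'
24-hour averages anti-correlate strongly — receptors 120 m apart across
the road disagree more than receptors kilometres apart on the same side:

```r
cross_receptor_correlation(
  filter(daily, receptor_id == "west_060"),
  filter(daily, receptor_id == "east_060")
)
#> [1] -0.7731061
```

How wrong can a short monitoring campaign be about the annual mean?
Enumerate every possible two-week campaign, then let a two-season design
(two windows 26 weeks apart) cancel the seasonal cycle:

```r
daily_east <- filter(daily, receptor_id == "east_060")
rbind(
  campaign_error(daily_east, weeks = 2, strategy = "single_period"),
  campaign_error(daily_east, weeks = 2, strategy = "two_season")
)
#> # A tibble: 2 × 6
#>   strategy      weeks mean_error min_error max_error n_windows
#>   <chr>         <dbl>      <dbl>     <dbl>     <dbl>     <int>
#> 1 single_period     2     0.143   0.000227     0.652       352
#> 2 two_season        2     0.0812  0.00411      0.315       170
```

A single evaluation of the composite model, at the nominal reference
source (receptor straight downwind at 60 m, 4 m/s wind, 10,000 veh/hr
emitting 1 g/km per vehicle):

```r
concentration(theta = 180, x = 60, u = 4, v = 10000, e = 1)
#> [1] 0.07154187
```

## Command line

A thin CLI wraps the same pipeline (`inst/cli/nearroad.R` in the source,
`system.file("cli", "nearroad.R", package = "nearroad")` once installed):

```sh
Rscript nearroad.R synth   --seed 1 --days 365 --out scenario/
Rscript nearroad.R predict --scenario scenario/ --pollutant CO --out hourly.csv
Rscript nearroad.R summarize --daily daily.csv --out field.csv
Rscript nearroad.R campaign-error --daily daily.csv --weeks 2 --out err.csv
Rscript nearroad.R evaluate --predicted p.csv --observed o.csv --out stats.csv
```

## Scope and caveats

The model is a fitted response surface, valid 15–300 m from the road and
1,000–15,000 veh/hr; it excludes street canyons, chemistry, road-parallel
transport and atmospheric-stability classes. Calm hours yield missing
values by design, and daily means require at least 12 valid hours. See
the vignette (`vignette("nearroad")`) for the full method description.
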