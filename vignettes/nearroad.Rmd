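---
title: "Modelling near-road pollutant concentrations with nearroad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling near-road pollutant concentrations with nearroad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nearroad)
library(dplyr)
```

# The model in one paragraph

`nearroad` predicts hourly pollutant concentrations at fixed receptors
near straight road segments with a fast, fully parametric surrogate of a
fleet emission model and a Gaussian line-source dispersion model. The
concentration at a receptor is a product of four terms: the segment's
fleet-average emission strength, a traffic-volume dispersion factor, a
wind-speed power law, and a wind-sector distance profile. Because every
term is a closed-form expression in four inputs — wind direction, wind
speed, receptor distance and traffic volume — a year of hourly
predictions over hundreds of receptors takes seconds, which makes the
model practical for exposure studies that need long time series at many
locations.

# Traffic and emissions

Hourly per-vehicle emission factors depend on travel speed, so the model
first estimates the mean speed of each segment from its hourly volume
with the Bureau of Public Roads volume-delay relation

$$S = \frac{S_{FF}}{1 + \alpha (V/C)^\beta},$$

where $S_{FF}$ is the free-flow speed and $C$ the capacity. With the
fitted coefficients, an at-capacity freeway slows from 60 to about
53.4 mph while a congested arterial collapses from 35 to 17.5 mph:

```{r}
bpr_speed(60, 12000, 12000, alpha = 0.1226, beta = 4.688)
bpr_speed(35, 1400, 1400, alpha = 1.00, beta = 4.688)
```

Traffic is carried by eight vehicle classes (light-duty vehicles, four
light-duty truck classes, heavy trucks, buses, motorcycles). A typical
weekday hourly profile is adjusted to Saturdays, Sundays and holidays by
a total-volume factor (F1), split across classes by the weekday mix
fractions (F2) times day-type light/heavy ratios (F3), and renormalised
so the classes sum to the adjusted total — weekends lose far more truck
traffic than car traffic. Emission factors are looked up per pollutant,
season and class at the nearest 5-mph speed bin and combined into the
segment emission rate

$$Q = 0.625\, V \sum_K M_K\, q_K \quad \text{(g h}^{-1}\text{ km}^{-1}),$$

with $M_K$ the class share and $q_K$ its factor in g/mi; the
fleet-average per-vehicle rate $E = Q/V$ (g km$^{-1}$ veh$^{-1}$) is the
emission input of the dispersion step.

```{r}
segment_emission_rate(
  10000,
  mix = c(ldv = 0.9, hdt = 0.1),
  factors = c(ldv = 10, hdt = 2)
)
```

# Geometry: the wind angle

Dispersion depends on where the wind puts the receptor relative to the
road. The wind angle $\theta$ orients the wind against the road/receptor
normal: $\theta = 180^\circ$ means the wind blows straight from the road
onto the receptor (worst case), $\theta = 0^\circ$ the receptor is dead
upwind, and $90^\circ/270^\circ$ are road-parallel winds. For a road
aligned 135° and wind from 112.5°, the receptor on the west side is
downwind and the east receptor upwind:

```{r}
wind_angle(112.5, 135, i_west = 1)
wind_angle(112.5, 135, i_west = 0)
```

The problem is mirror-symmetric about the normal, so $\theta$ is folded
onto 0–180° and snapped to one of nineteen 10° sectors that index the
fitted coefficient table. The three sectors at 0–20° are identically
zero: an upwind receptor sees nothing from the road.

# Dispersion: three multiplicative factors

For each sector the concentration falls off with distance $X$ (m, valid
15–300 m) as a sum of a fast and a slow exponential,

$$C(X) = k_1^* e^{-k_3 (X - k_2)} + k_4^* e^{-k_6 (X - k_5)},$$

scaled so it gives ppm for a nominal source of 10,000 veh/hr emitting
1 g km$^{-1}$ veh$^{-1}$ at a 4 m/s wind. Two factors rescale that
nominal value. Wind speed dilutes concentrations by the power law
$k_7 U^{k_8}$ ($k_7 = 2.81$, $k_8 = -0.739$), which is within 1% of
unity at the 4 m/s reference and implies more than an 80% drop between
1 and 10 m/s:

```{r}
p <- dispersion_params()
wind_speed_factor(4, p)
1 - wind_speed_factor(10, p) / wind_speed_factor(1, p)
```

Traffic itself stirs the air: vehicle-induced turbulence grows with
volume, so high flows disperse their own plume. The volume factor

$$B(V, X) = k_9 \exp\!\big[k_{10}(V - k_{11})\big(1 + k_{12}(1 - \ln X / k_{13})\big)\big]$$

equals $k_9 = 0.99898$ at the fitted pivot $V = 10{,}749$ veh/hr for
every distance and ranges from 0.89 (high flows, long distances) to 1.29
(low flows) over the validity window:

```{r}
g <- expand.grid(v = seq(1000, 15000, 500), x = seq(15, 300, 15))
round(range(volume_dispersion_factor(g$v, g$x, p)), 2)
```

The composite prediction multiplies everything together,

$$C = \frac{E\,V}{10^4}\; B(V, X)\; U^{k_8}\; C_{\theta}(X),$$

in ppm; multiplying by 1322 converts to µg m$^{-3}$:

```{r}
concentration(theta = 180, x = 60, u = 4, v = 10000, e = 1, p)
concentration(180, 60, 4, 10000, 1, p, units = "ugm3")
```

Calm hours are a hard boundary: a Gaussian line-source formulation
divides by wind speed, so hours flagged calm (or reported as 0 m/s)
produce *missing* predictions, never zeros, and speeds between 0 and
0.5 m/s are raised to the 0.5 m/s floor. The missingness then propagates
through the analytics — a daily mean needs at least 12 valid hours.

# A year at a synthetic site

The synthetic module generates every input the pipeline needs, emulating
a Great Lakes urban setting: a westerly-dominated 16-sector wind rose
with day-scale persistence and early-morning calms, a double-peaked
weekday traffic profile with weekend/holiday reductions that hit trucks
hardest, and seasonal speed-binned emission factors (U-shaped for CO and
NOx, speed-flat PM2.5 dominated by heavy diesels).

```{r}
cfg <- scenario_config(seed = 1)
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
```

The westerly rose makes the east receptor the usual downwind side: its
annual mean is several times the west receptor's, and because any given
hour can only be downwind on one side, the two sides' 24-hr averages are
*negatively* correlated — receptors 120 m apart across a road can
disagree more than receptors kilometres apart on the same side:

```{r}
cross_receptor_correlation(
  filter(daily, receptor_id == "west_060"),
  filter(daily, receptor_id == "east_060")
)
```

# Exposure analytics

The remaining helpers answer the questions exposure studies actually
ask. `select_extreme_days()` ranks days by the domain-mean concentration
to find worst and best days; `running_mean()` computes trailing 5- and
30-day means with a half-window completeness rule; `campaign_error()`
asks how far a short monitoring campaign can land from the annual mean —
enumerating every possible start day, and optionally averaging two
windows 26 weeks apart to cancel the seasonal cycle:

```{r}
daily_east <- filter(daily, receptor_id == "east_060")
rbind(
  campaign_error(daily_east, weeks = 2, strategy = "single_period"),
  campaign_error(daily_east, weeks = 2, strategy = "two_season")
)
```

`factor_of_two_stats()` compares paired predictions and observations
(fraction within a factor of two, correlation, relative mean bias), and
`plot_concentration_field()` / `plot_daily_series()` give quick ggplot
views of a spatial field and of a daily series with its running means.

# Practical limits

The model is a response surface, not physics: it is only as good as the
window it was fitted on. Distances are valid from 15 m (closer receptors
clamp, with a warning) to 300 m (beyond which you choose extrapolation
or missingness); the volume factor clamps to 1,000–15,000 veh/hr;
road-parallel transport, street canyons, chemistry and atmospheric
stability are all outside its scope. Within that window its value is
speed with honest missing-data semantics, which is exactly what
long-series exposure work needs.
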