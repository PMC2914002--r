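test_that("generators are deterministic in the seed and leave the RNG alone", {
  cfg <- scenario_config(seed = 11, n_days = 5)
  m1 <- generate_met(cfg)
  m2 <- generate_met(cfg)
  expect_identical(m1, m2)
  m3 <- generate_met(scenario_config(seed = 12, n_days = 5))
  expect_false(identical(m1$wind_dir, m3$wind_dir))
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_met(cfg))
  expect_identical(runif(1), before)
})

test_that("synthetic met respects the calm flag, speed floor and rose", {
  cfg <- scenario_config(seed = 4, n_days = 120)
  met <- generate_met(cfg)
  expect_equal(nrow(met), 120 * 24)
  expect_true(all(met$wind_speed[met$calm] == 0))
  expect_true(all(met$wind_speed[!met$calm] >= 0.5))
  expect_true(all(met$wind_dir >= 0 & met$wind_dir < 360))
  expect_equal(mean(met$wind_speed[!met$calm]), cfg$speed_mean,
    tolerance = 0.05
  )
  # calms concentrate in the early morning
  calm_rate <- tapply(met$calm, met$hour, mean)
  expect_gt(mean(calm_rate[1:6]), mean(calm_rate[11:16]))
  # westerly half dominates under the default rose
  west <- mean(met$wind_dir > 180 & met$wind_dir < 360)
  expect_gt(west, 0.55)
})

test_that("wind direction has day-scale persistence", {
  cfg <- scenario_config(seed = 5, n_days = 200)
  met <- generate_met(cfg)
  sector <- floor(((met$wind_dir + 11.25) %% 360) / 22.5)
  same_day <- tapply(sector, rep(seq_len(200), each = 24), function(s) {
    mean(s == s[1])
  })
  # hours match their day's first-hour sector far more often than chance
  expect_gt(mean(same_day), 0.4)
})

test_that("synthetic traffic reproduces the configured day-type reductions", {
  cfg <- scenario_config(seed = 6)
  tr <- generate_traffic(cfg)
  wd <- tr$weekday_profile
  expect_equal(sum(wd$total_vph), cfg$aadt_weekday, tolerance = 1e-4)
  # double peak: both rush hours exceed midday and the night minimum
  expect_gt(wd$total_vph[wd$hour == 7], wd$total_vph[wd$hour == 12])
  expect_gt(wd$total_vph[wd$hour == 17], wd$total_vph[wd$hour == 12])
  expect_gt(
    max(wd$total_vph) / min(wd$total_vph), 4
  )
  # F1 reproduces the weekend totals
  for (d in c("saturday", "sunday", "holiday")) {
    f <- tr$f1[tr$f1$day_type == d, ]
    f <- f[order(f$hour), ]
    expect_equal(
      sum(f$f1 * wd$total_vph) / sum(wd$total_vph),
      cfg$weekend_factor[[d]],
      tolerance = 0.01
    )
  }
})

test_that("heavy-duty mix averages ~12% and anti-correlates with volume", {
  cfg <- scenario_config(seed = 6)
  tr <- generate_traffic(cfg)
  wd <- tr$weekday_profile
  heavy <- tr$mix |>
    dplyr::filter(road_type == "freeway", class %in% c("hdt", "hdb")) |>
    dplyr::group_by(hour) |>
    dplyr::summarise(h = sum(fraction))
  expect_true(all(heavy$h >= 0.02 & heavy$h <= 0.4))
  wmean <- sum(heavy$h * wd$total_vph) / sum(wd$total_vph)
  expect_equal(wmean, cfg$heavy_fraction_mean, tolerance = 0.015)
  expect_lt(cor(heavy$h, wd$total_vph), -0.5)
  # mix fractions sum to one every hour on both road types
  sums <- tr$mix |>
    dplyr::group_by(road_type, hour) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))
})

test_that("synthetic emission factors have the expected qualitative shape", {
  cfg <- scenario_config(seed = 2)
  ef <- generate_emission_table(cfg)
  expect_invisible(validate_emission_table(ef))
  co_ldv <- ef |>
    dplyr::filter(pollutant == "CO", season == "springfall", class == "ldv") |>
    dplyr::arrange(speed_mph)
  # U-shape: interior minimum, higher at both ends
  i_min <- which.min(co_ldv$g_per_mi)
  expect_true(i_min > 1 && i_min < nrow(co_ldv))
  expect_gt(co_ldv$g_per_mi[1], co_ldv$g_per_mi[i_min])
  expect_gt(co_ldv$g_per_mi[13], co_ldv$g_per_mi[i_min])
  # PM2.5 flat in speed, and heavy-duty dominates the fleet PM total
  pm <- ef |> dplyr::filter(pollutant == "PM2.5", season == "winter")
  spread <- tapply(pm$g_per_mi, pm$class, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  h <- 0.12
  light <- c(
    ldv = 0.55, ldt1 = 0.18, ldt2 = 0.12, ldt3 = 0.08, ldt4 = 0.05,
    mc = 0.02
  ) * (1 - h)
  fr <- c(light, hdt = h * 0.85, hdb = h * 0.15)
  q <- tapply(pm$g_per_mi, pm$class, unique)
  share <- sum(fr[c("hdt", "hdb")] * q[c("hdt", "hdb")]) /
    sum(fr * q[names(fr)])
  expect_gt(share, 0.6)
  expect_lt(share, 0.8)
  # winter CO exceeds summer CO
  co <- ef |> dplyr::filter(pollutant == "CO", class == "ldv", speed_mph == 30)
  expect_gt(
    co$g_per_mi[co$season == "winter"], co$g_per_mi[co$season == "summer"]
  )
})

test_that("receptor grids and scenario files round-trip through disk", {
  g <- generate_receptor_grid(nx = 3, ny = 2, spacing = 10)
  expect_equal(nrow(g), 6)
  expect_equal(range(g$x_m), c(0, 20))
  expect_equal(range(g$y_m), c(0, 10))
  expect_false(any(duplicated(g$id)))

  dir <- withr::local_tempdir()
  cfg <- scenario_config(seed = 8, n_days = 3)
  write_scenario(cfg, dir)
  met <- read_met(file.path(dir, "met.csv"))
  expect_equal(nrow(met), 72)
  roads <- read_roads(file.path(dir, "roads.csv"))
  expect_equal(roads$capacity_vph, 12000)
  rec <- read_receptors(file.path(dir, "receptors.csv"))
  expect_equal(nrow(rec), 8)
  ef <- read_emission_factors(file.path(dir, "emission_factors.csv"))
  prof <- read_weekday_profile(file.path(dir, "traffic_weekday.csv"))
  mix <- read_mix(file.path(dir, "mix.csv"))
  f1 <- read_day_factors(file.path(dir, "f1.csv"))
  f3 <- read_day_factors(file.path(dir, "f3.csv"))
  traffic <- build_hourly_traffic(
    prof, roads, unique(met$date), mix, f1, f3
  )
  em <- segment_emissions(traffic, roads, ef, "NOx")
  h <- predict_hourly(roads, rec, met, em)
  expect_equal(nrow(h), 72 * 8)
  expect_true(any(h$conc > 0, na.rm = TRUE))
})

test_that("readers reject malformed inputs", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  readr::write_csv(tibble::tibble(id = "a", x_m = 1), f)
  expect_error(read_receptors(f), "missing column")
  readr::write_csv(
    tibble::tibble(
      date = "2006-01-01", hour = 0, wind_dir = 370, wind_speed = 3
    ), f
  )
  expect_error(read_met(f), "wind_dir")
  readr::write_csv(tibble::tibble(hour = 0:22, total_vph = 1), f)
  expect_error(read_weekday_profile(f), "hours 0-23")
  readr::write_csv(
    tibble::tibble(
      road_type = "freeway", class = "warp_drive", hour = 0, fraction = 1
    ), f
  )
  expect_error(read_mix(f), "unknown vehicle class")
})
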