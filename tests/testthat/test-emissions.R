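test_that("BPR speeds reproduce the fitted at-capacity values", {
  expect_equal(round(bpr_speed(60, 12000, 12000), 1), 53.4)
  expect_equal(round(bpr_speed(35, 1400, 1400, alpha = 1), 1), 17.5)
  # half capacity barely slows a freeway
  expect_equal(bpr_speed(60, 6000, 12000), 59.71598, tolerance = 1e-6)
})

test_that("BPR speed is monotone decreasing in volume and bounded", {
  v <- seq(0, 24000, by = 1000)
  s <- bpr_speed(60, v, 12000)
  expect_true(all(diff(s) < 0))
  expect_equal(s[1], 60)
  expect_error(bpr_speed(60, -1, 1000), "non-negative")
  expect_error(bpr_speed(60, 100, 0), "positive")
})

test_that("seasons map months correctly", {
  expect_equal(season_of(c(12, 1, 2)), rep("winter", 3))
  expect_equal(season_of(c(6, 7, 8)), rep("summer", 3))
  expect_equal(season_of(c(3, 4, 5, 9, 10, 11)), rep("springfall", 6))
  expect_error(season_of(13), "month")
})

test_that("duty groups split the eight classes as expected", {
  expect_length(vehicle_classes(), 8)
  expect_equal(sum(duty_class(vehicle_classes()) == "heavy"), 2)
  expect_equal(duty_class(c("hdt", "hdb", "ldv")), c("heavy", "heavy", "light"))
})

test_that("day-type volume adjustment uses F1 with weekday identity", {
  f1 <- tibble::tibble(
    day_type = c("sunday", "saturday"), hour = c(8, 8), f1 = c(0.5, 0.8)
  )
  expect_equal(
    adjust_total_volume(1000, c("weekday", "sunday", "saturday"), 8, f1),
    c(1000, 500, 800)
  )
  expect_error(
    adjust_total_volume(1000, "holiday", 8, f1),
    "missing F1"
  )
  expect_error(adjust_total_volume(-5, "weekday", 8, f1), "non-negative")
})

test_that("class volumes renormalise to the hourly total", {
  v <- class_volumes(
    100, c(light = 0.8, heavy = 0.2), c(light = 1, heavy = 0.5)
  )
  expect_equal(unname(v), c(800, 100) / 9, tolerance = 1e-12)
  expect_equal(sum(v), 100)
  # with all-1 F3 the split is just F2
  expect_equal(
    unname(class_volumes(100, c(a = 0.8, b = 0.2))), c(80, 20)
  )
  expect_error(class_volumes(100, numeric(0)), "empty")
  expect_error(class_volumes(100, c(a = 0, b = 0)), "zero")
})

test_that("emission-factor lookup snaps to the nearest 5-mph bin", {
  tab <- tidyr::expand_grid(
    pollutant = "CO", season = "winter", class = "ldv",
    speed_mph = seq(5, 65, 5)
  )
  tab$g_per_mi <- tab$speed_mph # factor equals its bin, for inspection
  validate_emission_table(tab)
  expect_equal(
    lookup_emission_factor(tab, "CO", "winter", "ldv", c(52.4, 52.5, 3, 90)),
    c(50, 55, 5, 65) # midpoints round up; out-of-range clamps
  )
  expect_error(
    lookup_emission_factor(tab, "NOx", "winter", "ldv", 30),
    "unknown"
  )
  expect_error(lookup_emission_factor(tab, "CO", "winter", "ldv", 0), "positive")
})

test_that("emission table validation catches gaps and flags speed-varying PM2.5", {
  tab <- tidyr::expand_grid(
    pollutant = "PM2.5", season = "winter", class = "hdt",
    speed_mph = seq(5, 65, 5)
  )
  tab$g_per_mi <- 0.3
  expect_invisible(validate_emission_table(tab))
  expect_error(validate_emission_table(tab[-3, ]), "missing or duplicated")
  tab2 <- tab
  tab2$g_per_mi <- tab2$speed_mph / 100
  expect_warning(validate_emission_table(tab2), "PM2.5")
})

test_that("segment emission rate matches hand-computed values", {
  r <- segment_emission_rate(
    10000, c(ldv = 0.9, hdt = 0.1), c(ldv = 10, hdt = 2)
  )
  expect_equal(r$Q_g_hr_km, 57500)
  expect_equal(r$E_g_km_veh, 5.75)
  # one class, unit factor: the mile-to-km constant alone
  r1 <- segment_emission_rate(1000, c(ldv = 1), c(ldv = 1))
  expect_equal(r1$Q_g_hr_km, 625)
  # strict units replace 0.625 by 1/1.609347
  rs <- segment_emission_rate(1000, c(ldv = 1), c(ldv = 1),
    strict_units = TRUE
  )
  expect_equal(rs$Q_g_hr_km, 1000 / 1.609347)
  expect_error(
    segment_emission_rate(100, c(a = 1), c(b = 1)),
    "same vehicle classes"
  )
})

test_that("holiday calendar and day types are correct for 2006", {
  h <- us_holidays(2006)
  expect_true(as.Date("2006-05-29") %in% h) # Memorial Day
  expect_true(as.Date("2006-09-04") %in% h) # Labor Day
  expect_true(as.Date("2006-11-23") %in% h) # Thanksgiving
  expect_equal(
    day_type_of(as.Date(c(
      "2006-01-02", "2006-01-07", "2006-01-08", "2006-07-04"
    ))),
    c("weekday", "saturday", "sunday", "holiday")
  )
})

test_that("hourly traffic expansion conserves totals and applies day factors", {
  cfg <- scenario_config(seed = 3, n_days = 7)
  tr <- generate_traffic(cfg)
  roads <- test_road()
  dates <- as.Date("2006-01-02") + 0:6 # Mon..Sun
  traffic <- build_hourly_traffic(
    tr$weekday_profile, roads, dates, tr$mix, tr$f1, tr$f3
  )
  # class volumes sum to the adjusted hourly total
  sums <- traffic |>
    dplyr::group_by(date, hour) |>
    dplyr::summarise(
      s = sum(volume_vph), tot = total_vph[1], .groups = "drop"
    )
  expect_equal(sums$s, sums$tot, tolerance = 1e-9)
  # Sunday daily total is the configured fraction of a weekday's
  dt <- traffic |>
    dplyr::distinct(date, hour, total_vph) |>
    dplyr::group_by(date) |>
    dplyr::summarise(tot = sum(total_vph))
  expect_equal(dt$tot[7] / dt$tot[1], 0.68, tolerance = 1e-3)
  expect_equal(dt$tot[6] / dt$tot[1], 0.77, tolerance = 1e-3)
  # heavy-duty volumes drop more than the total on Sunday
  hv <- traffic |>
    dplyr::filter(class %in% c("hdt", "hdb")) |>
    dplyr::group_by(date) |>
    dplyr::summarise(tot = sum(volume_vph))
  expect_equal(hv$tot[7] / hv$tot[1], 0.27, tolerance = 0.02)
})

test_that("segment emissions produce plausible fleet-average CO rates", {
  cfg <- scenario_config(seed = 3, n_days = 2)
  tr <- generate_traffic(cfg)
  ef <- generate_emission_table(cfg)
  roads <- test_road()
  traffic <- build_hourly_traffic(
    tr$weekday_profile, roads, as.Date("2006-01-02") + 0:1, tr$mix,
    tr$f1, tr$f3
  )
  em <- segment_emissions(traffic, roads, ef, "CO")
  expect_equal(nrow(em), 48)
  expect_true(all(em$E_g_km_veh > 1 & em$E_g_km_veh < 50))
  expect_equal(em$Q_g_hr_km, em$E_g_km_veh * em$total_vph)
  expect_true(all(em$speed_mph <= 60 & em$speed_mph > 30))
})
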