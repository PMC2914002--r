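#' Scenario configuration for the synthetic input generators
#'
#' Bundles every knob of the synthetic meteorology, traffic and
#' emission-factor generators. The defaults emulate the conditions of a
#' Great Lakes urban setting: a 16-sector wind rose dominated by SW and
#' WNW winds with a mean speed of 4.29 m/s; calms concentrated in the
#' early morning at an annual rate near 8 percent of hours; a
#' double-peaked weekday traffic profile whose daily totals drop by 23, 32
#' and 26 percent on Saturdays, Sundays and holidays (62, 73 and 49
#' percent for heavy-duty vehicles); a heavy-duty fraction averaging about
#' 12 percent and anti-correlated with total volume; and U-shaped CO/NOx
#' speed-emission curves with speed-flat PM2.5 dominated by heavy-duty
#' diesel.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param n_days Number of days to generate (default 365).
#' @param start_date First day (default 2006-01-01).
#' @param rose_prob Length-16 sector probabilities (sector 1 centred on
#'   north, clockwise every 22.5 degrees); normalised internally.
#' @param speed_mean,speed_sd Wind-speed distribution (m/s) before the
#'   0.5 m/s truncation.
#' @param calm_prob Length-24 per-hour calm probabilities.
#' @param dir_persistence Probability that an hour keeps its day's
#'   prevailing wind sector instead of drawing a fresh one; gives wind
#'   direction the day-scale persistence of real synoptic weather while
#'   leaving the marginal sector distribution equal to the rose.
#' @param aadt_weekday Typical weekday daily total volume (vehicles/day).
#' @param peak_hours,peak_ratio Morning/evening peak hours (0-23) and the
#'   peak-to-base ratio of the diurnal profile.
#' @param weekend_factor Named daily-total factors for `saturday`,
#'   `sunday`, `holiday` relative to a weekday.
#' @param heavy_weekend_factor Same, for the heavy-duty classes.
#' @param heavy_fraction_mean Volume-weighted mean heavy-duty fraction.
#' @param ef_min_speed_mph Speed (mph) of the minimum of the U-shaped
#'   CO/NOx curves.
#' @param ef_curvature Relative rise of the U-shaped curves at the ends of
#'   the 5-65 mph range.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1,
                            n_days = 365,
                            start_date = as.Date("2006-01-01"),
                            rose_prob = c(
                              3, 2, 3, 4, 3, 3, 4, 6,
                              10, 12, 10, 8, 10, 12, 6, 4
                            ),
                            speed_mean = 4.29,
                            speed_sd = 2.1,
                            calm_prob = c(
                              rep(0.16, 6), rep(0.08, 3), rep(0.04, 9),
                              rep(0.06, 3), rep(0.12, 3)
                            ),
                            dir_persistence = 0.8,
                            aadt_weekday = 100000,
                            peak_hours = c(7, 17),
                            peak_ratio = 8,
                            weekend_factor = c(
                              saturday = 0.77, sunday = 0.68, holiday = 0.74
                            ),
                            heavy_weekend_factor = c(
                              saturday = 0.38, sunday = 0.27, holiday = 0.51
                            ),
                            heavy_fraction_mean = 0.12,
                            ef_min_speed_mph = 45,
                            ef_curvature = 2.5) {
  if (length(rose_prob) != 16 || any(rose_prob < 0) || sum(rose_prob) <= 0) {
    abort("rose_prob must be 16 non-negative sector weights")
  }
  if (length(calm_prob) != 24 || any(calm_prob < 0 | calm_prob > 1)) {
    abort("calm_prob must be 24 probabilities in [0, 1]")
  }
  structure(
    list(
      seed = as.integer(seed), n_days = n_days, start_date = start_date,
      rose_prob = rose_prob / sum(rose_prob),
      speed_mean = speed_mean, speed_sd = speed_sd, calm_prob = calm_prob,
      dir_persistence = dir_persistence,
      aadt_weekday = aadt_weekday, peak_hours = peak_hours,
      peak_ratio = peak_ratio, weekend_factor = weekend_factor,
      heavy_weekend_factor = heavy_weekend_factor,
      heavy_fraction_mean = heavy_fraction_mean,
      ef_min_speed_mph = ef_min_speed_mph, ef_curvature = ef_curvature
    ),
    class = "scenario_config"
  )
}

#' Generate an hourly meteorology series
#'
#' Each day draws a prevailing 22.5-degree wind sector from the configured
#' rose; each hour keeps that sector with the configured persistence
#' probability or draws a fresh sector from the rose, so directions have
#' day-scale persistence while each hour's marginal sector distribution is
#' exactly the rose. Directions are jittered uniformly within the sector;
#' speeds are drawn from a normal distribution truncated at the 0.5 m/s
#' floor; calm hours (speed recorded as 0 with the calm flag set) are
#' drawn per hour of day.
#'
#' @param config A [scenario_config()].
#' @return Tibble `date`, `hour`, `wind_dir`, `wind_speed`, `calm`.
#' @export
generate_met <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  local_seed(config$seed + 101L)
  n <- config$n_days * 24L
  hour <- rep(0:23, config$n_days)
  date <- rep(config$start_date + seq_len(config$n_days) - 1, each = 24)
  calm <- runif(n) < config$calm_prob[hour + 1]
  day_sector <- sample.int(
    16, config$n_days,
    replace = TRUE, prob = config$rose_prob
  )
  fresh <- sample.int(16, n, replace = TRUE, prob = config$rose_prob)
  keep <- runif(n) < config$dir_persistence
  sector <- ifelse(keep, rep(day_sector, each = 24), fresh)
  dir <- ((sector - 1) * 22.5 + runif(n, -11.25, 11.25)) %% 360
  speed <- rnorm(n, config$speed_mean, config$speed_sd)
  bad <- which(speed < 0.5)
  while (length(bad) > 0) {
    speed[bad] <- rnorm(length(bad), config$speed_mean, config$speed_sd)
    bad <- bad[speed[bad] < 0.5]
  }
  speed[calm] <- 0
  tibble(
    date = date, hour = hour, wind_dir = round(dir, 1),
    wind_speed = round(speed, 2), calm = calm
  )
}

# Diurnal weekday shape: night base plus Gaussian rush-hour bumps.
diurnal_shape <- function(hours, peak_hours, peak_ratio) {
  base <- 1
  bump <- rowSums(vapply(
    peak_hours,
    function(p) (peak_ratio - 1) * exp(-((hours - p)^2) / (2 * 1.8^2)),
    numeric(length(hours))
  ))
  base + bump
}

#' Generate synthetic traffic inputs
#'
#' Produces the typical-weekday hourly volume profile (double-peaked, with
#' the configured peak hours and peak-to-base ratio, scaled to the weekday
#' daily total), the weekday vehicle-mix fractions (heavy-duty fraction
#' anti-correlated with total volume, highest in the very early morning),
#' and the F1 / F3 day-type factor tables reproducing the configured
#' weekend and holiday volume reductions (the F1 profile also flattens the
#' morning peak and raises the late-night share, as weekend traffic does).
#'
#' @param config A [scenario_config()].
#' @return A list of tibbles: `weekday_profile` (`road_id = NA`: applies
#'   to any road; columns `hour`, `total_vph`), `mix` (`road_type`,
#'   `class`, `hour`, `fraction`), `f1` (`day_type`, `hour`, `f1`), `f3`
#'   (`day_type`, `hour`, `duty`, `f3`).
#' @export
generate_traffic <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  local_seed(config$seed + 202L)
  hours <- 0:23
  shape <- diurnal_shape(hours, config$peak_hours, config$peak_ratio)
  wd <- config$aadt_weekday * shape / sum(shape)
  weekday_profile <- tibble(hour = hours, total_vph = round(wd, 1))

  # weekend shape: single broad midday bump, no morning rush
  we_shape <- diurnal_shape(hours, 14, config$peak_ratio * 0.55)
  f1 <- purrr::map_dfr(names(config$weekend_factor), function(d) {
    prof <- config$weekend_factor[[d]] * config$aadt_weekday *
      we_shape / sum(we_shape)
    tibble(day_type = d, hour = hours, f1 = round(prof / wd, 4))
  })

  # heavy fraction anti-correlated with volume, volume-weighted mean fixed
  raw <- (mean(wd) / wd)^0.6
  heavy <- raw * config$heavy_fraction_mean * sum(wd) / sum(raw * wd)
  heavy <- pmin(pmax(heavy, 0.02), 0.35)
  light_split <- c(
    ldv = 0.55, ldt1 = 0.18, ldt2 = 0.12, ldt3 = 0.08, ldt4 = 0.05,
    mc = 0.02
  )
  mix <- purrr::map_dfr(c("freeway", "arterial"), function(rt) {
    h <- if (rt == "arterial") pmin(heavy * 0.6, 0.35) else heavy
    purrr::map_dfr(hours + 1, function(i) {
      fr <- c(light_split * (1 - h[i]), hdt = unname(h[i]) * 0.85,
        hdb = unname(h[i]) * 0.15
      )
      tibble(
        road_type = rt, class = names(fr), hour = i - 1,
        fraction = unname(fr)
      )
    })
  })

  # The class-volume renormalisation rescales every class back to the
  # adjusted hourly total, so a naive heavy-duty F3 would be partially
  # undone. Invert it: with weekday heavy share h and adjusted-day heavy
  # share target h * r_eff, the required ratio is
  # (1 - h) r_eff / (1 - r_eff h); r_eff corrects for the day's hourly
  # shape so the daily heavy-duty total hits the configured reduction.
  f3 <- purrr::map_dfr(names(config$heavy_weekend_factor), function(d) {
    f1_d <- f1$f1[f1$day_type == d][order(f1$hour[f1$day_type == d])]
    r_eff <- config$heavy_weekend_factor[[d]] *
      sum(wd * heavy) / sum(f1_d * wd * heavy)
    f3h <- (1 - heavy) * r_eff / (1 - r_eff * heavy)
    tibble(
      day_type = d, hour = rep(hours, 2),
      duty = rep(c("light", "heavy"), each = 24),
      f3 = c(rep(1, 24), round(f3h, 5))
    )
  })

  list(
    weekday_profile = weekday_profile, mix = mix, f1 = f1, f3 = f3
  )
}

#' Generate a synthetic emission-factor lookup table
#'
#' Builds a complete pollutant x season x class x 5-mph-bin table with the
#' qualitative structure of fleet emission models: CO and NOx follow a
#' U-shaped (convex) speed curve with an interior minimum, HC declines
#' gently with speed, and PM2.5 is flat in speed with heavy-duty diesel
#' factors far above light-duty ones (so the heavy-duty share of fleet
#' PM2.5 is roughly 70 percent at a 12 percent heavy-duty fraction). CO is
#' higher in winter; PM2.5 is season-independent.
#'
#' @param config A [scenario_config()].
#' @return Emission-factor tibble (`pollutant`, `season`, `class`,
#'   `speed_mph`, `g_per_mi`) passing [validate_emission_table()].
#' @export
generate_emission_table <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  bins <- seq(5, 65, by = 5)
  u_curve <- function(s) {
    1 + config$ef_curvature * ((s - config$ef_min_speed_mph) / 60)^2
  }
  base <- list(
    CO = c(
      ldv = 8, ldt1 = 9, ldt2 = 10, ldt3 = 11, ldt4 = 12, hdt = 14,
      hdb = 13, mc = 12
    ),
    NOx = c(
      ldv = 0.7, ldt1 = 0.8, ldt2 = 0.9, ldt3 = 1.1, ldt4 = 1.2,
      hdt = 8.5, hdb = 7.5, mc = 0.9
    ),
    HC = c(
      ldv = 0.8, ldt1 = 0.9, ldt2 = 1.0, ldt3 = 1.1, ldt4 = 1.2,
      hdt = 1.0, hdb = 0.9, mc = 2.0
    ),
    PM2.5 = c(
      ldv = 0.02, ldt1 = 0.025, ldt2 = 0.03, ldt3 = 0.035, ldt4 = 0.04,
      hdt = 0.35, hdb = 0.30, mc = 0.02
    )
  )
  season_mult <- list(
    CO = c(winter = 1.3, springfall = 1.0, summer = 0.8),
    NOx = c(winter = 1.1, springfall = 1.0, summer = 0.9),
    HC = c(winter = 1.15, springfall = 1.0, summer = 1.05),
    PM2.5 = c(winter = 1.0, springfall = 1.0, summer = 1.0)
  )
  out <- purrr::map_dfr(names(base), function(p) {
    speed_fac <- switch(p,
      CO = u_curve(bins),
      NOx = u_curve(bins),
      HC = 1 + 0.3 * (35 - bins) / 60,
      PM2.5 = rep(1, length(bins))
    )
    purrr::map_dfr(names(season_mult[[p]]), function(se) {
      purrr::map_dfr(names(base[[p]]), function(cl) {
        tibble(
          pollutant = p, season = se, class = cl, speed_mph = bins,
          g_per_mi = round(base[[p]][[cl]] * season_mult[[p]][[se]] *
            speed_fac, 5)
        )
      })
    })
  })
  validate_emission_table(out)
  out
}

#' Generate a rectangular receptor grid
#'
#' @param nx,ny Number of columns and rows.
#' @param spacing Grid spacing, m.
#' @param origin Coordinates of the south-west corner (length-2).
#' @return Receptor tibble `id`, `x_m`, `y_m`.
#' @export
generate_receptor_grid <- function(nx = 41, ny = 43, spacing = 25,
                                   origin = c(0, 0)) {
  g <- tidyr::expand_grid(
    iy = seq_len(ny) - 1, ix = seq_len(nx) - 1
  )
  tibble(
    id = sprintf("r%03d_%03d", g$ix, g$iy),
    x_m = origin[1] + g$ix * spacing,
    y_m = origin[2] + g$iy * spacing
  )
}

#' Write a full synthetic scenario to CSV files
#'
#' Materialises met, traffic, day-type factors, mix, emission factors,
#' roads and receptors as the CSV dialects the readers consume, so a
#' scenario can be round-tripped through files or driven from the command
#' line.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @param roads Optional road table (defaults to a single north-south
#'   6-lane freeway through the origin).
#' @param receptors Optional receptor table (defaults to a small transect
#'   east and west of that road).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(config, dir, roads = NULL, receptors = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(roads)) {
    roads <- tibble(
      id = "R1", x1_m = 0, y1_m = -1000, x2_m = 0, y2_m = 1000,
      lanes = 6, sff_mph = 60, cap_vphpl = 2000, alpha = 0.1226,
      beta = 4.688, road_type = "freeway"
    )
  }
  if (is.null(receptors)) {
    xs <- c(-300, -150, -60, -15, 15, 60, 150, 300)
    receptors <- tibble(
      id = sprintf("x%+04d", xs), x_m = xs, y_m = 0
    )
  }
  tr <- generate_traffic(config)
  readr::write_csv(generate_met(config), file.path(dir, "met.csv"))
  readr::write_csv(tr$weekday_profile, file.path(dir, "traffic_weekday.csv"))
  readr::write_csv(tr$mix, file.path(dir, "mix.csv"))
  readr::write_csv(tr$f1, file.path(dir, "f1.csv"))
  readr::write_csv(tr$f3, file.path(dir, "f3.csv"))
  readr::write_csv(
    generate_emission_table(config),
    file.path(dir, "emission_factors.csv")
  )
  readr::write_csv(roads, file.path(dir, "roads.csv"))
  readr::write_csv(receptors, file.path(dir, "receptors.csv"))
  invisible(dir)
}
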