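#' Mean travel speed from the Bureau of Public Roads volume-delay function
#'
#' `S = S_FF / (1 + alpha * (V/C)^beta)`. Speed equals the free-flow speed
#' at zero volume and decreases monotonically as volume approaches (or
#' exceeds) capacity. The case-study coefficients give at-capacity drops
#' from 60 to 53.4 mph on a freeway (alpha = 0.1226) and from 35 to
#' 17.5 mph on an urban arterial (alpha = 1.00), both with beta = 4.688.
#'
#' @param free_flow_mph Free-flow speed (mph), > 0.
#' @param volume_vph Hourly traffic volume (vehicles/hr), >= 0.
#' @param capacity_vph Segment capacity (vehicles/hr), > 0.
#' @param alpha,beta BPR coefficients (alpha typically 0.05-1, beta 4-11).
#' @return Mean travel speed(s) in mph.
#' @export
bpr_speed <- function(free_flow_mph, volume_vph, capacity_vph,
                      alpha = 0.1226, beta = 4.688) {
  if (any(volume_vph < 0, na.rm = TRUE)) {
    abort("volume_vph must be non-negative")
  }
  if (any(capacity_vph <= 0, na.rm = TRUE)) {
    abort("capacity_vph must be positive")
  }
  free_flow_mph / (1 + alpha * (volume_vph / capacity_vph)^beta)
}

#' Season used by the seasonal emission-factor lookup
#'
#' Emission factors are tabulated by three seasons rather than by hour:
#' December-February is winter, June-August summer, and the remaining
#' months a combined spring/fall season.
#'
#' @param month Month number(s) 1-12.
#' @return Character vector: `"winter"`, `"springfall"` or `"summer"`.
#' @export
season_of <- function(month) {
  if (any(!month %in% 1:12)) abort("month must be in 1..12")
  c(
    "winter", "winter", "springfall", "springfall", "springfall",
    "summer", "summer", "summer", "springfall", "springfall",
    "springfall", "winter"
  )[month]
}

#' The eight vehicle classes of the emission model
#'
#' Light-duty vehicles, four light-duty truck classes, heavy-duty trucks,
#' heavy-duty buses and motorcycles. The `hdt` and `hdb` classes form the
#' heavy-duty group used by the day-type mix-adjustment ratios.
#'
#' @return Character vector of the eight class codes.
#' @export
vehicle_classes <- function() {
  c("ldv", "ldt1", "ldt2", "ldt3", "ldt4", "hdt", "hdb", "mc")
}

#' Heavy/light duty group of each vehicle class
#' @param class Vehicle class code(s) (see [vehicle_classes()]).
#' @return `"heavy"` for `hdt`/`hdb`, `"light"` otherwise.
#' @export
duty_class <- function(class) {
  ifelse(class %in% c("hdt", "hdb"), "heavy", "light")
}

#' Adjust a typical-weekday hourly volume to another day type
#'
#' `V_D = V_WD * F1[D, T]`, where `F1` is the day-type hourly volume factor
#' (identically 1 for weekdays). Factors are derived from year-round
#' permanent-traffic-recorder counts; typical values range from about 0.21
#' (early Sunday morning) to 1.37 (Saturday 1 am).
#'
#' @param weekday_volume_vph Typical weekday volume(s) (vehicles/hr).
#' @param day_type One of `"weekday"`, `"saturday"`, `"sunday"`,
#'   `"holiday"` (vectorised).
#' @param hour Hour of day 0-23 (vectorised).
#' @param f1 Tibble with columns `day_type`, `hour`, `f1`. Weekday rows may
#'   be omitted (factor 1 is implied).
#' @return Adjusted volume(s) (vehicles/hr).
#' @export
adjust_total_volume <- function(weekday_volume_vph, day_type, hour, f1) {
  if (any(weekday_volume_vph < 0, na.rm = TRUE)) {
    abort("weekday volume must be non-negative")
  }
  n <- max(length(weekday_volume_vph), length(day_type), length(hour))
  day_type <- rep_len(day_type, n)
  hour <- rep_len(hour, n)
  weekday_volume_vph <- rep_len(weekday_volume_vph, n)
  fac <- rep(1, n)
  need <- day_type != "weekday"
  if (any(need)) {
    key <- paste(day_type[need], hour[need])
    tab <- setNames(f1$f1, paste(f1$day_type, f1$hour))
    fac[need] <- tab[key]
    if (any(is.na(fac[need]))) {
      abort("missing F1 entry for some day_type/hour combinations")
    }
  }
  weekday_volume_vph * fac
}

#' Apportion an hourly total volume across vehicle classes
#'
#' Two-stage day-type adjustment: unadjusted class volumes are
#' `V* = V * F2 * F3` (weekday mix fraction `F2` times the day-type
#' light/heavy ratio `F3`), then all classes are rescaled by a common
#' hourly factor so they sum exactly to the total volume.
#'
#' @param total_vph Total volume for the hour (vehicles/hr).
#' @param f2 Named numeric vector of weekday mix fractions by class
#'   (non-negative, summing to 1).
#' @param f3 Named numeric vector of day-type ratios by class (all 1 on
#'   weekdays). Missing names default to 1.
#' @return Named numeric vector of class volumes summing to `total_vph`.
#' @export
class_volumes <- function(total_vph, f2, f3 = NULL) {
  if (length(f2) == 0) abort("empty vehicle-class set")
  if (any(f2 < 0)) abort("F2 fractions must be non-negative")
  if (sum(f2) == 0) abort("cannot apportion volume: all F2 fractions are zero")
  if (is.null(f3)) f3 <- setNames(rep(1, length(f2)), names(f2))
  f3 <- f3[names(f2)]
  f3[is.na(f3)] <- 1
  unadj <- total_vph * f2 * f3
  s <- sum(unadj)
  if (s == 0) {
    return(setNames(rep(0, length(f2)), names(f2)))
  }
  unadj * (total_vph / s)
}

#' Validate an emission-factor lookup table
#'
#' Checks the table forms a complete pollutant x season x class x speed-bin
#' grid over the 5-65 mph bins with non-negative factors, and warns when
#' PM2.5 factors vary with speed (the parent emission model treats exhaust
#' PM2.5 as speed-independent).
#'
#' @param table Tibble with columns `pollutant`, `season`, `class`,
#'   `speed_mph`, `g_per_mi`.
#' @return The table, invisibly, or an error.
#' @export
validate_emission_table <- function(table) {
  required <- c("pollutant", "season", "class", "speed_mph", "g_per_mi")
  if (!all(required %in% names(table))) {
    abort(paste(
      "emission-factor table needs columns",
      paste(required, collapse = ", ")
    ))
  }
  if (any(table$g_per_mi < 0)) abort("emission factors must be non-negative")
  bins <- seq(5, 65, by = 5)
  grid <- table %>%
    group_by(.data$pollutant, .data$season, .data$class) %>%
    summarise(
      ok = identical(as.numeric(sort(unique(.data$speed_mph))), as.numeric(bins)) &&
        dplyr::n() == length(bins),
      .groups = "drop"
    )
  if (!all(grid$ok)) {
    abort("emission-factor table has missing or duplicated speed bins")
  }
  pm <- table %>% filter(.data$pollutant == "PM2.5")
  if (nrow(pm) > 0) {
    spread <- pm %>%
      group_by(.data$season, .data$class) %>%
      summarise(
        flat = diff(range(.data$g_per_mi)) < 1e-12, .groups = "drop"
      )
    if (!all(spread$flat)) {
      warn("PM2.5 emission factors vary with speed; the parent model treats them as flat")
    }
  }
  invisible(table)
}

#' Look up an emission factor at the nearest 5-mph speed bin
#'
#' Factors are tabulated every 5 mph from 5 to 65 mph; the bin nearest the
#' segment's estimated speed is used, with midpoints (e.g. 52.5 mph)
#' rounding up and out-of-range speeds clamping to the end bins.
#'
#' @param table Emission-factor tibble (see [validate_emission_table()]).
#' @param pollutant,season,class Lookup keys (each scalar or vectorised to
#'   a common length with `speed_mph`).
#' @param speed_mph Segment speed(s), mph, > 0.
#' @return Emission factor(s), g per mile per vehicle.
#' @export
lookup_emission_factor <- function(table, pollutant, season, class, speed_mph) {
  if (any(speed_mph <= 0, na.rm = TRUE)) abort("speed must be positive")
  bin <- pmin(pmax(5 * floor(speed_mph / 5 + 0.5), 5), 65)
  key <- paste(pollutant, season, class, bin)
  tab <- setNames(
    table$g_per_mi,
    paste(table$pollutant, table$season, table$class, table$speed_mph)
  )
  out <- unname(tab[key])
  if (any(is.na(out) & !is.na(speed_mph))) {
    abort("unknown pollutant/season/class in emission-factor lookup")
  }
  out
}

#' Hourly segment emission rate from volume, mix and emission factors
#'
#' `Q = 0.625 * V * sum_K M_K * q_K` in g per hour per km of road, where
#' `M_K` is the class mix fraction and `q_K` the per-vehicle factor
#' (g/mi/vehicle) at the segment speed; 0.625 is the printed mile-to-km
#' conversion. The fleet-average per-vehicle rate `E = Q / V`
#' (g/km/vehicle) is also returned; it is the emission input of the
#' dispersion model. Set `strict_units = TRUE` to use the exact conversion
#' 1/1.609347 instead of the printed 0.625.
#'
#' @param volume_vph Total volume (vehicles/hr).
#' @param mix Named numeric vector of class mix fractions (sum 1).
#' @param factors Named numeric vector of emission factors (g/mi/vehicle)
#'   for the same classes.
#' @param strict_units Use 1/1.609347 mi->km instead of the rounded 0.625.
#' @return A list with `Q_g_hr_km` and `E_g_km_veh`.
#' @export
segment_emission_rate <- function(volume_vph, mix, factors,
                                  strict_units = FALSE) {
  if (length(mix) == 0) abort("empty vehicle-class set")
  if (!setequal(names(mix), names(factors))) {
    abort("mix and factors must cover the same vehicle classes")
  }
  conv <- if (strict_units) 1 / 1.609347 else 0.625
  per_veh <- conv * sum(mix * factors[names(mix)])
  list(Q_g_hr_km = volume_vph * per_veh, E_g_km_veh = per_veh)
}

#' Observed dates of the six major U.S. holidays
#'
#' New Year's Day, Memorial Day (last Monday of May), Independence Day,
#' Labor Day (first Monday of September), Thanksgiving (fourth Thursday of
#' November) and Christmas, on their calendar dates (no observed-date
#' shifting).
#'
#' @param year Calendar year(s).
#' @return A `Date` vector.
#' @export
us_holidays <- function(year) {
  one <- function(y) {
    wday_of <- function(d) as.POSIXlt(d)$wday # 0 = Sunday
    last_monday <- function(d) d - ((wday_of(d) - 1) %% 7)
    first_monday <- function(d) d + ((1 - wday_of(d)) %% 7)
    nth_thursday <- function(d, n) d + ((4 - wday_of(d)) %% 7) + 7 * (n - 1)
    as.Date(c(
      sprintf("%d-01-01", y),
      format(last_monday(as.Date(sprintf("%d-05-31", y)))),
      sprintf("%d-07-04", y),
      format(first_monday(as.Date(sprintf("%d-09-01", y)))),
      format(nth_thursday(as.Date(sprintf("%d-11-01", y)), 4)),
      sprintf("%d-12-25", y)
    ))
  }
  do.call(c, lapply(year, one))
}

#' Day type of a calendar date
#'
#' Holidays take precedence over the weekend types.
#'
#' @param date A `Date` vector.
#' @param holidays A `Date` vector of holiday dates (defaults to the six
#'   major U.S. holidays of the years spanned).
#' @return `"weekday"`, `"saturday"`, `"sunday"` or `"holiday"`.
#' @export
day_type_of <- function(date, holidays = NULL) {
  if (is.null(holidays)) {
    holidays <- us_holidays(sort(unique(as.integer(format(date, "%Y")))))
  }
  wd <- as.POSIXlt(date)$wday
  out <- ifelse(wd == 0, "sunday", ifelse(wd == 6, "saturday", "weekday"))
  out[date %in% holidays] <- "holiday"
  out
}

#' Expand weekday traffic profiles into an hourly year of class volumes
#'
#' Applies the day-type total-volume factor (F1), the weekday mix
#' fractions (F2) and the day-type light/heavy ratios (F3), then
#' renormalises classes to the adjusted hourly total, for every hour of the
#' requested date range.
#'
#' @param weekday_profile Tibble `road_id`, `hour`, `total_vph` (typical
#'   weekday); without a `road_id` column the profile applies to every
#'   road.
#' @param roads Road table from [road_segments()] (supplies `road_type`).
#' @param dates `Date` vector of days to expand.
#' @param mix Tibble `road_type`, `class`, `hour`, `fraction` (weekday F2).
#' @param f1 Tibble `day_type`, `hour`, `f1`.
#' @param f3 Tibble `day_type`, `hour`, `duty`, `f3` (`duty` is `"light"`
#'   or `"heavy"`).
#' @param holidays Optional `Date` vector, see [day_type_of()].
#' @return Long tibble: `date`, `hour`, `road_id`, `class`, `volume_vph`,
#'   `total_vph`, `day_type`.
#' @export
build_hourly_traffic <- function(weekday_profile, roads, dates, mix, f1, f3,
                                 holidays = NULL) {
  if (!"road_id" %in% names(weekday_profile)) {
    weekday_profile <- tidyr::expand_grid(
      road_id = roads$id, weekday_profile
    )
  }
  dtypes <- tibble(date = dates, day_type = day_type_of(dates, holidays))
  base <- tidyr::expand_grid(dtypes, hour = 0:23) %>%
    left_join(weekday_profile, by = "hour", relationship = "many-to-many") %>%
    left_join(
      roads %>% select("id", "road_type") %>% rename(road_id = "id"),
      by = "road_id"
    )
  base$total_vph <- adjust_total_volume(
    base$total_vph, base$day_type, base$hour, f1
  )
  long <- base %>%
    left_join(mix,
      by = c("road_type", "hour"),
      relationship = "many-to-many"
    ) %>%
    mutate(duty = duty_class(.data$class)) %>%
    left_join(f3, by = c("day_type", "hour", "duty"))
  long$f3[is.na(long$f3) | long$day_type == "weekday"] <- 1
  long %>%
    group_by(.data$date, .data$hour, .data$road_id) %>%
    mutate(
      unadj = .data$total_vph * .data$fraction * .data$f3,
      volume_vph = if (sum(.data$unadj) > 0) {
        .data$unadj * .data$total_vph[1] / sum(.data$unadj)
      } else {
        0 * .data$unadj
      }
    ) %>%
    ungroup() %>%
    select(
      "date", "hour", "road_id", "class", "volume_vph", "total_vph",
      "day_type"
    )
}

#' Hourly segment emission rates for one pollutant
#'
#' For each road-hour: BPR speed from the total volume, seasonal
#' emission-factor lookup at the nearest speed bin for each vehicle class,
#' then the mix-weighted segment rate and fleet-average per-vehicle rate.
#'
#' @param traffic Long class-volume tibble from [build_hourly_traffic()].
#' @param roads Road table from [road_segments()].
#' @param ef_table Emission-factor tibble (see
#'   [validate_emission_table()]).
#' @param pollutant Pollutant code present in `ef_table` (e.g. `"CO"`).
#' @param strict_units See [segment_emission_rate()].
#' @return Tibble: `date`, `hour`, `road_id`, `total_vph`, `speed_mph`,
#'   `Q_g_hr_km`, `E_g_km_veh`.
#' @export
segment_emissions <- function(traffic, roads, ef_table, pollutant,
                              strict_units = FALSE) {
  conv <- if (strict_units) 1 / 1.609347 else 0.625
  rd <- roads %>%
    select("id", "sff_mph", "capacity_vph", "alpha", "beta") %>%
    rename(road_id = "id")
  hourly <- traffic %>%
    distinct(.data$date, .data$hour, .data$road_id, .data$total_vph) %>%
    left_join(rd, by = "road_id") %>%
    mutate(
      speed_mph = bpr_speed(
        .data$sff_mph, .data$total_vph, .data$capacity_vph,
        .data$alpha, .data$beta
      ),
      season = season_of(as.integer(format(.data$date, "%m")))
    )
  cls <- traffic %>%
    left_join(
      hourly %>% select("date", "hour", "road_id", "speed_mph", "season"),
      by = c("date", "hour", "road_id")
    )
  cls$factor <- lookup_emission_factor(
    ef_table, pollutant, cls$season, cls$class, cls$speed_mph
  )
  q <- cls %>%
    group_by(.data$date, .data$hour, .data$road_id) %>%
    summarise(
      Q_g_hr_km = conv * sum(.data$volume_vph * .data$factor),
      .groups = "drop"
    )
  hourly %>%
    left_join(q, by = c("date", "hour", "road_id")) %>%
    mutate(
      E_g_km_veh = ifelse(.data$total_vph > 0,
        .data$Q_g_hr_km / .data$total_vph, 0
      )
    ) %>%
    select(
      "date", "hour", "road_id", "total_vph", "speed_mph", "Q_g_hr_km",
      "E_g_km_veh"
    )
}
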