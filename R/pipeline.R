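#' Predict hourly concentrations at receptors from all roads
#'
#' For every hour and receptor: the calm policy is applied to the wind,
#' the wind angle, distance, traffic volume and fleet-average emission
#' rate feed the composite reduced-form model for each road, and the
#' per-road contributions are summed (line-source superposition), plus any
#' configured background. Calm hours are missing (`NA`), never zero;
#' permanently upwind receptors get zeros.
#'
#' @param roads Road table from [road_segments()].
#' @param receptors Tibble `id`, `x_m`, `y_m`.
#' @param met Tibble `date`, `hour`, `wind_dir`, `wind_speed`, and
#'   optionally `calm` (logical).
#' @param emissions Tibble `date`, `hour`, `road_id`, `total_vph`,
#'   `E_g_km_veh` from [segment_emissions()].
#' @param params Parameter list from [dispersion_params()].
#' @param units `"ppm"` or `"ugm3"`.
#' @return Long tibble `receptor_id`, `date`, `hour`, `conc`, carrying a
#'   `log` attribute with calm, volume-clamp and distance-clamp tallies.
#' @export
predict_hourly <- function(roads, receptors, met, emissions,
                           params = dispersion_params(),
                           units = c("ppm", "ugm3")) {
  units <- match.arg(units)
  if (!"calm" %in% names(met)) met$calm <- FALSE
  met <- met %>% arrange(.data$date, .data$hour)
  geo <- suppressWarnings(receptor_road_geometry(receptors, roads))

  n_h <- nrow(met)
  n_r <- nrow(receptors)
  u <- apply_calm_policy(met$wind_speed, met$calm)
  total <- matrix(0, nrow = n_r, ncol = n_h)

  n_clamp_v <- 0L
  n_clamp_x <- 0L
  for (i in seq_len(nrow(roads))) {
    rd <- roads[i, ]
    em <- met %>%
      select("date", "hour") %>%
      left_join(
        emissions %>% filter(.data$road_id == rd$id),
        by = c("date", "hour")
      )
    if (any(is.na(em$total_vph))) {
      miss <- unique(em$date[is.na(em$total_vph)])
      abort(paste0(
        "traffic/emission series does not cover all met hours for road ",
        rd$id, "; first missing day: ", format(miss[1])
      ))
    }
    g <- geo %>% filter(.data$road_id == rd$id)
    g <- g[match(receptors$id, g$receptor_id), ]
    n_clamp_x <- n_clamp_x + sum(g$distance_m < 15 | g$distance_m > 300)
    n_clamp_v <- n_clamp_v +
      sum(em$total_vph < 1000 | em$total_vph > 15000, na.rm = TRUE)

    # wind angle depends on the receptor only through its side indicator
    th_west <- wind_angle(met$wind_dir, rd$alignment_deg, 1)
    th_east <- wind_angle(met$wind_dir, rd$alignment_deg, 0)
    theta <- matrix(rep(th_east, each = n_r), nrow = n_r)
    theta[g$i_west == 1, ] <- matrix(
      rep(th_west, each = sum(g$i_west == 1)),
      nrow = sum(g$i_west == 1)
    )
    contrib <- suppressWarnings(concentration(
      theta = as.vector(theta),
      x = rep(g$distance_m, times = n_h),
      u = rep(u, each = n_r),
      v = rep(em$total_vph, each = n_r),
      e = rep(em$E_g_km_veh, each = n_r),
      params = utils::modifyList(params, list(background = 0)),
      units = units
    ))
    total <- total + matrix(contrib, nrow = n_r)
  }
  total <- total + params$background

  out <- tibble(
    receptor_id = rep(receptors$id, times = n_h),
    date = rep(met$date, each = n_r),
    hour = rep(met$hour, each = n_r),
    conc = as.vector(total)
  )
  attr(out, "log") <- list(
    n_hours = n_h, n_receptors = n_r,
    n_calm = sum(is.na(u)),
    n_volume_clamped = n_clamp_v,
    n_distance_clamped = n_clamp_x,
    n_missing_values = sum(is.na(out$conc))
  )
  out
}

#' Daily (24-hr) averages with a completeness rule
#'
#' A daily mean is reported only when at least `min_hours` of the 24
#' hourly values are available (default 12, i.e. at least half); days with
#' fewer valid hours — typically calm-heavy days — are missing, not zero.
#'
#' @param hourly Long tibble from [predict_hourly()] (columns
#'   `receptor_id`, `date`, `conc`).
#' @param min_hours Minimum number of valid hours (default 12).
#' @return Tibble `receptor_id`, `date`, `conc`, `n_valid`.
#' @export
daily_average <- function(hourly, min_hours = 12) {
  hourly %>%
    group_by(.data$receptor_id, .data$date) %>%
    summarise(
      n_valid = sum(!is.na(.data$conc)),
      conc = ifelse(n_valid >= min_hours,
        mean(.data$conc, na.rm = TRUE), NA_real_
      ),
      .groups = "drop"
    ) %>%
    select("receptor_id", "date", "conc", "n_valid")
}

#' Per-receptor summary statistics of a daily concentration field
#'
#' Annual (period) mean, selected percentiles of the 24-hr values
#' (computed over non-missing days only, by linear interpolation between
#' order statistics), the maximum, and the count of valid days. For a
#' non-negative series the 98th percentile is at least the mean.
#'
#' @param daily Tibble from [daily_average()].
#' @param receptors Optional receptor table to attach coordinates.
#' @param probs Percentile levels (default 0.5 and 0.98).
#' @return One row per receptor with `mean`, `p<level>` columns, `max`,
#'   `n_days`.
#' @export
field_summary <- function(daily, receptors = NULL, probs = c(0.5, 0.98)) {
  out <- daily %>%
    group_by(.data$receptor_id) %>%
    summarise(
      mean = mean(.data$conc, na.rm = TRUE),
      max = ifelse(all(is.na(.data$conc)), NA_real_,
        max(.data$conc, na.rm = TRUE)
      ),
      n_days = sum(!is.na(.data$conc)),
      qs = list(if (all(is.na(.data$conc))) {
        setNames(rep(NA_real_, length(probs)), paste0(probs * 100, "%"))
      } else {
        quantile(.data$conc, probs = probs, na.rm = TRUE, type = 7)
      }),
      .groups = "drop"
    )
  q <- do.call(rbind, out$qs)
  colnames(q) <- paste0("p", probs * 100)
  out <- dplyr::bind_cols(out %>% select(-"qs"), as_tibble(q))
  if (!is.null(receptors)) {
    out <- out %>% left_join(
      receptors %>% rename(receptor_id = "id"),
      by = "receptor_id"
    )
  }
  out
}

#' Worst-case and best-case days of a concentration field
#'
#' Days are ranked by the daily concentration averaged across all
#' receptors of the modelled domain (over non-missing receptor values);
#' the worst day is the argmax, the best the argmin, ties broken by the
#' earliest date.
#'
#' @param daily Tibble from [daily_average()].
#' @return A list with `worst_day`, `best_day` (Dates) and the
#'   `domain_daily` tibble (`date`, `domain_mean`).
#' @export
select_extreme_days <- function(daily) {
  dom <- daily %>%
    group_by(.data$date) %>%
    summarise(
      domain_mean = ifelse(all(is.na(.data$conc)), NA_real_,
        mean(.data$conc, na.rm = TRUE)
      ),
      .groups = "drop"
    ) %>%
    arrange(.data$date)
  ok <- !is.na(dom$domain_mean)
  if (!any(ok)) abort("no day has a valid domain-mean concentration")
  v <- dom$domain_mean
  list(
    worst_day = dom$date[ok][which.max(v[ok])],
    best_day = dom$date[ok][which.min(v[ok])],
    domain_daily = dom
  )
}

#' Trailing running mean with a completeness rule
#'
#' The running mean over the trailing `window` days is reported when at
#' least `min_frac` of the days in the window are non-missing (mirroring
#' the spirit of the daily completeness rule); otherwise missing. A window
#' of 1 returns the series itself.
#'
#' @param x Numeric series (daily values, in date order).
#' @param window Window length in days (1, 5 and 30 are the conventional
#'   choices).
#' @param min_frac Minimum fraction of valid days in the window.
#' @return Numeric vector, same length as `x`.
#' @export
running_mean <- function(x, window, min_frac = 0.5) {
  if (window == 1) {
    return(x)
  }
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1, i - window + 1)
    w <- x[j:i]
    if (i >= window && sum(!is.na(w)) >= min_frac * window) {
      out[i] <- mean(w, na.rm = TRUE)
    }
  }
  out
}

#' Correlation of (running-mean) daily series at two receptors
#'
#' Pearson correlation of the trailing running means of two daily series,
#' using pairwise-complete days (calm-induced missingness is structural).
#' Requires at least `min_overlap` shared non-missing days; otherwise
#' returns `NA` with a diagnostic message.
#'
#' @param a,b Daily tibbles from [daily_average()] (single receptor each),
#'   or numeric vectors on a shared date grid.
#' @param window Running-mean window in days (1 = plain 24-hr averages).
#' @param min_overlap Minimum shared non-missing days (default 10).
#' @return Pearson correlation coefficient, or `NA`.
#' @export
cross_receptor_correlation <- function(a, b, window = 1, min_overlap = 10) {
  to_vec <- function(z) {
    if (is.data.frame(z)) z$conc[order(z$date)] else z
  }
  va <- running_mean(to_vec(a), window)
  vb <- running_mean(to_vec(b), window)
  if (length(va) != length(vb)) {
    abort("series must share the same date grid")
  }
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < min_overlap) {
    rlang::inform(sprintf(
      "only %d overlapping non-missing days (< %d); correlation not computed",
      sum(ok), min_overlap
    ))
    return(NA_real_)
  }
  cor(va[ok], vb[ok])
}

#' Error of short monitoring campaigns against the annual mean
#'
#' Estimates how far the mean of a short monitoring campaign can fall from
#' the annual mean at a receptor, enumerating every possible start day in
#' the series. The error of a campaign is
#' `|campaign mean - annual mean| / annual mean`. The `two_season`
#' strategy averages two equal windows 26 weeks apart (sampling opposite
#' seasons), which cancels much of the seasonal cycle.
#'
#' @param daily Daily tibble from [daily_average()] for one receptor, or a
#'   numeric vector of daily values in date order.
#' @param weeks Campaign length in weeks per window (1 or 2 typically).
#' @param strategy `"single_period"` or `"two_season"`.
#' @param detail Return the per-start errors instead of the summary.
#' @return Tibble with `strategy`, `weeks`, `mean_error`, `min_error`,
#'   `max_error`, `n_windows` (errors as fractions of the annual mean), or
#'   the per-start tibble when `detail = TRUE`.
#' @export
campaign_error <- function(daily, weeks = 1,
                           strategy = c("single_period", "two_season"),
                           detail = FALSE) {
  strategy <- match.arg(strategy)
  x <- if (is.data.frame(daily)) daily$conc[order(daily$date)] else daily
  n <- length(x)
  if (n < 365) abort("campaign_error needs at least one full year of daily values")
  annual <- mean(x, na.rm = TRUE)
  if (!is.finite(annual) || annual == 0) {
    abort("annual mean is zero or undefined; relative error is undefined")
  }
  len <- as.integer(weeks * 7)
  offset <- 26L * 7L
  win_mean <- function(s) {
    w <- x[s:(s + len - 1)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  if (strategy == "single_period") {
    starts <- seq_len(n - len + 1)
    means <- vapply(starts, win_mean, numeric(1))
  } else {
    starts <- seq_len(n - offset - len + 1)
    if (length(starts) == 0) {
      abort("series too short for the two-season strategy")
    }
    means <- vapply(
      starts,
      function(s) mean(c(win_mean(s), win_mean(s + offset))),
      numeric(1)
    )
  }
  err <- abs(means - annual) / annual
  per <- tibble(start = starts, campaign_mean = means, error = err) %>%
    filter(!is.na(.data$error))
  if (detail) {
    return(per)
  }
  tibble(
    strategy = strategy, weeks = weeks,
    mean_error = mean(per$error),
    min_error = min(per$error),
    max_error = max(per$error),
    n_windows = nrow(per)
  )
}

#' Factor-of-two agreement and bias between predictions and observations
#'
#' Evaluation utilities for paired daily predictions and measurements: the
#' fraction of pairs whose ratio lies within a factor of two
#' (0.5 <= pred/obs <= 2), the Pearson correlation, and the relative mean
#' bias `(mean(pred) - mean(obs)) / mean(obs)`.
#'
#' @param predicted,observed Numeric vectors of paired daily values;
#'   pairs with a missing member or a non-positive observation are
#'   dropped.
#' @return Tibble with `fraction_within_2x`, `correlation`, `mean_bias`,
#'   `n`.
#' @export
factor_of_two_stats <- function(predicted, observed) {
  ok <- !is.na(predicted) & !is.na(observed) & observed > 0
  if (!any(ok)) abort("no valid prediction/observation pairs")
  p <- predicted[ok]
  o <- observed[ok]
  ratio <- p / o
  tibble(
    fraction_within_2x = mean(ratio >= 0.5 & ratio <= 2),
    correlation = if (length(p) > 2 && stats::sd(p) > 0 && stats::sd(o) > 0) {
      cor(p, o)
    } else {
      NA_real_
    },
    mean_bias = (mean(p) - mean(o)) / mean(o),
    n = length(p)
  )
}
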