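#' Dispersion model parameters
#'
#' Loads the packaged coefficient set of the reduced-form dispersion model:
#' a 19-row wind-sector table (folded wind angle 0-180 degrees every 10)
#' with the six distance-profile coefficients per sector (the scale
#' coefficients already folded with the wind-speed constant k7), plus the
#' global parameters k7-k13 and the 1322 ppm-to-ug/m3 conversion. The three
#' upwind rows (0, 10, 20 degrees) are all zero; loading verifies this.
#'
#' @param sector_interpolation Interpolate linearly between adjacent sector
#'   rows instead of snapping to the nearest 10-degree row (off by
#'   default; the coefficients were fitted per discrete sector).
#' @param x_range_policy What to do for receptors beyond the 300 m fitted
#'   range: `"extrapolate"` evaluates the profile with a warning,
#'   `"missing"` returns `NA`. Distances under 15 m always clamp to 15 m.
#' @param background Scalar background concentration added to every
#'   non-missing prediction, in output units (default 0).
#' @return A list with elements `sectors` (tibble), the named scalars
#'   `k7`...`k13`, `ppm_to_ugm3`, and the policy settings.
#' @export
dispersion_params <- function(sector_interpolation = FALSE,
                              x_range_policy = c("extrapolate", "missing"),
                              background = 0) {
  x_range_policy <- match.arg(x_range_policy)
  sectors <- readr::read_csv(
    system.file("extdata", "sector_params.csv", package = "nearroad"),
    show_col_types = FALSE
  )
  scalars <- readr::read_csv(
    system.file("extdata", "scalar_params.csv", package = "nearroad"),
    show_col_types = FALSE
  )
  sc <- as.list(setNames(scalars$value, scalars$name))
  upwind <- sectors[sectors$angle_deg <= 20, -1]
  if (any(unlist(upwind) != 0)) {
    abort("corrupt sector table: upwind rows (0-20 degrees) must be zero")
  }
  if (any(sectors$k1_star < 0) || any(sectors$k4_star < 0) ||
    any(sectors$k3 < 0) || any(sectors$k6 < 0)) {
    abort("corrupt sector table: scale and decay coefficients must be non-negative")
  }
  c(
    list(sectors = sectors), sc,
    list(
      sector_interpolation = sector_interpolation,
      x_range_policy = x_range_policy,
      background = background
    )
  )
}

# Nearest sector row index (1 = 0 degrees ... 19 = 180), ties rounding up.
sector_index <- function(theta_folded) {
  pmin(floor(theta_folded / 10 + 0.5), 18) + 1
}

#' Double-exponential concentration-distance profile for one wind sector
#'
#' The unit concentration at distance `X` (m) from the road for a given
#' wind sector is the sum of a fast and a slow exponential decay, each with
#' a scale, a distance offset and a decay rate:
#' `C(X) = k1* exp(-k3 (X - k2)) + k4* exp(-k6 (X - k5))`. It gives the
#' concentration in ppm for the nominal source (10,000 vehicles/hr emitting
#' 1 g/km/vehicle at 4 m/s wind). All-zero coefficient rows (upwind
#' sectors) give 0.
#'
#' @param x Distance(s) from the road centreline, m; fitted range 15-300.
#' @param sector_row One row of the sector table (list or 1-row data
#'   frame with `k1_star`, `k2`, `k3`, `k4_star`, `k5`, `k6`).
#' @return Unit concentration(s), ppm per nominal emission.
#' @export
distance_profile <- function(x, sector_row) {
  sector_row$k1_star * exp(-sector_row$k3 * (x - sector_row$k2)) +
    sector_row$k4_star * exp(-sector_row$k6 * (x - sector_row$k5))
}

#' Wind-speed dilution factor
#'
#' Concentrations follow an approximately inverse power law in wind speed:
#' the factor `k7 * U^k8` (k7 = 2.81, k8 = -0.739) rescales the
#' concentration predicted at the nominal 4 m/s, where the factor is within
#' about 1 percent of unity. Calms must be removed upstream: speeds below
#' 0.5 m/s violate the calm-handling contract and raise an error.
#'
#' @param u Wind speed(s), m/s, >= 0.5.
#' @param params Parameter list from [dispersion_params()].
#' @return Dimensionless factor(s).
#' @export
wind_speed_factor <- function(u, params = dispersion_params()) {
  if (any(u < 0.5, na.rm = TRUE)) {
    abort("wind speed below 0.5 m/s: calm hours must be handled by the calm policy upstream")
  }
  params$k7 * u^params$k8
}

#' Traffic-volume dispersion factor
#'
#' Higher traffic increases vehicle-induced turbulence and so enhances
#' dispersion; the bracketed volume term captures this relative to the
#' nominal 10,000 vehicles/hr:
#' `B(V, X) = k9 exp(k10 (V - k11) (1 + k12 (1 - ln(X)/k13)))`.
#' It equals k9 (= 0.99898) exactly at V = k11 (= 10,749) for every
#' distance, decreases monotonically in volume, and over the validity
#' window (V in 1,000-15,000 vehicles/hr, X in 15-300 m) ranges from 0.89
#' at high flows and the longest distances to 1.29 at low flows. The weak
#' log-distance modifier leaves the factor unchanged at X = exp(k13), about
#' 197 m, damping the volume effect nearer the road and amplifying it
#' beyond, and it does not depend on wind angle.
#'
#' @param v Traffic volume(s), vehicles/hr; values outside 1,000-15,000 are
#'   clamped to the window edge with a warning.
#' @param x Distance(s) from the road, m (clamped to 15-300 for this
#'   factor).
#' @param params Parameter list from [dispersion_params()].
#' @return Dimensionless factor(s).
#' @export
volume_dispersion_factor <- function(v, x, params = dispersion_params()) {
  if (any(v < 1000 | v > 15000, na.rm = TRUE)) {
    warn("traffic volume outside the fitted 1,000-15,000 vehicles/hr window; clamped")
    v <- pmin(pmax(v, 1000), 15000)
  }
  x <- pmin(pmax(x, 15), 300)
  g <- 1 + params$k12 * (1 - log(x) / params$k13)
  params$k9 * exp(params$k10 * (v - params$k11) * g)
}

#' Apply the calm-wind policy to hourly wind observations
#'
#' Gaussian line-source models cannot represent calm hours: no prediction
#' is attempted and the hour is recorded as missing (never zero). Reported
#' speeds between 0 and 0.5 m/s are raised to the 0.5 m/s floor.
#'
#' @param speed Wind speed(s), m/s.
#' @param calm Logical calm flag(s) (default: speed of exactly 0, or
#'   missing, is calm).
#' @return Usable wind speed(s) with `NA` marking calm hours.
#' @export
apply_calm_policy <- function(speed, calm = NULL) {
  if (is.null(calm)) calm <- is.na(speed) | speed == 0
  calm <- calm | is.na(speed) | speed == 0
  out <- pmax(speed, 0.5)
  out[calm] <- NA_real_
  out
}

#' Composite reduced-form concentration at a receptor
#'
#' Multiplies the four submodels: the segment emission rate relative to the
#' nominal source (`E V / 10000`, with `E` the fleet-average per-vehicle
#' rate in g/km/vehicle), the volume dispersion factor, the wind-speed
#' power law `U^k8`, and the wind-sector distance profile (whose scale
#' coefficients absorb k7):
#' `C = (E V / 10^4) B(V, X) U^k8 [k1* e^{-k3 (X - k2)} + k4* e^{-k6 (X - k5)}]`
#' in ppm; `units = "ugm3"` multiplies the result by 1322. The result is 0
#' for upwind sectors (folded angle <= 20 degrees), missing (`NA`) for calm
#' hours, linear in the emission rate, and symmetric in the wind angle
#' about the road normal.
#'
#' @param theta Wind angle(s) in degrees (see [wind_angle()]); folded
#'   internally.
#' @param x Receptor distance(s) from the road centreline, m. Distances
#'   under 15 m clamp to 15 m with a warning; beyond 300 m the profile is
#'   extrapolated (or set missing) per the parameter range policy.
#' @param u Wind speed(s), m/s; `NA` marks calm hours and propagates.
#'   Speeds between 0 and 0.5 are raised to 0.5.
#' @param v Traffic volume(s), vehicles/hr. The emission scaling uses the
#'   true volume; the dispersion factor clamps it to its fitted window.
#' @param e Fleet-average emission rate(s), g/km/vehicle.
#' @param params Parameter list from [dispersion_params()].
#' @param units `"ppm"` (native) or `"ugm3"`.
#' @return Concentration(s) in the requested units, plus any configured
#'   background.
#' @export
concentration <- function(theta, x, u, v, e,
                          params = dispersion_params(),
                          units = c("ppm", "ugm3")) {
  units <- match.arg(units)
  n <- max(length(theta), length(x), length(u), length(v), length(e))
  theta <- rep_len(theta, n)
  x <- rep_len(x, n)
  u <- rep_len(u, n)
  v <- rep_len(v, n)
  e <- rep_len(e, n)

  if (any(x < 15, na.rm = TRUE)) {
    warn("receptor distance under the 15 m fitted range; clamped to 15 m")
  }
  beyond <- !is.na(x) & x > 300
  if (any(beyond)) {
    if (params$x_range_policy == "missing") {
      x[beyond] <- NA_real_
    } else {
      warn("receptor distance beyond the 300 m fitted range; profile extrapolated")
    }
  }
  x_prof <- pmax(x, 15)

  u <- apply_calm_policy(u)
  kernel <- profile_by_sector(theta, x_prof, params)
  bracket <- volume_dispersion_factor(v, x_prof, params)
  out <- (e * v / 10000) * bracket * u^params$k8 * kernel
  if (units == "ugm3") out <- out * params$ppm_to_ugm3
  out + params$background
}

# Sector-resolved distance profile, vectorised over theta and x.
profile_by_sector <- function(theta, x, params) {
  folded <- fold_wind_angle(theta)
  s <- params$sectors
  if (isTRUE(params$sector_interpolation)) {
    lo <- pmin(floor(folded / 10), 17) + 1
    hi <- lo + 1
    w <- folded / 10 - (lo - 1)
    p_lo <- distance_profile(x, s[lo, ])
    p_hi <- distance_profile(x, s[hi, ])
    (1 - w) * p_lo + w * p_hi
  } else {
    idx <- sector_index(folded)
    distance_profile(x, s[idx, ])
  }
}
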