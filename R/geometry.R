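#' Build and validate a table of straight road segments
#'
#' A road segment is a straight link described by its two endpoints in a
#' planar projected coordinate system (metres, e.g. UTM), its lane count,
#' free-flow speed, per-lane capacity, and the two coefficients of the
#' Bureau of Public Roads volume-delay function. The road alignment angle is
#' measured clockwise from north and lies in `[0, 180)` (90 = east-west).
#'
#' @param roads A data frame with columns `id`, `x1_m`, `y1_m`, `x2_m`,
#'   `y2_m`, `lanes`, `sff_mph`, `cap_vphpl`, `alpha`, `beta` and optionally
#'   `road_type` (`"freeway"` or `"arterial"`, used to pick the weekday
#'   vehicle-mix profile; defaults to `"freeway"`).
#' @return A tibble with the input columns plus `alignment_deg` (derived from
#'   the endpoints), `length_m` and `capacity_vph` (= `lanes * cap_vphpl`).
#' @examples
#' road_segments(data.frame(
#'   id = "M39", x1_m = 0, y1_m = -1000, x2_m = 0, y2_m = 1000,
#'   lanes = 6, sff_mph = 60, cap_vphpl = 2000, alpha = 0.1226, beta = 4.688
#' ))
#' @export
road_segments <- function(roads) {
  roads <- as_tibble(roads)
  required <- c(
    "id", "x1_m", "y1_m", "x2_m", "y2_m", "lanes", "sff_mph",
    "cap_vphpl", "alpha", "beta"
  )
  missing_cols <- setdiff(required, names(roads))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "road table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"road_type" %in% names(roads)) roads$road_type <- "freeway"
  dx <- roads$x2_m - roads$x1_m
  dy <- roads$y2_m - roads$y1_m
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) {
    abort("degenerate road segment: identical endpoints")
  }
  if (any(roads$lanes <= 0) || any(roads$sff_mph <= 0) ||
    any(roads$cap_vphpl <= 0)) {
    abort("lanes, free-flow speed and capacity must all be positive")
  }
  roads$alignment_deg <- road_alignment(roads$x1_m, roads$y1_m, roads$x2_m, roads$y2_m)
  roads$length_m <- len
  roads$capacity_vph <- roads$lanes * roads$cap_vphpl
  roads
}

#' Road alignment angle from endpoint coordinates
#'
#' Alignment is the compass bearing of the segment reduced modulo 180, so it
#' always lies in `[0, 180)`: 0 is a north-south road, 90 east-west.
#'
#' @param x1,y1,x2,y2 Endpoint coordinates (m, projected; x east, y north).
#' @return Alignment angle(s) in degrees in `[0, 180)`.
#' @export
road_alignment <- function(x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  if (any(dx == 0 & dy == 0)) {
    abort("degenerate road segment: identical endpoints")
  }
  (atan2(dx, dy) * 180 / pi) %% 180
}

# Unit direction vector along the road pointed toward the endpoint with the
# larger northing (larger easting for exactly east-west roads). This
# orientation fixes a deterministic left/right convention for every
# alignment; the side to the left of this direction is the "west" side used
# by the wind-angle indicator.
road_direction <- function(alignment_deg) {
  az <- ifelse(alignment_deg < 90, alignment_deg,
    ifelse(alignment_deg > 90, alignment_deg + 180, 90)
  )
  rad <- az * pi / 180
  list(dx = sin(rad), dy = cos(rad))
}

#' Receptor-to-road geometry: normal distance and side indicator
#'
#' Computes, for every receptor x road pair, the unsigned distance from the
#' receptor to the infinite road centreline, the west-side indicator used by
#' [wind_angle()], and a flag marking receptors whose normal foot falls
#' beyond the finite segment ends (these are still computed, with a
#' warning, because the model treats the link as a long straight element).
#'
#' The "west" side of a road is the side to the left of the along-road
#' direction that points toward the endpoint with the larger northing
#' (larger easting for an exactly east-west road, making its north side the
#' "west" side by convention).
#'
#' @param receptors Data frame with columns `id`, `x_m`, `y_m`.
#' @param roads A road table from [road_segments()].
#' @return A tibble with one row per receptor x road: `receptor_id`,
#'   `road_id`, `distance_m`, `i_west` (1 west of road, 0 otherwise) and
#'   `beyond_segment`.
#' @export
receptor_road_geometry <- function(receptors, roads) {
  receptors <- as_tibble(receptors)
  if (!all(c("id", "x_m", "y_m") %in% names(receptors))) {
    abort("receptor table needs columns id, x_m, y_m")
  }
  out <- purrr::map_dfr(seq_len(nrow(roads)), function(i) {
    rd <- roads[i, ]
    d <- road_direction(rd$alignment_deg)
    rx <- receptors$x_m - rd$x1_m
    ry <- receptors$y_m - rd$y1_m
    cross <- d$dx * ry - d$dy * rx
    along <- d$dx * rx + d$dy * ry
    # project segment endpoints onto the oriented axis
    ends <- sort(c(
      0,
      d$dx * (rd$x2_m - rd$x1_m) + d$dy * (rd$y2_m - rd$y1_m)
    ))
    tibble(
      receptor_id = receptors$id,
      road_id = rd$id,
      distance_m = abs(cross),
      i_west = as.integer(cross > 0),
      beyond_segment = along < ends[1] | along > ends[2]
    )
  })
  if (any(out$beyond_segment)) {
    warn(sprintf(
      "%d receptor-road pair(s) lie beyond the segment ends; distances use the infinite centreline",
      sum(out$beyond_segment)
    ))
  }
  out
}

#' Wind angle between a wind vector and a road/receptor pair
#'
#' The wind angle theta orients the wind relative to the receptor's side of
#' the road: theta = 0 means the wind is perpendicular to the road with the
#' receptor upwind, theta = 180 perpendicular with the receptor downwind,
#' and 90/270 are road-parallel winds. It is computed as
#' `theta = (W - R - 90 - 180 * |I_W - I_R|) mod 360`, where `W` is the
#' meteorological wind direction (degrees the wind blows from), `R` the road
#' alignment in `[0, 180)`, `I_W` the west-side indicator and `I_R = 1` when
#' `R > 90`. Equivalently, theta is the clockwise angle from the
#' road-to-receptor normal to the wind-from direction. For the classic
#' worked case (W = 112.5, R = 135) the downwind (west-side) receptor gets
#' 247.5 degrees and the upwind (east-side) receptor 67.5 degrees, and winds
#' from 45/225 degrees give 180 for the respective downwind receptors.
#'
#' @param wind_dir Wind direction(s), degrees in `[0, 360)`, FROM which the
#'   wind blows.
#' @param alignment_deg Road alignment angle(s) in `[0, 180)`.
#' @param i_west West-side indicator(s), 0 or 1 (see
#'   [receptor_road_geometry()]).
#' @return Wind angle(s) in degrees in `[0, 360)`.
#' @export
wind_angle <- function(wind_dir, alignment_deg, i_west) {
  if (any(alignment_deg < 0 | alignment_deg >= 180, na.rm = TRUE)) {
    abort("alignment_deg must lie in [0, 180)")
  }
  if (any(!i_west %in% c(0, 1), na.rm = TRUE)) {
    abort("i_west must be 0 or 1")
  }
  i_r <- as.numeric(alignment_deg > 90)
  (wind_dir - alignment_deg - 90 - 180 * abs(i_west - i_r)) %% 360
}

#' Fold a wind angle onto the symmetric half-range `[0, 180]`
#'
#' The dispersion problem is mirror-symmetric about the road normal: an
#' angle of 10 degrees is equivalent to 350. The folded angle
#' `min(theta, 360 - theta)` indexes the wind-sector coefficient table,
#' whose rows are listed as paired angles (10/350, 20/340, ...).
#'
#' @param theta Wind angle(s) in degrees in `[0, 360)`.
#' @return Folded angle(s) in `[0, 180]`.
#' @export
fold_wind_angle <- function(theta) {
  theta <- theta %% 360
  pmin(theta, 360 - theta)
}
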