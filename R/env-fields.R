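#' Current magnitude from velocity components
#'
#' Combines zonal (east-west) and meridional (north-south) velocity
#' components into a scalar speed, `sqrt(u^2 + v^2)`.
#'
#' @param u Zonal velocity (m/s). Vectorised.
#' @param v Meridional velocity (m/s). Recycled against `u`.
#' @return Numeric vector of speeds (m/s).
#' @examples
#' current_magnitude(3, 4) # 5
#' @export
current_magnitude <- function(u, v) {
  bad <- !is.finite(u) | !is.finite(v)
  if (any(bad)) {
    stop("non-finite velocity sample(s) at position(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  sqrt(u^2 + v^2)
}

#' Dynamic stratification of a velocity stack
#'
#' Vector combination of the standard deviations of the zonal and
#' meridional current components over a pixel's depth/time stack:
#' `DS = sqrt(sd(u)^2 + sd(v)^2)`. Unlike the standard deviation of the
#' speed itself, this captures variability in flow *direction* through the
#' water column, which vertically migrating larvae can exploit.
#'
#' @param u,v Zonal and meridional velocity samples (m/s), all depths and
#'   times pooled. At least two samples are required.
#' @return Dynamic stratification (m/s), a non-negative scalar.
#' @examples
#' dynamic_stratification(c(1, -1, 1, -1), c(0, 0, 0, 0))
#' @export
dynamic_stratification <- function(u, v) {
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  if (length(u) < 2L) stop("dynamic stratification needs >= 2 velocity samples")
  current_magnitude(u, v) # validates finiteness
  sqrt(stats::sd(u)^2 + stats::sd(v)^2)
}

#' Water-column mean within a depth range
#'
#' Unweighted arithmetic mean of a scalar sampled over (depth, time)
#' entries, restricted to levels inside `depth_range` (inclusive).
#' Level spacing is typically uneven in ocean-model output; no thickness
#' weighting is applied (`depth_weighting = "none"`), matching a plain
#' pixel average across depths.
#'
#' @param values Numeric samples, one per (depth, time) entry.
#' @param depth Depth (m, positive down) of each sample.
#' @param depth_range Length-2 numeric, `c(min, max)` depth in m.
#' @param depth_weighting Either `"none"` (default) or `"thickness"`;
#'   `"thickness"` weights each level by the gap to its neighbours.
#' @return Scalar mean.
#' @export
water_column_mean <- function(values, depth, depth_range = c(0, Inf),
                              depth_weighting = c("none", "thickness")) {
  depth_weighting <- match.arg(depth_weighting)
  stopifnot(length(values) == length(depth), length(depth_range) == 2L)
  sel <- depth >= depth_range[1] & depth <= depth_range[2]
  if (!any(sel)) stop("no depth levels inside range [",
                      depth_range[1], ", ", depth_range[2], "] m")
  v <- values[sel]
  if (all(is.na(v))) stop("all values missing within the requested depth range")
  if (depth_weighting == "none") return(mean(v, na.rm = TRUE))
  d <- depth[sel]
  lev <- sort(unique(d))
  gaps <- if (length(lev) == 1L) 1 else {
    mids <- c(lev[1], (lev[-1] + lev[-length(lev)]) / 2, lev[length(lev)])
    diff(mids)
  }
  w <- gaps[match(d, lev)]
  stats::weighted.mean(v, w, na.rm = TRUE)
}

#' Area of a regular lat/lon grid cell
#'
#' Small-cell approximation `(res * 111.32 km)^2 * cos(lat)`, adequate at
#' the 0.1 degree working resolution.
#'
#' @param lat Latitude of the cell centre (degrees).
#' @param resolution Cell size (degrees).
#' @return Area in km^2 (vectorised over `lat`).
#' @export
pixel_area <- function(lat, resolution) {
  if (any(abs(lat) > 90)) stop("|lat| must be <= 90")
  (resolution * 111.32)^2 * cos(lat * pi / 180)
}

#' Summarise a velocity/temperature stack into hydrographic fields
#'
#' Collapses per-pixel (depth, time) samples into the three scalar fields
#' used downstream: mean water-column temperature `T` (deg C), mean current
#' magnitude `U` (m/s; speeds are computed per sample first and then
#' averaged), and dynamic stratification `DS` (m/s).
#'
#' @param samples A data frame with columns `lon`, `lat`, `u`, `v`, `temp`
#'   and optionally `depth` (m, positive down).
#' @param depth_range Optional depth window, `c(min, max)` in m.
#' @return A tibble with one row per (lon, lat) pixel and columns
#'   `T`, `U`, `DS`, `n_samples`.
#' @export
summarise_env_stack <- function(samples, depth_range = c(0, Inf)) {
  stopifnot(is.data.frame(samples),
            all(c("lon", "lat", "u", "v", "temp") %in% names(samples)))
  if (!"depth" %in% names(samples)) samples$depth <- 0
  samples |>
    dplyr::filter(.data$depth >= depth_range[1], .data$depth <= depth_range[2]) |>
    dplyr::group_by(.data$lon, .data$lat) |>
    dplyr::summarise(
      T = mean(.data$temp, na.rm = TRUE),
      U = mean(current_magnitude(.data$u, .data$v), na.rm = TRUE),
      DS = dynamic_stratification(.data$u, .data$v),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}
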