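#' Rasterise a literature range onto the working grid
#'
#' Marks grid cells whose centres fall inside any of the supplied
#' lat/lon rectangles. Multiple rows encode disjoint range segments
#' (e.g. "Atlantic only" boundaries).
#'
#' @param grid A pixel tibble with columns `lon`, `lat` (cell centres).
#' @param bounds A data frame with columns `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`; one row per rectangle.
#' @param species Optional species name used in error messages.
#' @return Logical vector, one element per grid row.
#' @export
rasterize_range <- function(grid, bounds, species = NULL) {
  stopifnot(all(c("lon", "lat") %in% names(grid)),
            all(c("lat_min", "lat_max", "lon_min", "lon_max") %in% names(bounds)))
  mask <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(bounds))) {
    mask <- mask |
      (grid$lat >= bounds$lat_min[i] & grid$lat <= bounds$lat_max[i] &
         grid$lon >= bounds$lon_min[i] & grid$lon <= bounds$lon_max[i])
  }
  if (!any(mask)) {
    stop("range of ", if (is.null(species)) "species" else species,
         " does not intersect the grid")
  }
  mask
}

#' Potential distribution from range, depth and habitat filters
#'
#' Intersects a rasterised range with the species' depth range (inclusive
#' on both ends, against cell bathymetry) and its habitat classes, and
#' sums latitude-corrected cell areas into a potential habitat surface.
#'
#' @param grid Pixel tibble with `lon`, `lat`, `depth` (m, positive down)
#'   and, if habitat filtering is requested, a `habitat` column.
#' @param range_mask Logical vector from [rasterize_range()].
#' @param depth_range Length-2 numeric `c(min, max)` in m.
#' @param habitat_classes Character vector of admissible habitat labels,
#'   or `NULL` to skip habitat filtering.
#' @param resolution Grid cell size in degrees; taken from
#'   `attr(grid, "resolution")` when `NULL`.
#' @return An object of class `potential_distribution`: list with `mask`
#'   (logical vector), `area` (km^2) and `n_cells`.
#' @export
potential_habitat <- function(grid, range_mask, depth_range = c(0, Inf),
                              habitat_classes = NULL, resolution = NULL) {
  stopifnot(length(range_mask) == nrow(grid), "depth" %in% names(grid))
  if (is.null(resolution)) resolution <- attr(grid, "resolution")
  if (is.null(resolution)) stop("grid has no `resolution` attribute; supply one")
  mask <- range_mask &
    !is.na(grid$depth) &
    grid$depth >= depth_range[1] & grid$depth <= depth_range[2]
  if (!is.null(habitat_classes)) {
    if (!"habitat" %in% names(grid)) stop("grid has no `habitat` column")
    legend <- unique(stats::na.omit(grid$habitat))
    unknown <- setdiff(habitat_classes, legend)
    if (length(unknown)) {
      stop("unknown habitat class(es): ", paste(unknown, collapse = ", "),
           "; valid labels: ", paste(sort(legend), collapse = ", "))
    }
    mask <- mask & !is.na(grid$habitat) & grid$habitat %in% habitat_classes
  }
  if (!any(mask)) warning("no cells pass the depth/habitat filters; empty distribution")
  area <- sum(pixel_area(grid$lat[mask], resolution))
  structure(list(mask = mask, area = area, n_cells = sum(mask)),
            class = "potential_distribution")
}

#' @export
print.potential_distribution <- function(x, ...) {
  cat("Potential distribution:", x$n_cells, "cells,",
      format(round(x$area, 1), big.mark = ","), "km^2\n")
  invisible(x)
}

#' Range-mean environmental conditions for a species
#'
#' Arithmetic means of environmental and productivity variables over the
#' cells of a species' potential distribution, i.e. the conditions the
#' species experiences across its range at its preferred depths (depth
#' restriction having been applied when the distribution was built).
#'
#' @param grid Pixel tibble carrying the environmental columns.
#' @param dist A `potential_distribution` (or plain logical mask).
#' @param vars Character vector of columns to average; defaults to every
#'   numeric column except `lon`/`lat`.
#' @return A one-row tibble of per-variable means.
#' @export
species_env_means <- function(grid, dist, vars = NULL) {
  mask <- if (inherits(dist, "potential_distribution")) dist$mask else dist
  stopifnot(is.logical(mask), length(mask) == nrow(grid))
  if (!any(mask)) stop("empty distribution: no cells to average over")
  if (is.null(vars)) {
    vars <- setdiff(names(grid)[vapply(grid, is.numeric, logical(1))],
                    c("lon", "lat"))
  }
  grid[mask, vars, drop = FALSE] |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = TRUE)))
}
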