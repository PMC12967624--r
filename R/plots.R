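#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-pixel map layer
#'
#' Raster-style map of any numeric column of a pixel tibble (richness,
#' a mode proportion, an environmental field, ...).
#'
#' @param grid Pixel tibble with `lon`, `lat`.
#' @param var Column to map (string).
#' @return A ggplot.
#' @export
plot_map <- function(grid, var = "richness") {
  ggplot2::ggplot(grid, ggplot2::aes(.data$lon, .data$lat,
                                     fill = .data[[var]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = var) +
    ggplot2::theme_minimal()
}

#' Plot latitudinal band proportions by developmental mode
#'
#' @param bands A [band_summary()] tibble (optionally several stacked
#'   with a `method` column).
#' @return A ggplot with one bar group per band, error bars where sds
#'   exist.
#' @export
plot_band_summary <- function(bands) {
  p <- ggplot2::ggplot(bands, ggplot2::aes(factor(.data$band_mid),
                                           .data$proportion,
                                           fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$proportion - .data$sd, 0),
                   ymax = pmin(.data$proportion + .data$sd, 1)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3,
      na.rm = TRUE) +
    ggplot2::labs(x = "Latitudinal band (midpoint, deg N)",
                  y = "Proportion of species", fill = "Mode") +
    ggplot2::theme_minimal()
  if ("method" %in% names(bands)) p <- p + ggplot2::facet_wrap(~method)
  p
}

#' @describeIn morans_correlogram Correlogram plot with the null
#'   expectation `-1/(n-1)` and the patch size marked.
#' @param object The fitted object.
#' @param ... Unused.
#' @method autoplot correlogram
#' @export
autoplot.correlogram <- function(object, ...) {
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(.data$dist_km, .data$morans_i)) +
    ggplot2::geom_hline(yintercept = -1 / (object$n - 1), linetype = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Distance (km)", y = "Moran's I") +
    ggplot2::theme_minimal()
  if (!is.na(object$patch_size_km)) {
    p <- p + ggplot2::geom_vline(xintercept = object$patch_size_km,
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' @describeIn fit_sar_lag Observed-versus-predicted plot.
#' @param object The fitted object.
#' @param ... Unused.
#' @method autoplot sar_fit
#' @export
autoplot.sar_fit <- function(object, ...) {
  df <- tibble::tibble(predicted = object$fitted, observed = object$observed)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(
      x = "Predicted logit proportion", y = "Observed logit proportion",
      subtitle = sprintf("R2 = %.3f, rho = %.3f", object$r_squared,
                         object$rho)) +
    ggplot2::theme_minimal()
}

#' @describeIn trait_pca Score plot on the first two components.
#' @param object The fitted object.
#' @param colour Optional vector (e.g. developmental mode) to colour
#'   points by.
#' @param ... Unused.
#' @method autoplot trait_pca
#' @export
autoplot.trait_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  ve <- 100 * object$variance_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  p <- if (is.null(colour)) p + ggplot2::geom_point() else {
    df$colour <- colour
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                     colour = .data$colour)) +
      ggplot2::geom_point() + ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                    y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}
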