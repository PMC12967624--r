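#' Metabolic-scaling parameters
#'
#' Bundle of constants for the temperature-size scaling of developmental
#' time: activation energy `E` (eV), Boltzmann's constant `k` (eV/K), the
#' allometric exponent `alpha`, and the calibrated proportionality constant
#' `a0const` (days/mm^0.75), which is `NULL` until set by [calibrate_dt()].
#'
#' @param E Activation energy in eV; 0.65 eV is the canonical value for
#'   ectotherm metabolism.
#' @param alpha Allometric mass exponent; 0.25 under quarter-power scaling.
#' @param a0const Calibrated constant (days/mm^0.75), or `NULL`.
#' @return An object of class `metabolic_params`.
#' @export
metabolic_params <- function(E = 0.65, alpha = 0.25, a0const = NULL) {
  stopifnot(E > 0, alpha > 0, alpha < 1, is.null(a0const) || a0const > 0)
  structure(list(E = E, k = 8.617333e-5, alpha = alpha, a0const = a0const),
            class = "metabolic_params")
}

#' @export
print.metabolic_params <- function(x, ...) {
  cat("Metabolic-scaling parameters\n")
  cat("  E      =", x$E, "eV\n")
  cat("  k      =", format(x$k), "eV/K\n")
  cat("  alpha  =", x$alpha, "\n")
  cat("  a0const=", if (is.null(x$a0const)) "<uncalibrated>" else
    format(x$a0const), "days/mm^0.75\n")
  invisible(x)
}

#' Shell volume from linear dimensions
#'
#' Volume of an idealised shell. Embryo and juvenile shells are treated as
#' spheres of the given diameter; adult shells take one of four solids
#' depending on overall shape: cylinder, cone, rectangular parallelepiped,
#' or semi-spheroid (two equal equatorial semi-axes of `width/2` and a
#' polar semi-axis of `height`).
#'
#' @param shape One of `"sphere"`, `"cylinder"`, `"cone"`,
#'   `"parallelepiped"`, `"semi_spheroid"`.
#' @param length Shell length (mm); the sphere diameter for `"sphere"`.
#' @param width Shell width/diameter (mm) where applicable.
#' @param height Shell height (mm) for parallelepiped and semi-spheroid.
#' @return Volume in mm^3.
#' @export
shell_volume <- function(shape, length = NULL, width = NULL, height = NULL) {
  shape <- match.arg(shape, c("sphere", "cylinder", "cone",
                              "parallelepiped", "semi_spheroid"))
  need <- function(val, nm) {
    if (is.null(val) || is.na(val)) stop("shape '", shape,
                                         "' needs dimension `", nm, "`")
    if (val <= 0) stop("dimension `", nm, "` must be positive")
    val
  }
  switch(shape,
    sphere = (pi / 6) * need(length, "length")^3,
    cylinder = pi * (need(width, "width") / 2)^2 * need(length, "length"),
    cone = (pi / 3) * (need(width, "width") / 2)^2 * need(length, "length"),
    parallelepiped = need(length, "length") * need(width, "width") *
      need(height, "height"),
    semi_spheroid = (2 / 3) * pi * (need(width, "width") / 2)^2 *
      need(height, "height")
  )
}

#' Growth ratios between life stages
#'
#' Volume ratios juvenile/initial (`Gr1`), adult/juvenile (`Gr2`) and
#' adult/initial (`Gr3`); `Gr1 * Gr2 = Gr3` by construction.
#'
#' @param IS,JS,AS Initial (embryo/larva), juvenile and adult volumes
#'   (mm^3), all positive. Vectorised.
#' @return A tibble with columns `Gr1`, `Gr2`, `Gr3`.
#' @export
growth_ratios <- function(IS, JS, AS) {
  if (any(c(IS, JS, AS) <= 0, na.rm = TRUE)) stop("sizes must be positive")
  tibble::tibble(Gr1 = JS / IS, Gr2 = AS / JS, Gr3 = AS / IS)
}

#' Temperature-size metabolic term
#'
#' The Arrhenius-by-allometry term `x = exp(E/(k*T)) * deltaS^alpha` whose
#' proportionality to developmental time defines the scaling model.
#'
#' @param temp_K Temperature in Kelvin (> 0). Vectorised.
#' @param delta_s Size gain from initial stage to juvenile (mm^3, >= 0).
#' @param params A [metabolic_params()] object.
#' @return The metabolic term (mm^0.75 at `alpha = 0.25`).
#' @export
metabolic_term <- function(temp_K, delta_s, params = metabolic_params()) {
  stopifnot(inherits(params, "metabolic_params"))
  if (any(temp_K <= 0)) stop("temperature must be positive Kelvin")
  if (any(delta_s < 0)) stop("delta_s must be non-negative")
  exp(params$E / (params$k * temp_K)) * delta_s^params$alpha
}

#' Calibrate the developmental-time constant
#'
#' Ordinary least squares of observed developmental times on the
#' temperature-size metabolic term, through the origin by default (the
#' slope *is* the constant of proportionality). Records with rearing
#' temperature and the initial-to-juvenile size gain are required.
#'
#' @param data A data frame of calibration records.
#' @param dt_obs,temp_K,delta_s Column names (bare or string) holding the
#'   observed developmental time (days), rearing temperature (K) and size
#'   gain (mm^3).
#' @param params A [metabolic_params()] object.
#' @param intercept Fit a free intercept instead of forcing the line
#'   through the origin. Default `FALSE`.
#' @return An object of class `dt_calibration`: the updated
#'   `metabolic_params` (with `a0const` set to the slope), the fitted
#'   `lm`, and `r_squared` computed on the observed scale as
#'   `1 - SSres/SStot` about the mean of `dt_obs`.
#' @export
calibrate_dt <- function(data, dt_obs = "DT_obs", temp_K = "temp_K",
                         delta_s = "delta_s", params = metabolic_params(),
                         intercept = FALSE) {
  dt_obs <- data[[rlang::as_name(rlang::enquo(dt_obs))]]
  tK <- data[[rlang::as_name(rlang::enquo(temp_K))]]
  ds <- data[[rlang::as_name(rlang::enquo(delta_s))]]
  if (length(dt_obs) < 3L) stop("calibration needs >= 3 records")
  if (any(dt_obs <= 0)) stop("observed developmental times must be positive")
  x <- metabolic_term(tK, ds, params)
  if (stats::sd(x) == 0 && !intercept && all(x == 0)) {
    stop("degenerate metabolic term: all values zero")
  }
  if (stats::sd(x) == 0 && intercept) stop("degenerate metabolic term: constant")
  fit <- if (intercept) stats::lm(dt_obs ~ x) else stats::lm(dt_obs ~ x + 0)
  slope <- unname(stats::coef(fit)[["x"]])
  if (slope <= 0) stop("calibration produced a non-positive slope")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dt_obs - mean(dt_obs))^2)
  structure(list(
    params = metabolic_params(params$E, params$alpha, a0const = slope),
    fit = fit,
    r_squared = 1 - ss_res / ss_tot,
    n = length(dt_obs)
  ), class = "dt_calibration")
}

#' @export
print.dt_calibration <- function(x, ...) {
  cat("Developmental-time calibration (", x$n, " records)\n", sep = "")
  cat("  slope (a0const):", format(x$params$a0const), "days/mm^0.75\n")
  cat("  R^2            :", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' Developmental time from the calibrated scaling model
#'
#' `DT = a0const * exp(E/(k*T)) * deltaS^alpha` (days). Requires a
#' calibrated `a0const`; developmental time rises with the size gain and
#' falls with temperature.
#'
#' @inheritParams metabolic_term
#' @return Developmental time in days.
#' @export
developmental_time <- function(temp_K, delta_s, params) {
  stopifnot(inherits(params, "metabolic_params"))
  if (is.null(params$a0const)) {
    stop("`params$a0const` is not calibrated; run calibrate_dt() first")
  }
  params$a0const * metabolic_term(temp_K, delta_s, params)
}

#' Embryo (or adult) mass from volume
#'
#' Converts a volume in mm^3 to grams at a density of 1 g/L
#' (= 1e-6 g/mm^3), the literal density used by the fecundity model.
#'
#' @param volume Volume in mm^3 (> 0). Vectorised.
#' @param density_g_per_L Density in g/L; default 1.
#' @return Mass in g.
#' @export
embryo_mass <- function(volume, density_g_per_L = 1) {
  if (any(volume <= 0)) stop("volume must be positive")
  volume * density_g_per_L * 1e-6
}

#' Fecundity from embryo mass, adult mass and temperature
#'
#' Mass-corrected fecundity `Cx = exp(-0.99 * ln(m0) + 19.15)` scaled to a
#' whole female at temperature `T`:
#' `C = Cx * M^0.75 * exp(-E/(k*T))` offspring per female per day.
#'
#' @param m0 Initial embryo mass (g, > 0).
#' @param M Adult mass (g, > 0).
#' @param temp_K Environmental temperature (K, > 0).
#' @param params A [metabolic_params()] object (supplies `E` and `k`).
#' @return Fecundity in offspring female^-1 day^-1.
#' @export
fecundity <- function(m0, M, temp_K, params = metabolic_params()) {
  stopifnot(inherits(params, "metabolic_params"))
  if (any(m0 <= 0) || any(M <= 0)) stop("masses must be positive")
  if (any(temp_K <= 0)) stop("temperature must be positive Kelvin")
  cx <- exp(-0.99 * log(m0) + 19.15)
  cx * M^0.75 * exp(-params$E / (params$k * temp_K))
}

#' Append derived life-history quantities to a species table
#'
#' Takes a species trait table with volumes `IS`, `JS`, `AS` (mm^3) and a
#' per-species mean temperature `T` (deg C), and appends growth ratios,
#' developmental time and fecundity.
#'
#' @param traits Data frame with columns `IS`, `JS`, `AS`, `T`.
#' @param params A calibrated [metabolic_params()] object.
#' @return The input tibble with `Gr1`, `Gr2`, `Gr3`, `DT`, `C` appended.
#'   Species lacking `JS` get `DT = NA` (no imputation).
#' @export
derive_life_history <- function(traits, params) {
  stopifnot(all(c("IS", "JS", "AS", "T") %in% names(traits)))
  tK <- traits$T + 273.15
  out <- dplyr::bind_cols(tibble::as_tibble(traits),
                          growth_ratios(traits$IS, traits$JS, traits$AS))
  ds <- traits$JS - traits$IS
  out$DT <- ifelse(is.na(ds), NA_real_,
                   developmental_time(tK, pmax(ds, 0), params))
  out$C <- fecundity(embryo_mass(traits$IS), embryo_mass(traits$AS), tK, params)
  out
}
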