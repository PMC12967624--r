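#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_sar_lag Coefficient table (including `rho`) as a tidy
#'   tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy sar_fit
#' @export
tidy.sar_fit <- function(x, ...) {
  dplyr::bind_rows(
    x$coefficients,
    tibble::tibble(term = "rho", estimate = x$rho, std_error = x$rho_se,
                   z_value = x$rho / x$rho_se, p_value = x$rho_p_value)
  )
}

#' @describeIn fit_sar_lag One-row model summary.
#' @method glance sar_fit
#' @export
glance.sar_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, rho_p_value = x$rho_p_value,
                 r_squared = x$r_squared, aic = x$aic, aic_ols = x$aic_ols,
                 log_lik = x$log_lik, sigma2 = x$sigma2, n = x$n)
}

#' @describeIn lmm_fit Fixed-effect table as a tidy tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy mixed_fit
#' @export
tidy.mixed_fit <- function(x, ...) x$coefficients

#' @describeIn lmm_fit One-row model summary.
#' @method glance mixed_fit
#' @export
glance.mixed_fit <- function(x, ...) {
  tibble::tibble(group_variance = x$group_variance,
                 resid_variance = x$resid_variance,
                 lrt_p = x$lrt_p, r2_fixed = x$r2_fixed,
                 r2_group = x$r2_group, r2_total = x$r2_total,
                 aic = x$aic, aic_nogroup = x$aic_nogroup)
}

#' @describeIn binomial_glmm Coefficient table as a tidy tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy binomial_fit
#' @export
tidy.binomial_fit <- function(x, ...) x$coefficients

#' @describeIn binomial_glmm One-row model summary.
#' @method glance binomial_fit
#' @export
glance.binomial_fit <- function(x, ...) {
  tibble::tibble(lrt_p = x$lrt_p, aic = x$aic, aic_nogroup = x$aic_nogroup,
                 group_variance = x$group_variance, r_squared = x$r_squared,
                 accuracy_total = x$accuracy_total,
                 accuracy_pelagic = x$accuracy_pelagic,
                 accuracy_nonpelagic = x$accuracy_nonpelagic)
}

#' @describeIn calibrate_dt One-row calibration summary.
#' @param x A fitted object.
#' @param ... Unused.
#' @method glance dt_calibration
#' @export
glance.dt_calibration <- function(x, ...) {
  tibble::tibble(a0const = x$params$a0const, r_squared = x$r_squared, n = x$n)
}

#' @describeIn trait_pca Variance explained per component.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy trait_pca
#' @export
tidy.trait_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$variance_explained)),
                 variance_explained = x$variance_explained,
                 cumulative = cumsum(x$variance_explained))
}

#' @describeIn morans_correlogram Per-bin Moran's I as a tidy tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy correlogram
#' @export
tidy.correlogram <- function(x, ...) x$bins
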