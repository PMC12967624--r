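#' Clipped logit transform of a proportion
#'
#' `log(p/(1-p))` after clipping `p` into `[eps, 1-eps]` so that exact 0s
#' and 1s (common in species-poor pixels) stay finite.
#'
#' @param p Proportions in `[0, 1]`. Vectorised.
#' @param eps Clipping bound (default 1e-3).
#' @return Logits.
#' @export
logit_transform <- function(p, eps = 1e-3) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Great-circle distance matrix (km)
#'
#' Pairwise haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Data frame with columns `lon`, `lat` (degrees).
#' @return Symmetric matrix of distances in km.
#' @export
distance_matrix_km <- function(coords) {
  stopifnot(all(c("lon", "lat") %in% names(coords)))
  m <- as.matrix(coords[, c("lon", "lat")])
  geosphere::distm(m, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371)) # r in km -> result in km
}

#' Screen predictor subsets for collinearity
#'
#' Enumerates subsets of candidate predictors and keeps those where every
#' pairwise Pearson correlation has absolute value below `r_max` and every
#' variance inflation factor is below `vif_max`. Constant columns are
#' excluded up front with a warning.
#'
#' @param data Data frame holding the predictors.
#' @param predictors Character vector of candidate column names.
#' @param r_max Pairwise |Pearson r| threshold (default 0.65).
#' @param vif_max VIF threshold (default 3).
#' @param min_size,max_size Subset size limits.
#' @return Tibble of admissible subsets: `id`, `k` (size), list-column
#'   `predictors`.
#' @export
candidate_screen <- function(data, predictors, r_max = 0.65, vif_max = 3,
                             min_size = 1, max_size = length(predictors)) {
  stopifnot(length(predictors) >= 1, all(predictors %in% names(data)))
  sds <- vapply(data[predictors], stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("excluding constant predictor(s): ",
            paste(predictors[sds == 0], collapse = ", "))
    predictors <- predictors[sds > 0]
  }
  if (!length(predictors)) stop("no non-constant predictors left")
  cm <- stats::cor(data[predictors])
  subsets <- unlist(lapply(seq(min_size, min(max_size, length(predictors))),
                           function(k) utils::combn(predictors, k, simplify = FALSE)),
                    recursive = FALSE)
  keep <- vapply(subsets, function(vs) {
    if (length(vs) >= 2) {
      sub <- cm[vs, vs]
      if (max(abs(sub[upper.tri(sub)])) >= r_max) return(FALSE)
      if (max(vif_values(data, vs)) >= vif_max) return(FALSE)
    }
    TRUE
  }, logical(1))
  adm <- subsets[keep]
  tibble::tibble(id = seq_along(adm),
                 k = lengths(adm),
                 predictors = adm)
}

# Variance inflation factors for a predictor set: 1 / (1 - R^2) of each
# predictor regressed on the others.
vif_values <- function(data, vars) {
  if (length(vars) < 2) return(stats::setNames(rep(1, length(vars)), vars))
  vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = data)
    r2 <- summary(fit)$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
}

#' Moran's I spatial correlogram with patch size
#'
#' Computes Moran's I in successive great-circle distance bins (binary
#' membership weights within each bin) and locates the patch size: the
#' distance at which the correlogram first crosses zero from positive to
#' negative, by linear interpolation between the bracketing bin centres.
#' Under spatial independence the expectation of I is `-1/(n-1)` in every
#' bin.
#'
#' @param data Data frame with `lon`, `lat` and the value column.
#' @param value Column name (string) of the variable.
#' @param bin_width_km Bin width in km (default 50).
#' @param max_dist_km Largest distance considered; defaults to half the
#'   maximum pairwise distance.
#' @return An object of class `correlogram`: list with `bins` (tibble of
#'   `dist_km` bin centres, `morans_i`, `n_pairs`) and `patch_size_km`
#'   (`NA` with a message when no sign change exists).
#' @export
morans_correlogram <- function(data, value, bin_width_km = 50,
                               max_dist_km = NULL) {
  stopifnot(nrow(data) >= 10)
  z <- data[[value]] - mean(data[[value]])
  n <- length(z)
  D <- distance_matrix_km(data)
  if (is.null(max_dist_km)) max_dist_km <- max(D) / 2
  breaks <- seq(0, max_dist_km + bin_width_km, by = bin_width_km)
  denom <- sum(z^2)
  bins <- purrr::map_dfr(seq_len(length(breaks) - 1L), function(b) {
    w <- D > breaks[b] & D <= breaks[b + 1L]
    diag(w) <- FALSE
    s0 <- sum(w)
    i_val <- if (s0 > 0) (n / s0) * sum(w * outer(z, z)) / denom else NA_real_
    tibble::tibble(dist_km = (breaks[b] + breaks[b + 1L]) / 2,
                   morans_i = i_val, n_pairs = s0 / 2)
  }) |>
    dplyr::filter(!is.na(.data$morans_i))
  patch <- NA_real_
  iv <- bins$morans_i
  cross <- which(iv[-length(iv)] > 0 & iv[-1] <= 0)
  if (length(cross)) {
    b <- cross[1]
    x1 <- bins$dist_km[b]; x2 <- bins$dist_km[b + 1]
    y1 <- iv[b]; y2 <- iv[b + 1]
    patch <- x1 + y1 * (x2 - x1) / (y1 - y2)
  } else {
    message("correlogram has no positive-to-negative crossing; patch size NA")
  }
  structure(list(bins = bins, patch_size_km = patch, n = n),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("Moran's I correlogram (", nrow(x$bins), " bins, n = ", x$n, ")\n",
      sep = "")
  cat("  patch size:", if (is.na(x$patch_size_km)) "not reached" else
    paste(round(x$patch_size_km, 1), "km"), "\n")
  invisible(x)
}

#' Inverse-distance spatial weight matrix
#'
#' Neighbour weights `1/d_ij` for pairs closer than the patch size, zero
#' beyond it, rows normalised to sum to one. Points with no neighbour
#' within range get an all-zero row and are recorded in the `isolated`
#' attribute.
#'
#' @param coords Data frame with `lon`, `lat`.
#' @param patch_size_km Neighbourhood radius in km (> 0).
#' @param exponent Distance-decay exponent (default 1, i.e. `1/d`).
#' @return Row-standardised weight matrix with attribute `isolated`.
#' @export
build_weights <- function(coords, patch_size_km, exponent = 1) {
  stopifnot(patch_size_km > 0)
  D <- distance_matrix_km(coords)
  off <- D[upper.tri(D)]
  if (any(off == 0)) stop("coincident points (zero pairwise distance) in coords")
  W <- ifelse(D > 0 & D <= patch_size_km, 1 / D^exponent, 0)
  rs <- rowSums(W)
  isolated <- which(rs == 0)
  if (length(isolated)) {
    warning(length(isolated), " point(s) have no neighbour within ",
            patch_size_km, " km; their weight rows are zero")
  }
  W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(W, "isolated") <- isolated
  W
}

#' Fit a spatial lag (SAR) model by maximum likelihood
#'
#' Fits `y = rho * W y + X beta + eps` by profile maximum likelihood. The
#' log-determinant `log|I - rho W|` is evaluated exactly through the
#' eigenvalues of the (similarity-symmetrised) weight matrix, which is
#' exact at the few-hundred-pixel scale of reliability-filtered maps.
#' `rho` measures spatial autocorrelation (positive: neighbouring pixels
#' alike); its significance comes from a likelihood-ratio test against
#' the `rho = 0` (ordinary least squares) model. The reported R^2 is from
#' an ordinary regression of observed on model-predicted values, with
#' predictions from the reduced form `(I - rho W)^{-1} X beta`.
#'
#' @param data Data frame holding response and predictors.
#' @param formula Model formula, e.g. `logit_np ~ depth + T`.
#' @param W Row-standardised weight matrix from [build_weights()], or
#'   `NULL`/all-zero for a pure OLS fit.
#' @return An object of class `sar_fit` with elements `coefficients`
#'   (tibble: term, estimate, std_error, z_value, p_value), `rho`,
#'   `rho_p_value` (LRT), `sigma2`, `log_lik`, `aic`, `aic_ols`,
#'   `r_squared`, `fitted`, `residuals`, `n`.
#' @export
fit_sar_lag <- function(data, formula, W = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 2) stop("need n > p + 2 observations")
  if (qr(X)$rank < p) stop("singular design matrix")
  if (is.null(W)) W <- matrix(0, n, n)
  stopifnot(nrow(W) == n, ncol(W) == n)

  Wy <- as.vector(W %*% y)
  qx <- qr(X)
  e0 <- qr.resid(qx, y)
  eL <- qr.resid(qx, Wy)

  zero_W <- all(W == 0)
  if (zero_W) {
    eig <- numeric(0)
    rho_hat <- 0
  } else {
    # Row-standardised W built from a symmetric base is similar to a
    # symmetric matrix, so its spectrum is real; imaginary parts are
    # numerical noise.
    eig <- tryCatch({
      ev <- eigen(W, only.values = TRUE)$values
      if (is.complex(ev)) {
        if (max(abs(Im(ev))) > 1e-6) {
          stop("weight matrix has a genuinely complex spectrum")
        }
        Re(ev)
      } else ev
    }, error = function(e) stop("eigendecomposition of W failed: ",
                                conditionMessage(e)))
    lo <- if (min(eig) < 0) 1 / min(eig) + 1e-6 else -0.999
    hi <- if (max(eig) > 0) 1 / max(eig) - 1e-6 else 0.999
    prof <- function(rho) {
      e <- e0 - rho * eL
      s2 <- sum(e^2) / n
      sum(log(1 - rho * eig)) - n / 2 * log(s2)
    }
    opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
    rho_hat <- opt$maximum
  }

  loglik <- function(theta) {
    beta <- theta[seq_len(p)]
    rho <- theta[p + 1L]
    s2 <- theta[p + 2L]
    if (s2 <= 0) return(-Inf)
    e <- (y - rho * Wy) - X %*% beta
    ld <- if (zero_W) 0 else sum(log(pmax(1 - rho * eig, 1e-300)))
    -n / 2 * log(2 * pi * s2) + ld - sum(e^2) / (2 * s2)
  }

  beta_hat <- unname(qr.coef(qx, y - rho_hat * Wy))
  e_hat <- (y - rho_hat * Wy) - X %*% beta_hat
  s2_hat <- sum(e_hat^2) / n
  theta_hat <- c(beta_hat, rho_hat, s2_hat)
  ll <- as.numeric(loglik(theta_hat))

  # Asymptotic standard errors from the numeric Hessian of the full
  # likelihood (beta, rho, sigma2 jointly).
  H <- tryCatch(stats::optimHess(theta_hat, function(t) -loglik(t)),
                error = function(e) NULL)
  se <- rep(NA_real_, p + 1L)
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)[seq_len(p + 1L)]
      se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
  }
  est <- c(beta_hat, rho_hat)
  zv <- est / se
  coefs <- tibble::tibble(
    term = c(colnames(X), "rho"),
    estimate = est,
    std_error = se,
    z_value = zv,
    p_value = 2 * stats::pnorm(-abs(zv))
  )

  # rho = 0 reference fit (OLS) for the LRT and the non-spatial AIC.
  s2_ols <- sum(e0^2) / n
  ll_ols <- -n / 2 * (log(2 * pi * s2_ols) + 1)
  rho_p <- if (zero_W) NA_real_ else
    stats::pchisq(2 * (ll - ll_ols), df = 1, lower.tail = FALSE)

  pred <- if (zero_W || rho_hat == 0) as.vector(X %*% beta_hat) else
    as.vector(solve(diag(n) - rho_hat * W, X %*% beta_hat))
  r2 <- if (stats::sd(pred) == 0) {
    if (all(abs(y - pred) < 1e-12)) 1 else 0
  } else suppressWarnings(summary(stats::lm(y ~ pred))$r.squared)

  structure(list(
    coefficients = coefs[coefs$term != "rho", ],
    rho = rho_hat, rho_se = se[p + 1L], rho_p_value = rho_p,
    sigma2 = s2_hat, log_lik = ll,
    aic = -2 * ll + 2 * (p + 2), aic_ols = -2 * ll_ols + 2 * (p + 1),
    r_squared = r2, fitted = pred, residuals = y - pred,
    observed = y, n = n, formula = formula
  ), class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("Spatial lag (SAR) model:", deparse(x$formula), "\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf("rho = %.4f (LRT p = %s), R^2 = %.4f, AIC = %.2f (OLS AIC = %.2f)\n",
              x$rho, format.pval(x$rho_p_value, digits = 3), x$r_squared,
              x$aic, x$aic_ols))
  invisible(x)
}

#' Select the best spatial model by AIC over admissible predictor subsets
#'
#' Fits a [fit_sar_lag()] model for every admissible predictor subset and
#' returns the minimum-AIC fit; exact AIC ties go to the smaller subset.
#' The per-candidate table also reports the AIC of the non-spatial
#' (`rho = 0`) counterpart.
#'
#' @param data Data frame with response and predictors.
#' @param response Response column name (string).
#' @param candidates A [candidate_screen()] table (or list of character
#'   vectors of predictor names).
#' @param W Spatial weight matrix passed to each fit.
#' @return List with `best` (a `sar_fit`), `best_id`, and `table`
#'   (per-candidate `id`, `predictors`, `k`, `aic`, `aic_ols`,
#'   `r_squared`, `rho`).
#' @export
select_model <- function(data, response, candidates, W = NULL) {
  preds <- if (is.data.frame(candidates)) candidates$predictors else candidates
  if (!length(preds)) stop("no candidate predictor subsets supplied")
  fits <- vector("list", length(preds))
  errs <- character(0)
  for (i in seq_along(preds)) {
    f <- stats::reformulate(preds[[i]], response = response)
    fits[[i]] <- tryCatch(fit_sar_lag(data, f, W), error = function(e) {
      errs <<- c(errs, paste0("candidate ", i, ": ", conditionMessage(e)))
      NULL
    })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate fits failed:\n", paste(errs, collapse = "\n"))
  tab <- tibble::tibble(
    id = seq_along(preds)[ok],
    predictors = preds[ok],
    k = lengths(preds[ok]),
    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
    aic_ols = vapply(fits[ok], `[[`, numeric(1), "aic_ols"),
    r_squared = vapply(fits[ok], `[[`, numeric(1), "r_squared"),
    rho = vapply(fits[ok], `[[`, numeric(1), "rho")
  )
  # min AIC; break exact ties by subset size
  best_row <- order(tab$aic, tab$k)[1]
  list(best = fits[ok][[best_row]], best_id = tab$id[best_row], table = tab)
}
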