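#' Build the standardised trait matrix for multivariate analysis
#'
#' Natural-log transforms and z-scores the continuous life-history traits
#' and expands the categorical traits (developmental mode, diet) into one
#' 0/1 dummy column per level. Dummies are left unscaled.
#'
#' @param records Species data frame; must contain a `species` column,
#'   the continuous traits and the categorical traits.
#' @param continuous Names of continuous trait columns (positive values).
#' @param categorical Names of categorical trait columns.
#' @return Tibble with `species` plus standardised trait and dummy
#'   columns.
#' @export
build_trait_matrix <- function(records,
                               continuous = c("IS", "JS", "AS", "Gr1", "Gr2",
                                              "Gr3", "DT", "C"),
                               categorical = c("mode", "diet")) {
  stopifnot("species" %in% names(records), nrow(records) >= 3)
  continuous <- intersect(continuous, names(records))
  categorical <- intersect(categorical, names(records))
  out <- tibble::tibble(species = records$species)
  for (v in continuous) {
    x <- records[[v]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop("non-positive value of trait `", v, "` for species ",
           records$species[bad[1]])
    }
    if (anyNA(x)) stop("missing value of trait `", v, "`; complete cases required")
    lx <- log(x)
    if (stats::sd(lx) == 0) stop("trait `", v, "` has zero variance after log")
    out[[v]] <- as.vector(scale(lx))
  }
  for (v in categorical) {
    f <- factor(records[[v]])
    for (lev in levels(f)) out[[paste(v, lev, sep = "_")]] <- as.numeric(f == lev)
  }
  out
}

#' Principal component analysis of the trait matrix
#'
#' Eigen-decomposition (via `prcomp`, centred, unscaled: continuous
#' columns are already z-scored) of the trait matrix.
#'
#' @param trait_matrix A [build_trait_matrix()] result (the `species`
#'   column, if present, is carried through to the scores).
#' @return An object of class `trait_pca`: `scores` tibble, `loadings`
#'   matrix (orthonormal columns), `variance_explained` (sums to 1),
#'   `center`.
#' @export
trait_pca <- function(trait_matrix) {
  sp <- if ("species" %in% names(trait_matrix)) trait_matrix$species else NULL
  X <- as.matrix(trait_matrix[setdiff(names(trait_matrix), "species")])
  if (nrow(X) < 3) stop("PCA needs >= 3 rows")
  if (all(apply(X, 2, stats::sd) == 0)) stop("rank-0 matrix: no variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  if (!is.null(sp)) scores <- dplyr::bind_cols(tibble::tibble(species = sp), scores)
  structure(list(scores = scores, loadings = pc$rotation,
                 variance_explained = ve, center = pc$center),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA:", nrow(x$scores), "species,", ncol(x$loadings), "components\n")
  cat("  PC1 + PC2 explain",
      sprintf("%.1f%%", 100 * sum(x$variance_explained[1:2])), "of variance\n")
  invisible(x)
}

#' Linear mixed model with a superfamily random intercept
#'
#' Fits `y ~ predictors + (1 | group)` by maximum likelihood (ML, not
#' REML, so likelihoods are comparable across models differing in random
#' structure), tests the random term with a likelihood-ratio test against
#' the fixed-only linear model, and partitions explained variance:
#' `r2_fixed` = fixed-effect variance over total, `r2_group` = random
#' intercept variance over total, `r2_total` = their sum.
#'
#' @param data Data frame.
#' @param response Response column name (string), e.g. a PC score.
#' @param predictors Character vector of fixed-effect column names.
#' @param group Grouping column name (string), e.g. `"superfamily"`.
#' @return An object of class `mixed_fit`: `coefficients` tibble
#'   (term, estimate, std_error, t_value, p_value), `group_variance`,
#'   `resid_variance`, `lrt_p`, `r2_fixed`, `r2_group`, `r2_total`,
#'   `aic`, `aic_nogroup`, and the underlying `lme4` fit.
#' @export
lmm_fit <- function(data, response, predictors, group) {
  stopifnot(length(unique(data[[group]])) >= 2)
  fml <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "), "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = data, REML = FALSE)
  if (isTRUE(fit@optinfo$conv$lme4$code < 0)) {
    stop("lmer did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  red <- stats::lm(stats::reformulate(predictors, response = response),
                   data = data)
  ll_full <- as.numeric(stats::logLik(fit))
  ll_red <- as.numeric(stats::logLik(red))
  lrt_stat <- max(0, 2 * (ll_full - ll_red))
  lrt_p <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)

  cf <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(cf), estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"], t_value = cf[, "t value"],
    p_value = 2 * stats::pnorm(-abs(cf[, "t value"]))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_g <- vc$vcov[vc$grp == group]
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  tot <- var_f + var_g + var_e
  structure(list(
    coefficients = coefs,
    group_variance = var_g, resid_variance = var_e,
    lrt_stat = lrt_stat, lrt_p = lrt_p,
    r2_fixed = var_f / tot, r2_group = var_g / tot,
    r2_total = (var_f + var_g) / tot,
    aic = stats::AIC(fit), aic_nogroup = stats::AIC(red),
    fit = fit
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Linear mixed model (ML)\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf("group var = %.4f (LRT p = %s); R2 fixed/group/total = %.3f/%.3f/%.3f\n",
              x$group_variance, format.pval(x$lrt_p, digits = 3),
              x$r2_fixed, x$r2_group, x$r2_total))
  cat(sprintf("AIC = %.2f (no-group AIC = %.2f)\n", x$aic, x$aic_nogroup))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' Per-observation weights proportional to the inverse of the class
#' frequency, normalised so the weights sum to the number of
#' observations. With balanced classes every weight is 1.
#'
#' @param y Binary class vector (logical, 0/1, factor or character).
#' @return Numeric weight per observation.
#' @examples
#' class_weights(rep(c(0, 1), c(61, 33)))
#' @export
class_weights <- function(y) {
  f <- factor(y)
  if (nlevels(f) < 2) stop("both classes must be present")
  tab <- table(f)
  w <- as.numeric(length(y) / (nlevels(f) * tab[f]))
  w
}

#' Weighted binomial mixed model of developmental mode
#'
#' Logistic mixed model of a binary developmental-mode outcome (pelagic =
#' 1, non-pelagic = 0) on environmental predictors with a random group
#' (superfamily) intercept, fitted by ML through `glmmTMB`. Class
#' imbalance is handled by inverse-frequency [class_weights()].
#' Significance of the group term comes from a likelihood-ratio test
#' against the same model without it, and AIC is reported for both.
#' Classification accuracy uses a 0.5 probability threshold; per-class
#' accuracy is the recall of that class.
#'
#' @param data Data frame.
#' @param response Binary response column name (string); 0/1 or logical,
#'   1 meaning pelagic.
#' @param predictors Character vector of predictor column names.
#' @param group Grouping column name (string).
#' @param weights Either `TRUE` (compute [class_weights()]), `FALSE`
#'   (unweighted), or a numeric vector.
#' @return An object of class `binomial_fit`: `coefficients` tibble,
#'   `lrt_p`, `aic`, `aic_nogroup`, `group_variance`, `r_squared`
#'   (squared correlation of outcome and fitted probability),
#'   `accuracy_total`, `accuracy_pelagic`, `accuracy_nonpelagic`
#'   (percent), `separation` flag, and the underlying fits.
#' @export
binomial_glmm <- function(data, response, predictors, group, weights = TRUE) {
  y <- as.numeric(data[[response]])
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1 (1 = pelagic)")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(unique(data[[group]])) < 2) stop("need >= 2 groups")
  w <- if (isTRUE(weights)) class_weights(y) else
    if (isFALSE(weights)) rep(1, length(y)) else weights
  dat <- data
  dat$.y <- y
  dat$.w <- w
  fml <- stats::as.formula(paste(
    ".y ~", paste(predictors, collapse = " + "), "+ (1 |", group, ")"))
  fml0 <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  # Weights are prior observation weights, not binomial trial counts; the
  # family code cannot tell the difference, so silence only that warning.
  quiet_fit <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("non-integer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  fit <- quiet_fit(glmmTMB::glmmTMB(fml, data = dat,
                                    family = stats::binomial(), weights = .w))
  fit0 <- quiet_fit(glmmTMB::glmmTMB(fml0, data = dat,
                                     family = stats::binomial(), weights = .w))
  ll <- as.numeric(stats::logLik(fit)); ll0 <- as.numeric(stats::logLik(fit0))
  lrt_stat <- max(0, 2 * (ll - ll0))
  lrt_p <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)

  cf <- summary(fit)$coefficients$cond
  coefs <- tibble::tibble(
    term = rownames(cf), estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    z_value = unname(cf[, "z value"]),
    p_value = unname(cf[, "Pr(>|z|)"])
  )
  separation <- any(abs(coefs$estimate[-1]) > 50) ||
    any(!is.finite(coefs$std_error))
  if (separation) warning("possible complete separation: extreme coefficients")

  prob <- stats::predict(fit, type = "response")
  pred <- as.numeric(prob >= 0.5)
  acc_tot <- mean(pred == y)
  acc_pel <- mean(pred[y == 1] == 1)
  acc_np <- mean(pred[y == 0] == 0)
  vc <- glmmTMB::VarCorr(fit)$cond
  var_g <- if (length(vc)) as.numeric(vc[[1]][1, 1]) else 0

  structure(list(
    coefficients = coefs, lrt_stat = lrt_stat, lrt_p = lrt_p,
    aic = stats::AIC(fit), aic_nogroup = stats::AIC(fit0),
    group_variance = var_g,
    r_squared = stats::cor(y, prob)^2,
    accuracy_total = 100 * acc_tot,
    accuracy_pelagic = 100 * acc_pel,
    accuracy_nonpelagic = 100 * acc_np,
    separation = separation,
    fitted = prob, observed = y, fit = fit, fit_nogroup = fit0
  ), class = "binomial_fit")
}

#' @export
print.binomial_fit <- function(x, ...) {
  cat("Weighted binomial mixed model (pelagic = 1)\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat(sprintf("group var = %.4g (LRT p = %s); AIC = %.2f (no-group AIC = %.2f)\n",
              x$group_variance, format.pval(x$lrt_p, digits = 3),
              x$aic, x$aic_nogroup))
  cat(sprintf("accuracy: %.0f%% total, %.0f%% pelagic, %.0f%% non-pelagic; R2 = %.3f\n",
              x$accuracy_total, x$accuracy_pelagic, x$accuracy_nonpelagic,
              x$r_squared))
  invisible(x)
}
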