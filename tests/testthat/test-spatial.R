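test_that("logit transform clips at eps and is antisymmetric", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(1), log(0.999 / 0.001))
  expect_equal(logit_transform(1), -logit_transform(0))
  p <- seq(0.05, 0.95, 0.05)
  expect_equal(logit_transform(p) + logit_transform(1 - p), rep(0, length(p)))
  expect_error(logit_transform(1.2), "\\[0, 1\\]")
})

test_that("candidate screening rejects collinear subsets", {
  d <- correlated_design(400, r = 0.7, seed = 2)
  d$dup <- d$a
  # duplicated pair: any subset holding both a and dup is rejected
  cand <- candidate_screen(d, c("a", "c", "dup"))
  has_both <- vapply(cand$predictors, function(v)
    all(c("a", "dup") %in% v), logical(1))
  expect_false(any(has_both))
  # planted r = 0.7 pair rejected, orthogonal pairs kept
  cand2 <- candidate_screen(d, c("a", "b", "c"))
  has_ab <- vapply(cand2$predictors, function(v)
    all(c("a", "b") %in% v), logical(1))
  expect_false(any(has_ab))
  expect_true(any(vapply(cand2$predictors, function(v)
    setequal(v, c("a", "c")), logical(1))))
  # near-orthogonal trio passes everywhere (VIF ~ 1)
  set.seed(3)
  o <- tibble::tibble(x = rnorm(500), y = rnorm(500), z = rnorm(500))
  expect_equal(nrow(candidate_screen(o, c("x", "y", "z"))), 7)
  expect_warning(candidate_screen(dplyr::mutate(o, k = 1), c("x", "k")),
                 "constant")
})

test_that("correlogram Moran's I matches the brute-force double sum", {
  set.seed(8)
  n <- 40
  pts <- tibble::tibble(lon = runif(n, 0, 3), lat = runif(n, 40, 43),
                        z = rnorm(n))
  cg <- morans_correlogram(pts, "z", bin_width_km = 60, max_dist_km = 240)
  D <- distance_matrix_km(pts)
  for (b in seq_len(nrow(cg$bins))) {
    lo <- cg$bins$dist_km[b] - 30; hi <- cg$bins$dist_km[b] + 30
    W <- (D > lo & D <= hi) * 1; diag(W) <- 0
    if (sum(W) == 0) next
    expect_equal(cg$bins$morans_i[b], brute_moran(pts$z, W), tolerance = 1e-10)
  }
})

test_that("correlogram recovers structure and the null expectation", {
  # iid noise: every bin near -1/(n-1)
  set.seed(12)
  n <- 120
  reps <- replicate(30, {
    pts <- tibble::tibble(lon = runif(n, 0, 3), lat = runif(n, 40, 43),
                          z = rnorm(n))
    cg <- suppressMessages(morans_correlogram(pts, "z", bin_width_km = 80,
                                              max_dist_km = 160))
    cg$bins$morans_i[1:2]
  })
  expect_equal(rowMeans(reps), rep(-1 / (n - 1), 2), tolerance = 0.015)
  # periodic field along a meridian: I(d) ~ cos(2 pi d / L), crossing at L/4
  L <- 800
  lat_km <- seq(0, 1600, by = 20)
  pts2 <- tibble::tibble(lon = 0, lat = 40 + lat_km / 111.19466,
                         z = cos(2 * pi * lat_km / L))
  cg2 <- morans_correlogram(pts2, "z", bin_width_km = 50, max_dist_km = 700)
  expect_gt(cg2$bins$morans_i[1], 0)
  expect_lt(abs(cg2$patch_size_km - L / 4), 50)
})

test_that("weight matrices are inverse-distance, truncated, row-standardised", {
  # 3 collinear equidistant points along a meridian, spacing ~111.19 km
  pts <- tibble::tibble(lon = 0, lat = c(40, 41, 42))
  D <- distance_matrix_km(pts)
  d1 <- D[1, 2]; d2 <- D[1, 3]
  W <- build_weights(pts, patch_size_km = 2 * d2)
  expect_equal(rowSums(W), rep(1, 3))
  expect_equal(W[1, 2], (1 / d1) / (1 / d1 + 1 / d2))
  expect_equal(W[2, 1], 0.5)
  # truncation beyond the patch size
  Wt <- build_weights(pts, patch_size_km = d1 + 1)
  expect_equal(Wt[1, 3], 0)
  expect_warning(W0 <- build_weights(pts, patch_size_km = 10), "no neighbour")
  expect_true(all(W0 == 0))
  expect_error(build_weights(tibble::tibble(lon = c(0, 0), lat = c(40, 40)), 100),
               "coincident")
})

test_that("SAR at rho = 0 collapses to ordinary least squares", {
  sim <- sar_sim(n = 120, rho = 0, beta = c(1, 2, -1), seed = 31)
  fit <- fit_sar_lag(sim$data, y ~ x1 + x2, sim$W)
  ols <- lm(y ~ x1 + x2, data = sim$data)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 0.1)
  expect_lt(abs(fit$rho), 0.15)
  # with W = 0 the ML fit is exactly OLS and the likelihoods coincide
  fit0 <- fit_sar_lag(sim$data, y ~ x1 + x2, W = NULL)
  expect_equal(fit0$coefficients$estimate, unname(coef(ols)), tolerance = 1e-9)
  expect_equal(fit0$aic - 2 * (3 + 2), fit0$aic_ols - 2 * (3 + 1),
               tolerance = 1e-9)
})

test_that("SAR recovers a planted positive rho", {
  sim <- sar_sim(n = 150, rho = 0.4, beta = c(1, 2, -1), seed = 7)
  fit <- fit_sar_lag(sim$data, y ~ x1 + x2, sim$W)
  expect_lt(abs(fit$rho - 0.4), 2.5 * fit$rho_se)
  expect_lt(fit$rho_p_value, 0.05)
  expect_lt(fit$aic, fit$aic_ols)
  expect_gt(fit$r_squared, 0.5)
})

test_that("a perfect non-spatial fit yields R^2 = 1", {
  d <- tibble::tibble(x1 = 1:30, y = 3 + 2 * (1:30))
  fit <- fit_sar_lag(d, y ~ x1, W = NULL)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_sar_lag(dplyr::mutate(d, x2 = x1), y ~ x1 + x2, NULL),
               "singular")
})

test_that("model selection minimises AIC and prefers smaller ties", {
  set.seed(17)
  n <- 150
  d <- tibble::tibble(lon = runif(n, 0, 3), lat = runif(n, 40, 43),
                      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 1 + 2 * d$x1 - 1.5 * d$x2 + rnorm(n, 0, 0.5)
  cand <- candidate_screen(d, c("x1", "x2", "x3"))
  sel <- select_model(d, "y", cand, W = NULL)
  best_vars <- sel$table$predictors[sel$table$aic == min(sel$table$aic)][[1]]
  expect_true(setequal(best_vars, c("x1", "x2")))
  # single candidate returned trivially
  one <- select_model(d, "y", list("x1"), W = NULL)
  expect_equal(one$best_id, 1)
  # exact tie broken toward the smaller subset
  tied <- tibble::tibble(id = 1:2, k = c(2, 1),
                         aic = c(10, 10), aic_ols = c(10, 10))
  expect_equal(order(tied$aic, tied$k)[1], 2)
})
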