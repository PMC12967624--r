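fake_species <- function(n = 60, group_sd = 0, seed = 1) {
  set.seed(seed)
  mode <- sample(c("non_pelagic", "planktotrophic", "lecithotrophic"), n,
                 replace = TRUE, prob = c(0.35, 0.55, 0.10))
  IS <- rlnorm(n, ifelse(mode == "non_pelagic", log(0.05), log(1e-4)), 0.8)
  JS <- IS * pmax(rlnorm(n, ifelse(mode == "planktotrophic", log(100), log(6)),
                         0.4), 1.1)
  AS <- JS * rlnorm(n, log(1e4), 0.8)
  tibble::tibble(
    species = sprintf("sp%02d", seq_len(n)),
    superfamily = paste0("SF", sample.int(6, n, replace = TRUE)),
    mode = mode,
    diet = sample(c("carnivore", "herbivore"), n, replace = TRUE),
    IS = IS, JS = JS, AS = AS,
    DT = rlnorm(n, ifelse(mode == "lecithotrophic", log(20), log(100)), 0.4),
    C = rlnorm(n, log(1e4), 1),
    depth = runif(n, 10, 800),
    M_CHLA = runif(n, 0.1, 0.3)
  )
}

test_that("trait matrix standardises logs and expands dummies", {
  rec <- tibble::tibble(species = c("a", "b", "c"),
                        IS = c(1, 10, 100), JS = c(2, 20, 200),
                        mode = c("non_pelagic", "planktotrophic",
                                 "planktotrophic"))
  tm <- build_trait_matrix(rec, continuous = c("IS", "JS"),
                           categorical = "mode")
  expect_equal(tm$IS, as.vector(scale(log(c(1, 10, 100)))))
  expect_equal(mean(tm$JS), 0, tolerance = 1e-12)
  expect_equal(sd(tm$JS), 1, tolerance = 1e-12)
  expect_equal(tm$mode_non_pelagic, c(1, 0, 0))
  expect_equal(tm$mode_planktotrophic, c(0, 1, 1))
  expect_error(build_trait_matrix(
    tibble::tibble(species = c("a", "b", "c"), IS = c(1, -2, 3)),
    continuous = "IS", categorical = character(0)), "b")
  expect_error(build_trait_matrix(
    tibble::tibble(species = c("a", "b", "c"), IS = c(2, 2, 2)),
    continuous = "IS", categorical = character(0)), "zero variance")
})

test_that("PCA is orthonormal, complete, and reconstructs the data", {
  tm <- build_trait_matrix(fake_species(40),
                           continuous = c("IS", "JS", "AS", "DT", "C"),
                           categorical = c("mode", "diet"))
  pc <- trait_pca(tm)
  expect_equal(sum(pc$variance_explained), 1, tolerance = 1e-12)
  L <- pc$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-9,
               ignore_attr = TRUE)
  X <- as.matrix(tm[setdiff(names(tm), "species")])
  Xc <- sweep(X, 2, pc$center)
  S <- as.matrix(pc$scores[setdiff(names(pc$scores), "species")])
  expect_equal(S %*% t(L), Xc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA separates planted developmental-mode structure", {
  sp <- fake_species(80, seed = 5)
  tm <- build_trait_matrix(sp, continuous = c("IS", "JS", "DT"),
                           categorical = character(0))
  pc <- trait_pca(tm)
  np <- sp$mode == "non_pelagic"
  tt <- t.test(pc$scores$PC1[np], pc$scores$PC1[!np])
  expect_lt(tt$p.value, 0.01)
})

test_that("mixed model partitions variance and tests the group term", {
  set.seed(23)
  n_g <- 12; n_per <- 12
  g <- rep(paste0("SF", 1:n_g), each = n_per)
  x <- rnorm(n_g * n_per)
  # planted group sd twice the residual sd
  b_g <- rnorm(n_g, 0, 2)
  y <- 1 + 0.8 * x + b_g[as.integer(factor(g))] + rnorm(n_g * n_per, 0, 1)
  d <- tibble::tibble(y = y, x = x, superfamily = g)
  fit <- lmm_fit(d, "y", "x", "superfamily")
  expect_lt(fit$lrt_p, 1e-6)
  expect_gt(fit$group_variance, 1)   # true 4, generous bracket
  expect_lt(fit$group_variance, 12)
  expect_gte(fit$r2_total, fit$r2_fixed)
  expect_equal(fit$r2_total - fit$r2_fixed, fit$r2_group, tolerance = 1e-12)
  expect_lt(fit$aic, fit$aic_nogroup)
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  se <- fit$coefficients$std_error[fit$coefficients$term == "x"]
  expect_lt(abs(est - 0.8), 2.5 * se)
})

test_that("absent group effects are not spuriously detected", {
  set.seed(31)
  hits <- replicate(20, {
    n <- 120
    d <- tibble::tibble(x = rnorm(n),
                        superfamily = paste0("SF", sample.int(8, n, TRUE)))
    d$y <- 1 + 0.5 * d$x + rnorm(n)
    suppressMessages(lmm_fit(d, "y", "x", "superfamily"))$lrt_p < 0.05
  })
  expect_lte(mean(hits), 0.10)
})

test_that("class weights are inverse-frequency and sum to n", {
  expect_equal(class_weights(rep(c(0, 1), 25)), rep(1, 50))
  w <- class_weights(rep(c(0, 1), c(61, 33)))
  expect_equal(unique(w[rep(c(0, 1), c(61, 33)) == 1]), 94 / (2 * 33))
  expect_equal(unique(w[rep(c(0, 1), c(61, 33)) == 0]), 94 / (2 * 61))
  expect_equal(sum(w), 94)
  set.seed(2)
  y <- rbinom(77, 1, 0.3)
  expect_equal(sum(class_weights(y)), 77)
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("binomial mixed model recovers planted effects and accuracies", {
  set.seed(41)
  n <- 400
  d <- tibble::tibble(
    depth = c(runif(0.75 * n, 10, 160), runif(0.25 * n, 300, 1200)),
    M_CHLA = runif(n, 0.1, 0.3),
    superfamily = paste0("SF", sample.int(8, n, TRUE)))
  eta <- 3.4 - 0.0047 * d$depth - 14.2 * d$M_CHLA
  d$pelagic <- rbinom(n, 1, plogis(eta))
  fit <- binomial_glmm(d, "pelagic", c("depth", "M_CHLA"), "superfamily")
  cf <- fit$coefficients
  expect_lt(cf$estimate[cf$term == "depth"], 0)
  expect_lt(cf$estimate[cf$term == "M_CHLA"], 0)
  expect_lt(abs(cf$estimate[cf$term == "depth"] + 0.0047),
            2.5 * cf$std_error[cf$term == "depth"])
  # accuracy decomposition: total = frequency-weighted mean of class recalls
  p1 <- mean(d$pelagic)
  expect_equal(fit$accuracy_total,
               p1 * fit$accuracy_pelagic + (1 - p1) * fit$accuracy_nonpelagic,
               tolerance = 1e-9)
  # nested deviances: the group model can never fit worse
  expect_gte(fit$lrt_stat, 0)
})

test_that("separable data are classified perfectly and flagged", {
  set.seed(6)
  n <- 80
  d <- tibble::tibble(x = c(rnorm(n / 2, -4), rnorm(n / 2, 4)),
                      superfamily = paste0("SF", sample.int(4, n, TRUE)))
  d$y <- as.numeric(d$x > 0)
  fit <- suppressWarnings(binomial_glmm(d, "y", "x", "superfamily"))
  expect_equal(fit$accuracy_total, 100)
  expect_equal(fit$accuracy_pelagic, 100)
  expect_equal(fit$accuracy_nonpelagic, 100)
})
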