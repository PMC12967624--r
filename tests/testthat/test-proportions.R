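mini_grid <- function(n = 4) {
  g <- tidyr::expand_grid(lat = 40 + seq_len(n) - 0.5, lon = c(0.5, 1.5))
  g$depth <- 50
  attr(g, "resolution") <- 1
  g
}

test_that("stacked proportions count modes per pixel", {
  g <- mini_grid()
  n <- nrow(g)
  m1 <- rep(TRUE, n)                       # everywhere
  m2 <- g$lat < 42                         # south only
  pm <- stack_proportions(g, list(m1, m2, m2, m1),
                          c("non_pelagic", "planktotrophic",
                            "planktotrophic", "non_pelagic"))
  south <- pm$lat < 42
  expect_equal(unique(pm$richness[south]), 4L)
  expect_equal(unique(pm$prop_np[south]), 0.5)
  expect_equal(unique(pm$prop_pt[south]), 0.5)
  expect_equal(unique(pm$prop_np[!south]), 1)
  occ <- pm$richness > 0
  expect_true(all(abs(pm$prop_np + pm$prop_pt + pm$prop_lc - 1)[occ] < 1e-9))
  expect_error(stack_proportions(g, list(m1), NA_character_), "without a")
})

test_that("minimum reliable species count follows the power formula", {
  expect_identical(n_min(0.351, 0.30), 20L)
  expect_identical(n_min(0.5, 0.5), 8L)
  expect_identical(n_min(0, 0.3), 0L)
  expect_identical(n_min(1, 0.3), 0L)
  # maximised at p = 0.5, non-increasing in delta_p
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_equal(ps[which.max(vapply(ps, n_min, integer(1), delta_p = 0.2))], 0.5)
  expect_true(all(diff(vapply(c(0.1, 0.2, 0.3, 0.5), function(d)
    n_min(0.351, d), integer(1))) <= 0))
  expect_error(n_min(0.3, 0), "positive")
})

test_that("chao1 matches its defining formula and conventions", {
  expect_equal(chao1(10, 0, 0), 10)
  expect_equal(chao1(10, 4, 2), 14)
  expect_equal(chao1(5, 3, 0), 8)
  expect_equal(chao1(10, 4, 2, bias_corrected = TRUE), 12)
  expect_error(chao1(3, 4, 1), "s_obs")
  expect_error(chao1(5, -1, 0), "non-negative")
})

test_that("chao1 agrees with brute-force frequency counting", {
  set.seed(21)
  for (i in 1:100) {
    abund <- rpois(sample(5:40, 1), lambda = runif(1, 0.5, 3))
    abund <- abund[abund > 0]
    if (!length(abund)) next
    s <- length(abund); f1 <- sum(abund == 1); f2 <- sum(abund == 2)
    manual <- if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
    expect_equal(chao1(s, f1, f2), manual)
    expect_gte(chao1(s, f1, f2), s)
    if (f1 == 0) expect_equal(chao1(s, f1, f2), s)
  }
})

test_that("occurrence binning produces consistent survey summaries", {
  occ <- tibble::tibble(
    species = c("a", "a", "b", "c", "c", "c", "d", "e"),
    lat = c(rep(40.1, 6), 40.7, 40.7),
    lon = 0.2)
  os <- occurrence_summary(occ, resolution = 0.5)
  expect_equal(nrow(os), 2)
  p1 <- os[os$lat == 40.25, ]
  expect_equal(p1$s_obs, 3)          # a, b, c
  expect_equal(p1$f1, 1)             # b
  expect_equal(p1$f2, 1)             # a
  expect_equal(p1$chao1, 3 + 1 / 2)
  expect_true(all(os$f1 + 2 * os$f2 <= os$n_records))
  expect_true(all(os$chao1 >= os$s_obs))
  expect_true(all(os$rel_chao >= 1))
  # Darwin-Core column names accepted
  occ_dc <- dplyr::rename(occ, decimalLatitude = lat, decimalLongitude = lon)
  expect_equal(occurrence_summary(occ_dc), os)
})

test_that("reliability mask applies both filters with strict thresholds", {
  g <- mini_grid()
  pm <- stack_proportions(g, list(rep(TRUE, nrow(g))), "non_pelagic")
  pm$richness <- c(19L, 20L, 25L, 25L, 25L, 25L, 25L, 25L)
  occ_sum <- tibble::tibble(lon = rep(c(0.25, 1.25), 4),
                            lat = rep(40.25 + 0:3, each = 2),
                            n_records = 50, s_obs = 10,
                            f1 = 0, f2 = 2,
                            chao1 = 10 * c(1, 1.5, 1.19, 1.2, 1, 1, 1, 1)) |>
    dplyr::mutate(rel_chao = chao1 / s_obs)
  rm <- reliability_mask(pm, occ_sum, nmin = 20, survey_resolution = 1)
  expect_equal(rm$passes_nmin, pm$richness >= 20)
  expect_equal(rm$passes_survey, c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(rm$passes, rm$passes_nmin & rm$passes_survey)
  # unsurveyed pixels fail
  rm2 <- reliability_mask(pm, occ_sum[-1, ], nmin = 20, survey_resolution = 1)
  expect_false(rm2$passes_survey[1])
})

test_that("band methods agree on a homogeneous world and diverge when planted", {
  g <- mini_grid(45)  # lats 40.5 .. 84.5 -> restrict bands below
  g <- g[g$lat < 70 & g$lat > 45, ]
  attr(g, "resolution") <- 1
  n <- nrow(g)
  dists <- list(rep(TRUE, n), rep(TRUE, n), rep(TRUE, n))
  modes <- c("non_pelagic", "planktotrophic", "planktotrophic")
  pm <- stack_proportions(g, dists, modes)
  bands <- seq(45, 70, 5)
  pooled <- band_summary(pm, "pooled", dists = dists, modes = modes, bands = bands)
  pxm <- band_summary(pm, "pixel_mean", bands = bands)
  expect_equal(pooled$proportion, pxm$proportion, tolerance = 1e-12)
  expect_true(all(abs(tapply(pooled$proportion, pooled$band_lower, sum) - 1) < 1e-9))

  # one all-non-pelagic pixel among many pelagic-only pixels:
  # pooled says 50/50 species, pixel_mean is dominated by the many pixels
  g2 <- mini_grid(5)
  n2 <- nrow(g2)
  np_only <- seq_len(n2) == 1
  pt_all <- !np_only
  pm2 <- stack_proportions(g2, list(np_only, pt_all),
                           c("non_pelagic", "planktotrophic"))
  b2 <- band_summary(pm2, "pooled", dists = list(np_only, pt_all),
                     modes = c("non_pelagic", "planktotrophic"),
                     bands = c(40, 45))
  expect_equal(b2$proportion[b2$mode == "non_pelagic"], 0.5)
  b2px <- band_summary(pm2, "pixel_mean", bands = c(40, 45))
  expect_equal(b2px$proportion[b2px$mode == "non_pelagic"], 1 / n2)

  # empty bands are reported as NA, not dropped
  b3 <- band_summary(pm2, "pixel_mean", bands = c(40, 45, 50))
  expect_equal(sum(is.na(b3$proportion)), 3)
  expect_equal(nrow(b3), 6)
})

test_that("permutation test is exact in its degenerate limits", {
  pool <- rep(c(TRUE, FALSE), c(33, 61))
  set.seed(10)
  expect_equal(proportion_permutation_test(94, 33 / 94, pool), 1)
  # observed equal to the reference: every permutation is at least as extreme
  expect_equal(proportion_permutation_test(20, mean(pool), pool), 1)
  # grossly deviant pixel: all species non-pelagic
  expect_lt(proportion_permutation_test(20, 1, pool, n_perm = 200), 0.05)
  expect_error(proportion_permutation_test(5, 0.5, pool, n_perm = 0), "n_perm")
})

test_that("mann_kendall flags monotone series and passes flat ones", {
  expect_lt(mann_kendall(c(1, 2, 3, 5, 8, 9, 11, 14, 15))$p_value, 0.01)
  expect_equal(mann_kendall(c(1, 2, 3, 5, 8, 9, 11, 14, 15))$tau, 1)
  set.seed(2)
  expect_gt(mann_kendall(rnorm(9))$p_value, 0.05)
  expect_true(is.na(mann_kendall(c(1, 2, NA))$tau))
})
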