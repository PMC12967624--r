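#' Stack species distributions into richness and mode-proportion maps
#'
#' Adds per-species presence masks into a per-pixel species count and,
#' separately per developmental mode, into per-pixel mode counts; the
#' proportion of each mode is its count over the pixel richness.
#' Proportions are `NA` where richness is zero.
#'
#' @param grid Pixel tibble (`lon`, `lat`, ...).
#' @param dists List of `potential_distribution` objects or logical masks,
#'   one per species, all aligned to `grid`.
#' @param modes Character vector of developmental modes, one per species:
#'   `"non_pelagic"`, `"planktotrophic"` or `"lecithotrophic"`.
#' @return A `proportion_map`: the grid tibble with `richness`, `n_np`,
#'   `n_pt`, `n_lc`, `prop_np`, `prop_pt`, `prop_lc` appended.
#' @export
stack_proportions <- function(grid, dists, modes) {
  if (length(dists) != length(modes)) stop("one mode per distribution required")
  if (any(is.na(modes))) {
    stop("species without a developmental mode at position(s): ",
         paste(which(is.na(modes)), collapse = ", "))
  }
  modes <- match.arg(modes, c("non_pelagic", "planktotrophic", "lecithotrophic"),
                     several.ok = TRUE)
  masks <- lapply(dists, function(d) {
    m <- if (inherits(d, "potential_distribution")) d$mask else d
    stopifnot(is.logical(m), length(m) == nrow(grid))
    m
  })
  mm <- matrix(unlist(masks), nrow = nrow(grid))
  out <- tibble::as_tibble(grid)
  out$richness <- as.integer(rowSums(mm))
  out$n_np <- as.integer(rowSums(mm[, modes == "non_pelagic", drop = FALSE]))
  out$n_pt <- as.integer(rowSums(mm[, modes == "planktotrophic", drop = FALSE]))
  out$n_lc <- as.integer(rowSums(mm[, modes == "lecithotrophic", drop = FALSE]))
  r <- ifelse(out$richness > 0, out$richness, NA_integer_)
  out$prop_np <- out$n_np / r
  out$prop_pt <- out$n_pt / r
  out$prop_lc <- out$n_lc / r
  attr(out, "resolution") <- attr(grid, "resolution")
  class(out) <- c("proportion_map", class(out))
  out
}

#' Minimum species count for a reliable pixel proportion
#'
#' Normal-approximation sample size needed to detect an absolute deviation
#' `delta_p` from a reference proportion `p` with the stated power at a
#' two-sided significance level:
#' `ceil(((z_{1-alpha/2} + z_{power}) / delta_p)^2 * p * (1 - p))`.
#' Pixels holding fewer species than this cannot support a trustworthy
#' mode proportion.
#'
#' @param p Reference proportion (0 < p < 1; degenerate 0/1 returns 0).
#' @param delta_p Detectable absolute deviation in proportion (> 0).
#' @param alpha Two-sided significance level.
#' @param power Desired statistical power.
#' @return Integer minimum species count.
#' @examples
#' n_min(0.351, 0.30) # 20
#' @export
n_min <- function(p, delta_p, alpha = 0.05, power = 0.8) {
  stopifnot(p >= 0, p <= 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (delta_p <= 0) stop("`delta_p` must be positive")
  if (p == 0 || p == 1) return(0L)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling((z / delta_p)^2 * p * (1 - p)))
}

#' Chao1 richness estimate
#'
#' Nonparametric lower bound on true richness from singleton and doubleton
#' frequencies: `S_obs + f1^2 / (2 f2)` when doubletons exist, with the
#' classic fallback `S_obs + f1 (f1 - 1) / 2` when `f2 = 0`. The
#' bias-corrected variant `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` is
#' available via `bias_corrected = TRUE`.
#'
#' @param s_obs Observed species count (vectorised).
#' @param f1 Number of species observed exactly once.
#' @param f2 Number of species observed exactly twice.
#' @param bias_corrected Use the bias-corrected form throughout.
#' @return Numeric estimate(s), always `>= s_obs`.
#' @export
chao1 <- function(s_obs, f1, f2, bias_corrected = FALSE) {
  if (any(c(s_obs, f1, f2) < 0)) stop("counts must be non-negative")
  if (any(s_obs < f1 + f2)) stop("s_obs must be >= f1 + f2")
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    ifelse(f2 > 0, s_obs + f1^2 / (2 * f2), s_obs + f1 * (f1 - 1) / 2)
  }
}

#' Bin occurrence records into a survey-effort summary
#'
#' Bins individual occurrence records into pixels of the given resolution
#' and computes, per pixel, the observed species count `s_obs`, singleton
#' and doubleton frequencies `f1`/`f2`, the [chao1()] estimate, and the
#' relative Chao index `rel_chao = chao1 / s_obs` (survey completeness:
#' values near 1 indicate a complete inventory).
#'
#' @param occurrences Data frame with columns `species`, `lat`, `lon`
#'   (Darwin-Core `decimalLatitude`/`decimalLongitude` also accepted).
#' @param resolution Pixel size in degrees (default 0.5).
#' @return Tibble with one row per occupied pixel: `lon`, `lat` (cell
#'   centres), `n_records`, `s_obs`, `f1`, `f2`, `chao1`, `rel_chao`.
#' @export
occurrence_summary <- function(occurrences, resolution = 0.5) {
  occ <- tibble::as_tibble(occurrences)
  if (!"lat" %in% names(occ) && "decimalLatitude" %in% names(occ)) {
    occ$lat <- occ$decimalLatitude
  }
  if (!"lon" %in% names(occ) && "decimalLongitude" %in% names(occ)) {
    occ$lon <- occ$decimalLongitude
  }
  stopifnot(all(c("species", "lat", "lon") %in% names(occ)))
  occ |>
    dplyr::mutate(
      lon = floor(.data$lon / resolution) * resolution + resolution / 2,
      lat = floor(.data$lat / resolution) * resolution + resolution / 2
    ) |>
    dplyr::count(.data$lon, .data$lat, .data$species, name = "k") |>
    dplyr::group_by(.data$lon, .data$lat) |>
    dplyr::summarise(
      n_records = sum(.data$k),
      s_obs = dplyr::n(),
      f1 = sum(.data$k == 1L),
      f2 = sum(.data$k == 2L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      chao1 = chao1(.data$s_obs, .data$f1, .data$f2),
      rel_chao = .data$chao1 / .data$s_obs
    )
}

#' Reliability flags for a proportion map
#'
#' Flags each proportion-map pixel by the two reliability criteria: the
#' modelled richness must reach `nmin` species (`passes_nmin`), and the
#' enclosing survey pixel must be well inventoried, i.e. relative Chao
#' below `rel_chao_threshold` (`passes_survey`). Pixels with no
#' occurrence records fail the survey test. `passes` is the conjunction.
#'
#' @param prop_map A [stack_proportions()] result.
#' @param occ_summary An [occurrence_summary()] table (at
#'   `survey_resolution`).
#' @param nmin Minimum modelled richness, typically from [n_min()].
#' @param rel_chao_threshold Survey-completeness cut-off (default 1.2).
#' @param survey_resolution Resolution (degrees) at which `occ_summary`
#'   was binned (default 0.5).
#' @return `prop_map` with `rel_chao`, `passes_survey`, `passes_nmin`,
#'   `passes` appended.
#' @export
reliability_mask <- function(prop_map, occ_summary, nmin,
                             rel_chao_threshold = 1.2,
                             survey_resolution = 0.5) {
  key <- function(x, res) floor(x / res) * res + res / 2
  occ <- occ_summary |>
    dplyr::transmute(.slon = key(.data$lon, survey_resolution),
                     .slat = key(.data$lat, survey_resolution),
                     rel_chao = .data$rel_chao)
  out <- prop_map |>
    dplyr::mutate(.slon = key(.data$lon, survey_resolution),
                  .slat = key(.data$lat, survey_resolution)) |>
    dplyr::left_join(occ, by = c(".slon", ".slat")) |>
    dplyr::select(-".slon", -".slat") |>
    dplyr::mutate(
      passes_survey = !is.na(.data$rel_chao) &
        .data$rel_chao < rel_chao_threshold,
      passes_nmin = .data$richness >= nmin,
      passes = .data$passes_survey & .data$passes_nmin
    )
  attr(out, "resolution") <- attr(prop_map, "resolution")
  class(out) <- unique(c("proportion_map", class(out)))
  out
}

#' Latitudinal band summaries of developmental-mode proportions
#'
#' Summarises mode proportions in latitudinal bands with the three
#' methodologies, in ascending order of reliability:
#' \describe{
#'   \item{`pooled`}{one proportion per band from the set of species
#'     present anywhere in the band (presence/absence pooling);
#'     per-band proportions sum to 1.}
#'   \item{`pixel_mean`}{mean and sd of per-pixel proportions over all
#'     occupied pixels in the band.}
#'   \item{`filtered`}{as `pixel_mean`, restricted to pixels passing the
#'     [reliability_mask()] flags (minimum richness and survey
#'     completeness).}
#' }
#' Bands with no qualifying pixels (or species) are reported with `NA`
#' values rather than dropped.
#'
#' @param prop_map A [stack_proportions()] result; for `filtered` it must
#'   carry the reliability columns from [reliability_mask()].
#' @param method One of `"pooled"`, `"pixel_mean"`, `"filtered"`.
#' @param dists,modes Needed for `pooled` only: the per-species masks and
#'   modes used to build the map.
#' @param bands Band edges in degrees latitude (default `seq(25, 70, 5)`).
#' @return Tibble with columns `band_lower`, `band_mid`, `mode`,
#'   `proportion`, `sd`, `n` (species for `pooled`, pixels otherwise).
#' @export
band_summary <- function(prop_map, method = c("pooled", "pixel_mean", "filtered"),
                         dists = NULL, modes = NULL,
                         bands = seq(25, 70, by = 5)) {
  method <- match.arg(method)
  lower <- bands[-length(bands)]
  upper <- bands[-1]
  mode_levels <- c("non_pelagic", "planktotrophic", "lecithotrophic")

  if (method == "pooled") {
    if (is.null(dists) || is.null(modes)) {
      stop("method 'pooled' needs per-species `dists` and `modes`")
    }
    masks <- lapply(dists, function(d)
      if (inherits(d, "potential_distribution")) d$mask else d)
    rows <- purrr::map2_dfr(lower, upper, function(lo, hi) {
      in_band <- prop_map$lat >= lo & prop_map$lat < hi
      present <- vapply(masks, function(m) any(m & in_band), logical(1))
      n_sp <- sum(present)
      props <- if (n_sp > 0) {
        as.numeric(table(factor(modes[present], levels = mode_levels))) / n_sp
      } else rep(NA_real_, 3)
      tibble::tibble(band_lower = lo, band_mid = (lo + hi) / 2,
                     mode = mode_levels, proportion = props,
                     sd = NA_real_, n = n_sp)
    })
    return(rows)
  }

  if (method == "filtered") {
    if (!"passes" %in% names(prop_map)) {
      stop("method 'filtered' needs reliability flags; run reliability_mask()")
    }
  }
  purrr::map2_dfr(lower, upper, function(lo, hi) {
    px <- prop_map[prop_map$lat >= lo & prop_map$lat < hi &
                     prop_map$richness > 0, ]
    if (method == "filtered") px <- px[px$passes, ]
    cols <- c(non_pelagic = "prop_np", planktotrophic = "prop_pt",
              lecithotrophic = "prop_lc")
    tibble::tibble(
      band_lower = lo, band_mid = (lo + hi) / 2, mode = mode_levels,
      proportion = vapply(cols, function(cc)
        if (nrow(px)) mean(px[[cc]]) else NA_real_, numeric(1),
        USE.NAMES = FALSE),
      sd = vapply(cols, function(cc)
        if (nrow(px) > 1) stats::sd(px[[cc]]) else NA_real_, numeric(1),
        USE.NAMES = FALSE),
      n = nrow(px)
    )
  })
}

#' Permutation test for a pixel's mode proportion
#'
#' Tests whether the non-pelagic proportion observed among the species of
#' a pixel deviates from the reference proportion of the full species
#' pool. Null pixels are assembled by drawing the same number of species
#' from the pool without replacement; the two-sided p-value is the
#' fraction of permuted proportions at least as far from the reference as
#' the observed one (ties count as extreme).
#'
#' @param n_species Number of species in the pixel.
#' @param observed_prop Observed non-pelagic proportion in the pixel.
#' @param pool_modes Logical vector over the species pool (`TRUE` =
#'   non-pelagic), or a character vector of modes.
#' @param n_perm Number of permutations (default 100).
#' @param reference Reference proportion; defaults to the pool mean.
#' @return The permutation p-value.
#' @export
proportion_permutation_test <- function(n_species, observed_prop, pool_modes,
                                        n_perm = 100, reference = NULL) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  if (is.character(pool_modes) || is.factor(pool_modes)) {
    pool_modes <- as.character(pool_modes) == "non_pelagic"
  }
  stopifnot(is.logical(pool_modes), n_species <= length(pool_modes),
            n_species >= 1)
  ref <- if (is.null(reference)) mean(pool_modes) else reference
  obs_dev <- abs(observed_prop - ref)
  perm_dev <- vapply(seq_len(n_perm), function(i) {
    abs(mean(sample(pool_modes, n_species)) - ref)
  }, numeric(1))
  mean(perm_dev >= obs_dev - 1e-12)
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test of a sequence against its order,
#' via Kendall's tau. `NA` values are dropped (with their positions).
#'
#' @param x Numeric sequence (e.g. band proportions from south to north).
#' @return Tibble with `tau`, `p_value`, `n`.
#' @export
mann_kendall <- function(x) {
  idx <- seq_along(x)[!is.na(x)]
  x <- x[!is.na(x)]
  if (length(x) < 3L) {
    return(tibble::tibble(tau = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(idx, x, method = "kendall"))
  tibble::tibble(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
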