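#' Synthetic environmental grid
#'
#' Seeded generator of a co-registered pixel grid emulating a continental
#' margin: shallow shelf/bank cells whose areal fraction shrinks poleward
#' (so high latitudes are predominantly deep), a latitudinal temperature
#' gradient, and per-pixel AR(1) current series from which mean current
#' `U` and dynamic stratification `DS` are computed. Per-pixel seasonal
#' chlorophyll series yield contingency (`M_CHLA`) fields via
#' [colwell()].
#'
#' @param seed Integer seed; identical seeds give identical grids.
#' @param lat_range,lon_range Extents in degrees.
#' @param resolution Cell size in degrees (default 0.5).
#' @param shelf_frac_south,shelf_frac_north Fraction of the longitudinal
#'   extent occupied by shelf at the southern/northern edge.
#' @param shelf_depths,deep_depths Depth ranges (m) for shelf and deep
#'   cells.
#' @param temp_south,temp_north Water-column mean temperature (deg C) at
#'   the southern/northern edge.
#' @param n_time Length of the per-pixel current series (0 skips currents;
#'   `U`/`DS` are then `NA`).
#' @param current_sd Stationary sds `c(sd_u, sd_v)` of the AR(1) current
#'   components (m/s).
#' @param current_phi AR(1) autocorrelation of the current series.
#' @param n_years Years of monthly chlorophyll per pixel.
#' @param chla_noise_sd Lognormal noise sd of the chlorophyll series.
#' @return Pixel tibble (`lon`, `lat`, `depth`, `habitat`, `T`, `U`,
#'   `DS`, `chla_mean`, `M_CHLA`, `P_CHLA`, `C_CHLA`, `is_shelf`) with a
#'   `resolution` attribute.
#' @export
gen_env_grid <- function(seed, lat_range = c(25, 70), lon_range = c(0, 10),
                         resolution = 0.5,
                         shelf_frac_south = 0.8, shelf_frac_north = 0.1,
                         shelf_depths = c(10, 120), deep_depths = c(400, 1500),
                         temp_south = 20, temp_north = 5,
                         n_time = 0, current_sd = c(0.05, 0.05),
                         current_phi = 0.5,
                         n_years = 19, chla_noise_sd = 0.3) {
  set.seed(seed)
  lons <- seq(lon_range[1] + resolution / 2, lon_range[2] - resolution / 2,
              by = resolution)
  lats <- seq(lat_range[1] + resolution / 2, lat_range[2] - resolution / 2,
              by = resolution)
  if (length(lons) * length(lats) < 100) stop("grid too small; need >= 100 cells")
  grid <- tidyr::expand_grid(lat = lats, lon = lons)
  n <- nrow(grid)

  # Shallow (shelf/bank) cells are scattered across longitude with a
  # poleward-declining fraction: high latitudes are predominantly deep,
  # but at every latitude the shallow cells sample all longitudes, so no
  # longitudinal composition gradient can masquerade as a latitudinal one.
  frac <- shelf_frac_south + (shelf_frac_north - shelf_frac_south) *
    (grid$lat - lat_range[1]) / diff(lat_range)
  grid$is_shelf <- stats::runif(n) < frac
  grid$depth <- ifelse(grid$is_shelf,
                       stats::runif(n, shelf_depths[1], shelf_depths[2]),
                       stats::runif(n, deep_depths[1], deep_depths[2]))
  grid$habitat <- sample(c("rock", "mud", "sand", "coarse"), n, replace = TRUE)
  grid$T <- temp_south + (temp_north - temp_south) *
    (grid$lat - lat_range[1]) / diff(lat_range) -
    1.5 * log10(grid$depth / 10) + stats::rnorm(n, 0, 0.2)

  if (n_time >= 2) {
    ar1 <- function(npx, nt, sdx, phi) {
      innov_sd <- sdx * sqrt(1 - phi^2)
      x <- matrix(stats::rnorm(npx * nt, 0, innov_sd), npx, nt)
      x[, 1] <- stats::rnorm(npx, 0, sdx)
      for (t in 2:nt) x[, t] <- phi * x[, t - 1] + x[, t]
      x
    }
    u <- ar1(n, n_time, current_sd[1], current_phi) + 0.02
    v <- ar1(n, n_time, current_sd[2], current_phi) + 0.02
    grid$U <- rowMeans(sqrt(u^2 + v^2))
    grid$DS <- sqrt(apply(u, 1, stats::sd)^2 + apply(v, 1, stats::sd)^2)
  } else {
    grid$U <- NA_real_
    grid$DS <- NA_real_
  }

  # Seasonal chlorophyll: the cycle amplitude varies pixel to pixel with
  # no spatial trend, so productivity seasonality carries no planted
  # geographic signal that the shelf geometry could convert into a
  # latitudinal mode gradient. The amplitude/noise defaults put the
  # contingency field in the realistic 0.1-0.35 range observed for
  # surface chlorophyll.
  amp <- stats::runif(n, 0.1, 1.3)
  months <- rep(1:12, n_years)
  seas <- sin(2 * pi * (months - 1) / 12)
  cw <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    series <- (2 + amp[i] * seas) *
      exp(stats::rnorm(length(months), 0, chla_noise_sd))
    res <- colwell(series, months)
    cw[i, ] <- c(mean(series), max(series), res$P, res$C, res$M)
  }
  grid$chla_mean <- cw[, 1]
  grid$chla_max <- cw[, 2]
  grid$P_CHLA <- cw[, 3]
  grid$C_CHLA <- cw[, 4]
  grid$M_CHLA <- cw[, 5]
  attr(grid, "resolution") <- resolution
  attr(grid, "truth") <- list(shelf_frac = c(shelf_frac_south, shelf_frac_north),
                              current_sd = current_sd, chla_amp_range = range(amp))
  grid
}

#' Synthetic monthly chlorophyll series
#'
#' Monthly sinusoid with multiplicative lognormal noise:
#' `chla = (mean + amplitude * sin(2*pi*(month-1)/12)) * exp(N(0, sd))`.
#' Zero amplitude and zero noise give a constant series (Colwell
#' `P = C = 1, M = 0`); a strong cycle with little noise drives `M`
#' toward its deterministic-cycle ceiling.
#'
#' @param seed Integer seed.
#' @param n_years Number of whole years (>= 2).
#' @param mean_chla Baseline concentration (mg/m^3).
#' @param seasonal_amplitude Amplitude of the annual cycle (>= 0, and at
#'   most `mean_chla` so values stay non-negative).
#' @param noise_sd Lognormal noise sd.
#' @return Tibble with `year`, `month`, `chla`.
#' @export
gen_chla <- function(seed, n_years = 2, mean_chla = 2, seasonal_amplitude = 1,
                     noise_sd = 0.1) {
  if (seasonal_amplitude < 0) stop("seasonal amplitude must be non-negative")
  stopifnot(n_years >= 2, mean_chla >= seasonal_amplitude)
  set.seed(seed)
  out <- tidyr::expand_grid(year = seq_len(n_years), month = 1:12)
  det <- mean_chla + seasonal_amplitude * sin(2 * pi * (out$month - 1) / 12)
  out$chla <- det * exp(stats::rnorm(nrow(out), 0, noise_sd))
  out
}

#' Synthetic species pool with ranges and developmental modes
#'
#' Draws a pool of species over a synthetic grid. Each species gets a
#' bathymetric affinity (shelf or deep), a depth range, a latitudinal
#' range rectangle, habitat classes, and a potential distribution built
#' with the same range/depth/habitat machinery as the real pipeline.
#' The developmental mode is then drawn from a logistic model on the
#' species' range-mean depth and chlorophyll seasonality:
#' `P(pelagic) = plogis(b0 + b1 * depth + b2 * M_CHLA)` with the default
#' coefficients negative in depth and seasonality, so deep-ranged species
#' are mostly non-pelagic. Pelagic species are split into planktotrophic
#' and lecithotrophic with probability `p_planktotrophic`. Latitude never
#' enters the mode model. Superfamily labels are assigned independently
#' of mode by default (`superfamily_sd = 0`); a positive value adds a
#' superfamily-level logit shift of that standard deviation.
#'
#' Body sizes are lognormal with mode-dependent shifts (non-pelagic
#' species have much larger initial and juvenile volumes; planktotrophic
#' larvae grow ~100-fold before metamorphosis).
#'
#' @param seed Integer seed.
#' @param grid A [gen_env_grid()] grid.
#' @param n_species Pool size (>= 10).
#' @param mode_coefs Logistic coefficients `c(intercept, depth, M_CHLA)`
#'   on the pelagic-probability logit scale. Depth in m.
#' @param p_deep Probability a species is deep-ranged. The default
#'   keeps deep pixels an order of magnitude poorer than the shelf,
#'   with richness well below the usual minimum-count threshold.
#' @param p_planktotrophic Probability a pelagic species is
#'   planktotrophic (vs lecithotrophic).
#' @param superfamily_sd Sd of the superfamily logit shift (0 = mode
#'   independent of superfamily).
#' @param n_superfamilies Number of superfamily labels.
#' @param lat_start_frac,lat_extent_frac Range rectangles in latitude:
#'   the southern edge sits at `lat_min + span * U(lat_start_frac)` and
#'   the extent is `span * U(lat_extent_frac)`, truncated to the grid.
#'   The defaults make most species span the whole grid.
#' @return List with `species` (trait tibble incl. `mode`, `superfamily`,
#'   env means), `dists` (list of `potential_distribution`), `bounds`
#'   (range rectangles) and `truth` (the planted coefficients).
#' @export
gen_species <- function(seed, grid, n_species = 94,
                        mode_coefs = c(3.4, -0.0047, -14.2),
                        p_deep = 0.15, p_planktotrophic = 0.836,
                        superfamily_sd = 0, n_superfamilies = 8,
                        lat_start_frac = c(-0.25, 0),
                        lat_extent_frac = c(1.1, 1.5)) {
  if (n_species < 10) stop("need >= 10 species")
  if (length(mode_coefs) != 3 || any(!is.finite(mode_coefs))) {
    stop("`mode_coefs` must be 3 finite logistic coefficients")
  }
  set.seed(seed)
  lat_rng <- range(grid$lat)
  lon_rng <- range(grid$lon)
  habitats <- unique(grid$habitat)

  deep <- stats::runif(n_species) < p_deep
  depth_min <- ifelse(deep, 200, 0)
  depth_max <- ifelse(deep, stats::runif(n_species, 800, 2000),
                      stats::runif(n_species, 40, 160))
  # Latitudinal rectangles are near-cosmopolitan by default: random edges
  # sit mostly outside or near the grid margins, so developmental-mode
  # composition carries no latitudinal structure beyond what bathymetry
  # imposes (per-pixel richness still declines poleward through the
  # shrinking shelf). Narrower pools can be generated via
  # `lat_start_frac`/`lat_extent_frac`.
  span <- diff(lat_rng)
  lat_min <- lat_rng[1] + span * stats::runif(n_species, lat_start_frac[1],
                                              lat_start_frac[2])
  lat_max <- pmin(lat_min + span * stats::runif(n_species, lat_extent_frac[1],
                                                lat_extent_frac[2]),
                  lat_rng[2] + 0.5)
  lon_w <- diff(lon_rng)
  lon_min <- stats::runif(n_species, lon_rng[1] - 0.5, lon_rng[1] + 0.5 * lon_w)
  lon_max <- pmin(lon_min + stats::runif(n_species, 0.3 * lon_w, 1.2 * lon_w),
                  lon_rng[2] + 0.5)
  n_hab <- sample(2:4, n_species, replace = TRUE)
  hab_classes <- lapply(n_hab, function(k) sample(habitats, k))
  superfamily <- paste0("SF", sample.int(n_superfamilies, n_species,
                                         replace = TRUE))
  sf_shift <- stats::setNames(
    stats::rnorm(n_superfamilies, 0, superfamily_sd),
    paste0("SF", seq_len(n_superfamilies)))

  bounds <- tibble::tibble(lat_min = lat_min, lat_max = lat_max,
                           lon_min = lon_min, lon_max = lon_max)
  dists <- vector("list", n_species)
  envm <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    rm <- rasterize_range(grid, bounds[i, ], species = paste0("sp", i))
    dists[[i]] <- suppressWarnings(
      potential_habitat(grid, rm, c(depth_min[i], depth_max[i]),
                        habitat_classes = hab_classes[[i]]))
    envm[[i]] <- if (dists[[i]]$n_cells > 0) {
      species_env_means(grid, dists[[i]],
                        vars = intersect(c("depth", "T", "U", "DS", "chla_mean",
                                           "M_CHLA", "P_CHLA", "C_CHLA"),
                                         names(grid)))
    } else {
      tibble::tibble(depth = (depth_min[i] + depth_max[i]) / 2,
                     T = NA_real_, M_CHLA = mean(grid$M_CHLA))
    }
  }
  env <- dplyr::bind_rows(envm)

  eta <- mode_coefs[1] + mode_coefs[2] * env$depth +
    mode_coefs[3] * env$M_CHLA + sf_shift[superfamily]
  pelagic <- stats::runif(n_species) < stats::plogis(eta)
  mode <- ifelse(!pelagic, "non_pelagic",
                 ifelse(stats::runif(n_species) < p_planktotrophic,
                        "planktotrophic", "lecithotrophic"))

  is_mu <- c(non_pelagic = log(0.05), planktotrophic = log(1e-4),
             lecithotrophic = log(1e-3))
  gr1_mu <- c(non_pelagic = log(6), planktotrophic = log(100),
              lecithotrophic = log(5))
  IS <- stats::rlnorm(n_species, is_mu[mode], 1)
  Gr1 <- pmax(stats::rlnorm(n_species, gr1_mu[mode], 0.5), 1.05)
  JS <- IS * Gr1
  AS <- JS * pmax(stats::rlnorm(n_species, log(1e4), 1), 1.05)

  species <- dplyr::bind_cols(
    tibble::tibble(
      species = sprintf("sp%03d", seq_len(n_species)),
      superfamily = superfamily, mode = mode,
      diet = sample(c("carnivore", "omnivore", "herbivore"), n_species,
                    replace = TRUE, prob = c(0.54, 0.04, 0.42)),
      depth_min = depth_min, depth_max = depth_max,
      lat_min = lat_min, lat_max = lat_max,
      IS = IS, JS = JS, AS = AS,
      area_km2 = vapply(dists, `[[`, numeric(1), "area")
    ),
    env
  )
  list(species = species, dists = dists, bounds = bounds,
       truth = list(mode_coefs = mode_coefs, superfamily_sd = superfamily_sd,
                    sf_shift = sf_shift))
}

#' Synthetic occurrence records under spatially biased effort
#'
#' Emulates an aggregated occurrence database: for every pixel and every
#' species present there, the number of records is Poisson with mean
#' equal to the pixel's sampling effort. Low effort yields many
#' singletons (relative Chao well above 1); unbounded effort drives the
#' relative Chao to 1 (complete census).
#'
#' @param seed Integer seed.
#' @param grid The pixel grid.
#' @param dists Per-species distributions (masks aligned to `grid`).
#' @param effort Per-pixel expected records per present species: either a
#'   numeric vector over grid rows or a function of latitude. The default
#'   is a poleward-declining exponential,
#'   `3 * exp(-(lat - min(lat)) / 12)`.
#' @return Occurrence tibble (`species`, `lon`, `lat`), one row per
#'   record.
#' @export
gen_occurrences <- function(seed, grid, dists, effort = NULL) {
  set.seed(seed)
  if (is.null(effort)) effort <- function(lat) 8 * exp(-(lat - min(lat)) / 15)
  eff <- if (is.function(effort)) effort(grid$lat) else effort
  stopifnot(length(eff) == nrow(grid))
  if (any(eff < 0)) stop("effort must be non-negative")
  recs <- purrr::imap_dfr(dists, function(d, i) {
    m <- if (inherits(d, "potential_distribution")) d$mask else d
    idx <- which(m)
    if (!length(idx)) return(NULL)
    k <- stats::rpois(length(idx), eff[idx])
    keep <- k > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(species = sprintf("sp%03d", i),
                   lon = rep(grid$lon[idx[keep]], k[keep]),
                   lat = rep(grid$lat[idx[keep]], k[keep]))
  })
  recs
}

#' Generate a complete synthetic study system
#'
#' Orchestrates [gen_env_grid()], [gen_species()] and
#' [gen_occurrences()] into one seeded world with stored ground truth:
#' grid, species pool with distributions, proportion map, occurrence
#' records and their survey summary. Sub-generators get seeds derived
#' deterministically from `seed`.
#'
#' @param seed Integer seed.
#' @param n_species Species pool size.
#' @param ... Passed to [gen_env_grid()].
#' @param mode_coefs,superfamily_sd Passed to [gen_species()].
#' @param effort Passed to [gen_occurrences()].
#' @return List with `grid`, `species`, `dists`, `prop_map`,
#'   `occurrences`, `occ_summary`, `truth`.
#' @export
gen_world <- function(seed, n_species = 94, ...,
                      mode_coefs = c(3.4, -0.0047, -14.2),
                      superfamily_sd = 0, effort = NULL) {
  grid <- gen_env_grid(seed, ...)
  sp <- gen_species(seed + 1003L, grid, n_species = n_species,
                    mode_coefs = mode_coefs, superfamily_sd = superfamily_sd)
  prop_map <- stack_proportions(grid, sp$dists, sp$species$mode)
  occ <- gen_occurrences(seed + 2003L, grid, sp$dists, effort = effort)
  occ_sum <- if (nrow(occ)) {
    occurrence_summary(occ, resolution = attr(grid, "resolution"))
  } else {
    tibble::tibble(lon = numeric(), lat = numeric(), n_records = integer(),
                   s_obs = integer(), f1 = integer(), f2 = integer(),
                   chao1 = numeric(), rel_chao = numeric())
  }
  list(grid = grid, species = sp$species, dists = sp$dists,
       prop_map = prop_map, occurrences = occ, occ_summary = occ_sum,
       truth = c(sp$truth, list(seed = seed)))
}

#' The sampling-artefact experiment
#'
#' Runs replicate synthetic worlds in which developmental mode depends on
#' depth and productivity seasonality but never on latitude, while
#' geography (a poleward-shrinking shelf) and sampling effort (a
#' poleward-declining exponential) conspire to make high latitudes deep,
#' species-poor and under-surveyed. For each world the non-pelagic band
#' proportions are summarised with the naive per-pixel average
#' (`pixel_mean`) and with the reliability-filtered method (`filtered`:
#' minimum richness and relative Chao below threshold), and each band
#' series is tested for a monotone latitudinal trend with
#' [mann_kendall()]. The naive method manufactures an apparent poleward
#' rise in non-pelagic development; the filtered method should not.
#'
#' @param seed Base seed; world `i` uses `seed + i`.
#' @param n_worlds Number of replicate worlds.
#' @param n_species Species pool size per world.
#' @param rel_chao_threshold Survey-completeness cut-off.
#' @param nmin Minimum richness; defaults to [n_min()] at the world's own
#'   reference non-pelagic proportion with `delta_p = 0.3`.
#' @param ... Passed to [gen_world()].
#' @return Tibble with one row per world: `world`, `tau_pixel_mean`,
#'   `p_pixel_mean`, `tau_filtered`, `p_filtered`, `n_bands_filtered`.
#' @export
sampling_artefact_experiment <- function(seed, n_worlds = 50, n_species = 94,
                                         rel_chao_threshold = 1.2,
                                         nmin = NULL, ...) {
  purrr::map_dfr(seq_len(n_worlds), function(i) {
    w <- gen_world(seed + i, n_species = n_species, ...)
    p_ref <- mean(w$species$mode == "non_pelagic")
    nm <- if (is.null(nmin)) n_min(p_ref, 0.3) else nmin
    pm <- reliability_mask(w$prop_map, w$occ_summary, nmin = nm,
                           rel_chao_threshold = rel_chao_threshold)
    naive <- band_summary(pm, "pixel_mean")
    filt <- band_summary(pm, "filtered")
    np_naive <- naive$proportion[naive$mode == "non_pelagic"]
    np_filt <- filt$proportion[filt$mode == "non_pelagic"]
    mk_n <- mann_kendall(np_naive)
    mk_f <- mann_kendall(np_filt)
    tibble::tibble(world = i,
                   tau_pixel_mean = mk_n$tau, p_pixel_mean = mk_n$p_value,
                   tau_filtered = mk_f$tau, p_filtered = mk_f$p_value,
                   n_bands_filtered = sum(!is.na(np_filt)))
  })
}
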