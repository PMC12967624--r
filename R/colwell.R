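#' Month-by-state contingency table for a periodic series
#'
#' Bins a monthly series into `n_classes` equal-width magnitude classes
#' spanning the observed range of non-missing values and cross-tabulates
#' month (1-12) against class. The maximum value is assigned to the top
#' class; a constant series puts every observation in class 1. Missing
#' months are dropped, not imputed.
#'
#' @param values Numeric observations (e.g. monthly chlorophyll-a, mg/m^3).
#' @param months Integer month labels (1-12), same length as `values`.
#' @param n_classes Number of magnitude classes (>= 2); 11 by default, the
#'   conventional choice for these indices.
#' @param binning `"equal_width"` (default) or `"log_width"` (equal-width
#'   bins on the natural-log scale; requires strictly positive values).
#' @return Integer matrix with 12 rows (months) and `n_classes` columns.
#' @export
classify_states <- function(values, months, n_classes = 11,
                            binning = c("equal_width", "log_width")) {
  binning <- match.arg(binning)
  stopifnot(length(values) == length(months), n_classes >= 2)
  keep <- !is.na(values) & !is.na(months)
  values <- values[keep]; months <- as.integer(months[keep])
  if (length(values) == 0L) stop("all values missing: cannot classify states")
  if (any(months < 1L | months > 12L)) stop("months must be in 1..12")
  x <- if (binning == "log_width") {
    if (any(values <= 0)) stop("log_width binning requires positive values")
    log(values)
  } else values
  rng <- range(x)
  if (rng[1] == rng[2]) {
    state <- rep.int(1L, length(x))
  } else {
    width <- (rng[2] - rng[1]) / n_classes
    state <- pmin(floor((x - rng[1]) / width) + 1L, n_classes)
  }
  tab <- table(factor(months, levels = 1:12),
               factor(state, levels = seq_len(n_classes)))
  tab <- matrix(as.integer(tab), nrow = 12L,
                dimnames = list(month = 1:12, state = seq_len(n_classes)))
  tab
}

# Shannon entropy (natural log) of a vector of counts.
shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Colwell's predictability, constancy and contingency
#'
#' Information-theoretic decomposition of a periodic time series into
#' predictability `P`, constancy `C` and contingency `M` (seasonality),
#' computed from a month-by-state contingency table with natural-log
#' entropies:
#' `C = 1 - H(Y)/log(s)`, `M = (H(X) + H(Y) - H(XY))/log(s)`, `P = C + M`,
#' where `X` is the month marginal, `Y` the state marginal, `XY` the full
#' table, and `s` the configured number of state classes (not the number
#' of occupied classes). All three indices lie in [0, 1] and satisfy
#' `P = C + M` exactly.
#'
#' @inheritParams classify_states
#' @return A one-row tibble with columns `P`, `C`, `M`, `s` and a
#'   list-column `table` holding the month-by-state count matrix.
#' @examples
#' colwell(rep(5, 24), rep(1:12, 2))        # constant: P = C = 1, M = 0
#' colwell(rep(c(0, 1), 12), rep(1:12, 2), n_classes = 2) # seasonal: M = 1
#' @export
colwell <- function(values, months, n_classes = 11,
                    binning = c("equal_width", "log_width")) {
  tab <- classify_states(values, months, n_classes, binning)
  n <- sum(tab)
  hx <- shannon(rowSums(tab))   # months
  hy <- shannon(colSums(tab))   # states
  hxy <- shannon(as.vector(tab))
  s <- n_classes
  C <- 1 - hy / log(s)
  M <- (hx + hy - hxy) / log(s)
  tibble::tibble(P = C + M, C = C, M = M, s = s, n = n, table = list(tab))
}

#' Per-pixel chlorophyll summary statistics
#'
#' Arithmetic mean and maximum over the non-missing values of a monthly
#' chlorophyll-a series.
#'
#' @param values Numeric series (mg/m^3); `NA`s are dropped.
#' @return A one-row tibble with `chla_mean` and `chla_max`.
#' @export
chla_stats <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("all chlorophyll values missing")
  tibble::tibble(chla_mean = mean(v), chla_max = max(v))
}

#' Colwell indices and chlorophyll statistics for every pixel
#'
#' Applies [colwell()] and [chla_stats()] pixel-wise to a long-format
#' monthly chlorophyll table.
#'
#' @param chla A data frame with columns `lon`, `lat`, `year`, `month`,
#'   `chla`.
#' @inheritParams classify_states
#' @return A tibble with one row per pixel: `lon`, `lat`, `chla_mean`,
#'   `chla_max`, `P_CHLA`, `C_CHLA`, `M_CHLA`.
#' @export
summarise_chla <- function(chla, n_classes = 11) {
  stopifnot(all(c("lon", "lat", "year", "month", "chla") %in% names(chla)))
  chla |>
    dplyr::group_by(.data$lon, .data$lat) |>
    dplyr::summarise(
      chla_mean = mean(.data$chla, na.rm = TRUE),
      chla_max = max(.data$chla, na.rm = TRUE),
      cw = colwell(.data$chla, .data$month, n_classes)[, c("P", "C", "M")],
      .groups = "drop"
    ) |>
    tidyr::unpack("cw") |>
    dplyr::rename(P_CHLA = "P", C_CHLA = "C", M_CHLA = "M")
}
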