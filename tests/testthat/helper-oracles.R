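# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Colwell indices by direct entropy sums over a table built with cut().
colwell_oracle <- function(values, months, n_classes = 11) {
  keep <- !is.na(values)
  values <- values[keep]; months <- months[keep]
  rng <- range(values)
  state <- if (rng[1] == rng[2]) rep(1L, length(values)) else {
    br <- seq(rng[1], rng[2], length.out = n_classes + 1)
    as.integer(cut(values, br, include.lowest = TRUE, labels = FALSE))
  }
  tab <- matrix(0, 12, n_classes)
  for (i in seq_along(state)) tab[months[i], state[i]] <- tab[months[i], state[i]] + 1
  N <- sum(tab)
  H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  hx <- H(rowSums(tab)); hy <- H(colSums(tab)); hxy <- H(as.vector(tab))
  C <- 1 - hy / log(n_classes)
  M <- (hx + hy - hxy) / log(n_classes)
  list(P = C + M, C = C, M = M)
}

# Moran's I by the explicit double sum.
brute_moran <- function(z, W) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * zc[i] * zc[j]
  (n / sum(W)) * num / sum(zc^2)
}

# Simulate from the spatial lag model y = rho W y + X beta + eps.
sar_sim <- function(n, rho, beta, sigma = 1, seed = 1) {
  set.seed(seed)
  coords <- tibble::tibble(lon = runif(n, 0, 4), lat = runif(n, 40, 44))
  W <- suppressWarnings(build_weights(coords, patch_size_km = 150))
  X <- cbind(1, rnorm(n), rnorm(n))
  eps <- rnorm(n, 0, sigma)
  y <- solve(diag(n) - rho * W, X %*% beta + eps)
  list(data = tibble::tibble(y = as.vector(y), x1 = X[, 2], x2 = X[, 3],
                             lon = coords$lon, lat = coords$lat),
       W = W)
}

# Correlated design columns with a given correlation between cols 1 and 2.
correlated_design <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  tibble::tibble(a = z1, b = r * z1 + sqrt(1 - r^2) * z2, c = z3)
}
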