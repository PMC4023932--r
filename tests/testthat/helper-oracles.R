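# Independent reference implementations used to check the package's
# statistics. These deliberately use naive O(n^2) double loops over a dense
# weights matrix, not the package's own code paths.

# dense binary distance-band weights matrix
oracle_weights <- function(xy, band, include_self = FALSE) {
  n <- nrow(xy)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (i == j) {
        if (include_self) w[i, j] <- 1
      } else if (d <= band) {
        w[i, j] <- 1
      }
    }
  }
  w
}

# Moran's I with randomisation variance, straight from the defining sums
oracle_moran <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  W <- sum(w)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  }
  I <- (n / W) * num / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) S1 <- S1 + (w[i, j] + w[j, i])^2
  }
  S1 <- S1 / 2
  S2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2
  V <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
          b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)) /
    ((n - 1) * (n - 2) * (n - 3) * W^2) - EI^2
  list(I = I, EI = EI, V = V, z = (I - EI) / sqrt(V),
       W = W, S1 = S1, S2 = S2, b2 = b2)
}

# Gi* from the defining per-location sums
oracle_gistar <- function(x, w_star) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  vapply(seq_len(n), function(i) {
    sw <- sum(w_star[i, ])
    sw2 <- sum(w_star[i, ]^2)
    swx <- sum(w_star[i, ] * x)
    den <- S * sqrt((n * sw2 - sw^2) / (n - 1))
    if (den == 0) 0 else (swx - xbar * sw) / den
  }, numeric(1))
}

# winding number containment test (boundary treated as inside)
oracle_winding_pip <- function(pt, poly) {
  n <- nrow(poly)
  wn <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (pt[2] - a[2]) - (pt[1] - a[1]) * (b[2] - a[2])
    # on-segment check
    if (abs(cross) < 1e-9 * max(1, abs(b[1] - a[1]) + abs(b[2] - a[2])) &&
        pt[1] >= min(a[1], b[1]) - 1e-12 && pt[1] <= max(a[1], b[1]) + 1e-12 &&
        pt[2] >= min(a[2], b[2]) - 1e-12 && pt[2] <= max(a[2], b[2]) + 1e-12) {
      return(TRUE)
    }
    if (a[2] <= pt[2]) {
      if (b[2] > pt[2] && cross > 0) wn <- wn + 1
    } else {
      if (b[2] <= pt[2] && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Moran's I z-score against an explicit permutation null
oracle_perm_moran_z <- function(x, w, n_perm = 999, seed = 1) {
  n <- length(x)
  stat <- function(v) {
    z <- v - mean(v)
    (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  }
  obs <- stat(x)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(x)), numeric(1))
  })
  (obs - mean(null)) / stats::sd(null)
}

# area of a lat/lon rectangle on the sphere, by spherical excess
oracle_spherical_cell_area <- function(lat1, lat2, lon1, lon2,
                                       R = 6371007.181) {
  R^2 * (lon2 - lon1) * pi / 180 *
    (sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
}

# small record set builder for unit tests
make_records <- function(n = 5, seed = 1, error_km = NULL) {
  with_local_seed(seed, {
    df <- data.frame(
      voucher_id = sprintf("V%03d", seq_len(n)),
      sex = sample(c("female", "male"), n, replace = TRUE),
      morph = character(n),
      morph_group = character(n),
      subspecies = character(n),
      country = sample(c("Kenya", "Uganda", "Tanzania"), n, replace = TRUE),
      locality = rep("test site", n),
      latitude = runif(n, -10, 10),
      longitude = runif(n, 20, 40),
      geocode_error_km = if (is.null(error_km)) runif(n, 0, 39) else error_km,
      stringsAsFactors = FALSE
    )
    record_set(df, provenance = "unit test")
  })
}
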