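test_that("the four-point line example gives I = 1/3 and E[I] = -1/3", {
  xy <- cbind(0:3, rep(0, 4))
  w <- build_weights(xy, 1)
  res <- morans_i(c(1, 1, 0, 0), w)
  expect_equal(res$I, 1 / 3, tolerance = 1e-12)
  expect_equal(res$expected_I, -1 / 3, tolerance = 1e-12)
  # and agrees with the defining double sum
  o <- oracle_moran(c(1, 1, 0, 0), oracle_weights(xy, 1))
  expect_equal(res$I, o$I, tolerance = 1e-12)
})

test_that("constant values and empty weights are rejected", {
  xy <- cbind(0:4, rep(0, 5))
  w <- build_weights(xy, 1)
  expect_error(morans_i(rep(2, 5), w), "zero variance")
  w0 <- build_weights(xy, 0.5)
  expect_error(morans_i(1:5, w0), "empty weights")
  ws <- build_weights(xy, 1, include_self = TRUE)
  expect_error(morans_i(1:5, ws), "include_self")
})

test_that("Moran's I matches the brute-force oracle to 1e-10 relative", {
  xy <- generate_csr(200, c(0, 1e6, 0, 1e6), seed = 31)
  vals <- with_local_seed(32, rpois(200, 3) + runif(200))
  for (band in c(8e4, 1.5e5)) {
    res <- morans_i(vals, build_weights(xy, band))
    o <- oracle_moran(vals, oracle_weights(xy, band))
    expect_equal(res$I, o$I, tolerance = 1e-10)
    expect_equal(res$variance, o$V, tolerance = 1e-10)
    expect_equal(res$z, o$z, tolerance = 1e-10)
    expect_equal(res$S1, o$S1)
    expect_equal(res$S2, o$S2)
  }
})

test_that("Moran's I is invariant under affine transforms of the values", {
  xy <- generate_csr(80, c(0, 1e5, 0, 1e5), seed = 8)
  vals <- with_local_seed(9, rnorm(80))
  w <- build_weights(xy, 2e4)
  base <- morans_i(vals, w)
  for (ab in list(c(3, 0), c(-2, 5), c(0.1, -7))) {
    tr <- morans_i(ab[1] * vals + ab[2], w)
    expect_equal(tr$I, base$I, tolerance = 1e-12)
    expect_equal(tr$z, base$z, tolerance = 1e-10)
  }
})

test_that("analytic randomisation z agrees with a permutation null", {
  # the analytic z should sit within 0.3 of the z estimated from 999
  # random permutations of the values over the fixed locations
  for (seed in c(1, 2, 3)) {
    xy <- generate_csr(100, c(0, 1e6, 0, 1e6), seed = seed)
    vals <- with_local_seed(seed + 100, rgamma(100, 2))
    w <- build_weights(xy, 1.8e5)
    analytic <- morans_i(vals, w)$z
    perm <- oracle_perm_moran_z(vals, oracle_weights(xy, 1.8e5),
                                n_perm = 999, seed = seed)
    expect_lt(abs(analytic - perm), 0.3)
  }
})

test_that("incremental band selection is consistent with per-band calls", {
  loc <- data.frame(x = generate_csr(60, c(0, 1e5, 0, 1e5), 6)[, 1],
                    y = generate_csr(60, c(0, 1e5, 0, 1e5), 6)[, 2])
  loc$value <- with_local_seed(7, rpois(60, 2) + 1)
  bands <- seq(1e4, 5e4, by = 1e4)
  inc <- incremental_moran(loc, bands)
  for (k in seq_along(bands)) {
    direct <- morans_i(loc$value, build_weights(as.matrix(loc[, 1:2]),
                                                bands[k]))
    expect_equal(inc$results$z[k], direct$z, tolerance = 1e-12)
  }
  expect_equal(inc$best_band, bands[which.max(inc$results$z)])
})

test_that("a single valid band is selected; unusable bands are skipped", {
  loc <- data.frame(x = c(0, 1, 2, 3, 10, 11) * 1e3,
                    y = rep(0, 6),
                    value = c(5, 4, 5, 1, 1, 2))
  one <- suppressWarnings(incremental_moran(loc, bands = 1.5e3))
  expect_equal(one$best_band, 1.5e3)
  # first band leaves isolated points only -> skipped with a warning
  expect_warning(
    both <- incremental_moran(loc, bands = c(10, 1.5e3)),
    "skipped")
  expect_equal(both$best_band, 1.5e3)
  expect_error(
    suppressWarnings(incremental_moran(loc, bands = c(5, 10))),
    "all distance bands")
})

test_that("band selection recovers a planted cluster scale", {
  # two tight clusters of high-count sites at scale ~s over a sparse
  # background: the z-peak should sit within one band step of s
  s <- 5e4
  with_local_seed(77, {
    bg <- generate_csr(120, c(0, 1e6, 0, 1e6), seed = 78)
    c1 <- cbind(2.5e5 + runif(40, -s / 2, s / 2),
                2.5e5 + runif(40, -s / 2, s / 2))
    c2 <- cbind(7e5 + runif(40, -s / 2, s / 2),
                7e5 + runif(40, -s / 2, s / 2))
    loc <- data.frame(x = c(bg[, 1], c1[, 1], c2[, 1]),
                      y = c(bg[, 2], c1[, 2], c2[, 2]),
                      value = c(rpois(120, 1) + 1, rpois(80, 8) + 3))
  })
  bands <- seq(2.5e4, 2.5e5, by = 2.5e4)
  inc <- incremental_moran(loc, bands)
  expect_lte(abs(inc$best_band - s), 2.5e4)
})
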