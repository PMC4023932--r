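test_that("generation is deterministic in the seed and leaves global RNG
           state alone", {
  cfg <- reference_scenario(seed = 101, size = 0.3)
  set.seed(999)
  before <- .Random.seed
  rs1 <- generate_records(cfg)
  expect_identical(.Random.seed, before)
  rs2 <- generate_records(cfg)
  expect_identical(as.data.frame(rs1), as.data.frame(rs2))
  rs3 <- generate_records(reference_scenario(seed = 102, size = 0.3))
  expect_false(identical(rs1$latitude, rs3$latitude))
})

test_that("a single cluster with no background yields points in the disc", {
  cfg <- synthetic_config(
    seed = 5, extent = c(-1e6, 1e6, -1e6, 1e6), n_background = 0,
    clusters = list(list(centre = c(0, 0), radius_m = 5e4, n_sites = 50,
                         mean_extra = 0)),
    regions = list(list(polygon = rect_poly(-1e6, 1e6, -1e6, 1e6),
                        subspecies = "tibullus", country = "Tanzania",
                        morph_freq = c(cenea = 1))))
  rs <- generate_records(cfg)
  expect_equal(nrow(rs), 50)  # mean_extra = 0 -> exactly one specimen/site
  pp <- project_records(rs)
  d <- sqrt(rowSums(as.matrix(pp)^2))
  expect_true(all(d <= 5e4 + 1))  # 1 m slack for the lat/lon round trip
})

test_that("female morph frequencies match the configured table", {
  freq <- c(cenea = 0.5, hippocoonides = 0.3, natalica = 0.2)
  cfg <- synthetic_config(
    seed = 7, extent = c(-1e6, 1e6, -1e6, 1e6), n_background = 2000,
    background_mean_extra = 0,
    female_fraction = 1,
    regions = list(list(polygon = rect_poly(-1e6, 1e6, -1e6, 1e6),
                        subspecies = "tibullus", country = "Tanzania",
                        morph_freq = freq)))
  rs <- generate_records(cfg)
  n <- nrow(rs)
  for (m in names(freq)) {
    p <- freq[[m]]
    expect_lt(abs(mean(rs$morph == m) - p), 3 * sqrt(p * (1 - p) / n))
  }
  # morph groups follow the registry
  expect_true(all(rs$morph_group[rs$morph == "cenea"] == "cenea"))
})

test_that("records respect structural invariants of the data model", {
  cfg <- reference_scenario(seed = 44, size = 0.5)
  rs <- generate_records(cfg)
  expect_false(any(duplicated(rs$voucher_id)))
  expect_true(all(rs$sex %in% c("male", "female")))
  expect_true(all(rs$morph[rs$sex == "male"] == ""))
  expect_true(all(rs$geocode_error_km >= 0 & rs$geocode_error_km <= 60))
  expect_true(all(abs(rs$latitude) < 90))
  # specimen counts per site sum to the record count
  loc <- aggregate_localities(rs)
  expect_equal(sum(loc$value), nrow(rs))
})

test_that("raster cells take the class of the first polygon containing their
           centre", {
  cfg <- synthetic_config(
    seed = 1, extent = c(0, 100, 0, 100), n_background = 1,
    regions = list(list(polygon = rect_poly(0, 100, 0, 100),
                        subspecies = "x", country = "y",
                        morph_freq = c(cenea = 1))),
    raster = list(extent = c(0, 100, 0, 100), cell_m = 10, nodata = -9L,
                  classes = list(
                    list(id = 2L, polygon = rect_poly(0, 50, 0, 100)),
                    list(id = 1L, polygon = rect_poly(0, 100, 0, 100)))))
  r <- generate_raster(cfg)
  expect_equal(dim(r$grid), c(10, 10))
  # straight boundary: west half class 2, east half class 1
  expect_true(all(r$grid[, 1:5] == 2L))
  expect_true(all(r$grid[, 6:10] == 1L))
  # containment oracle at every centre
  for (i in with_local_seed(2, sample(100, 20))) {
    row <- (i - 1) %/% 10 + 1
    col <- (i - 1) %% 10 + 1
    cx <- (col - 0.5) * 10
    cy <- (10 - row + 0.5) * 10
    want <- if (cx <= 50) 2L else 1L
    expect_identical(r$grid[row, col], want)
  }
})

test_that("a uniform single-class raster and nodata outside classes", {
  cfg <- synthetic_config(
    seed = 1, extent = c(0, 100, 0, 100), n_background = 1,
    regions = list(list(polygon = rect_poly(0, 100, 0, 100),
                        subspecies = "x", country = "y",
                        morph_freq = c(cenea = 1))),
    raster = list(extent = c(0, 100, 0, 100), cell_m = 20, nodata = -9L,
                  classes = list(
                    list(id = 7L, polygon = rect_poly(0, 100, 0, 60)))))
  r <- generate_raster(cfg)
  expect_true(all(r$grid[4:5, ] == 7L))   # south rows covered
  expect_true(all(r$grid[1:2, ] == -9L))  # north rows nodata
})

test_that("CSR generation is reproducible, in-extent and has the expected
           nearest-neighbour spacing", {
  ext <- c(0, 1e6, 0, 1e6)
  a <- generate_csr(2000, ext, seed = 3)
  b <- generate_csr(2000, ext, seed = 3)
  expect_identical(a, b)
  expect_true(all(a[, 1] >= 0 & a[, 1] <= 1e6 &
                    a[, 2] >= 0 & a[, 2] <= 1e6))
  d <- as.matrix(dist(a))
  diag(d) <- Inf
  mean_nn <- mean(apply(d, 1, min))
  clark_evans <- 0.5 / sqrt(2000 / 1e12)
  expect_lt(abs(mean_nn - clark_evans) / clark_evans, 0.05)
})
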