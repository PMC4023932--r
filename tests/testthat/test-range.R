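test_that("convex hull of simple configurations", {
  tri <- rbind(c(0, 0), c(4, 0), c(2, 3))
  h <- convex_hull(tri)
  expect_equal(nrow(h), 3)
  expect_equal(polygon_area(h), 6)
  # starts at the lowest-y (then lowest-x) vertex, counter-clockwise
  expect_equal(h[1, ], c(x = 0, y = 0))
  expect_gt(mimicmaps:::signed_area(h), 0)

  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
              c(0.5, 0.5), c(0.2, 0.8), c(0.9, 0.1))
  hs <- convex_hull(sq)
  expect_equal(nrow(hs), 4)
  expect_equal(polygon_area(hs), 1)
})

test_that("degenerate hulls are rejected", {
  expect_error(convex_hull(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(convex_hull(cbind(0:5, 0:5)), "degenerate")
})

test_that("all points lie inside or on their own hull", {
  pts <- generate_csr(1000, c(0, 1e5, 0, 1e5), seed = 81)
  h <- convex_hull(pts)
  expect_true(all(point_in_polygon(pts, h)))
})

# helper: total area of parts intersected with a rectangle
clip_polygon_rect_area_helper <- function(parts, xmin, xmax, ymin, ymax) {
  out <- list()
  for (p in parts) {
    piece <- mimicmaps:::clip_polygon_rect(p, xmin, xmax, ymin, ymax)
    if (nrow(piece) >= 3) out[[length(out) + 1]] <- piece
  }
  out
}

test_that("clipping removes unoccupied classes exactly", {
  # two-class raster split down the middle at x = 100; points only on side A
  g <- matrix(0L, 10, 20)
  g[, 1:10] <- 1L
  g[, 11:20] <- 2L
  r <- class_raster(g, origin = c(0, 0), cell_m = 10)
  pts <- with_local_seed(82, cbind(runif(30, 5, 95), runif(30, 5, 95)))
  hull <- convex_hull(rbind(pts, c(150, 50)))  # hull reaches into side B
  rp <- clip_by_occupied_classes(hull, r, pts, taxon = "test")
  expect_identical(rp$occupied_classes, 1L)
  # no clipped area east of the class boundary (tolerance 1e-6 of a cell)
  for (part in rp$clipped) expect_lte(max(part[, 1]), 100 + 1e-6)
  spill <- polygon_area(rp$clipped) -
    polygon_area(clip_polygon_rect_area_helper(rp$clipped, 0, 100, 0, 100))
  expect_lt(abs(spill), 1e-6 * 100)
  # every occurrence point lies inside the clipped polygon, and hull area
  # bounds clipped area
  expect_true(all(point_in_polygon(pts, rp)))
  expect_lte(polygon_area(rp$clipped), polygon_area(hull))
})

test_that("clipping is the identity on a single-class raster and idempotent", {
  g <- matrix(1L, 10, 10)
  r <- class_raster(g, origin = c(0, 0), cell_m = 10)
  pts <- with_local_seed(83, cbind(runif(20, 10, 90), runif(20, 10, 90)))
  hull <- convex_hull(pts)
  rp <- clip_by_occupied_classes(hull, r, pts)
  expect_equal(polygon_area(rp$clipped), polygon_area(hull),
               tolerance = 1e-9)
  # idempotence: re-clipping the clipped parts changes nothing
  rp2 <- clip_by_occupied_classes(rp$clipped, r, pts)
  expect_equal(polygon_area(rp2$clipped), polygon_area(rp$clipped),
               tolerance = 1e-9)

  # idempotence also on a mixed-class raster
  g2 <- matrix(0L, 10, 10)
  g2[, 1:5] <- 1L
  g2[, 6:10] <- 2L
  r2 <- class_raster(g2, origin = c(0, 0), cell_m = 10)
  ptsA <- with_local_seed(84, cbind(runif(15, 5, 45), runif(15, 5, 95)))
  hull2 <- convex_hull(rbind(ptsA, c(80, 50)))
  rpA <- clip_by_occupied_classes(hull2, r2, ptsA)
  rpB <- clip_by_occupied_classes(rpA$clipped, r2, ptsA)
  expect_equal(polygon_area(rpB$clipped), polygon_area(rpA$clipped),
               tolerance = 1e-9)
})

test_that("occupied classes cover every occurrence for random scenarios", {
  for (seed in 1:3) {
    g <- matrix(with_local_seed(seed, sample(1:4, 400, replace = TRUE)),
                20, 20)
    r <- class_raster(g, origin = c(0, 0), cell_m = 10)
    pts <- with_local_seed(seed + 10, cbind(runif(40, 1, 199),
                                            runif(40, 1, 199)))
    hull <- convex_hull(pts)
    rp <- clip_by_occupied_classes(hull, r, pts)
    expect_true(all(point_in_polygon(pts, rp)))
    expect_lte(polygon_area(rp$clipped), polygon_area(hull) + 1e-9)
    expect_setequal(rp$occupied_classes,
                    sort(unique(extract_class(r, pts))))
  }
})

test_that("per-taxon range inference skips sparse taxa and is order
           invariant", {
  cfg <- reference_scenario(seed = 11, size = 0.4)
  rs <- generate_records(cfg)
  geo <- filter_geocoded(rs, 40)
  raster <- generate_raster(cfg)
  ranges <- suppressWarnings(infer_ranges(geo, raster,
                                          group_by = "subspecies"))
  expect_true(length(ranges) >= 2)
  for (rp in ranges) {
    expect_lte(polygon_area(rp$clipped),
               polygon_area(rp$hull) * (1 + 1e-9))
  }
  # permutation of record order yields identical polygons
  perm <- with_local_seed(12, geo[sample(nrow(geo)), ])
  perm <- record_set(as.data.frame(perm))
  ranges2 <- suppressWarnings(infer_ranges(perm, raster,
                                           group_by = "subspecies"))
  expect_identical(names(ranges), names(ranges2))
  for (nm in names(ranges)) {
    expect_equal(polygon_area(ranges[[nm]]$clipped),
                 polygon_area(ranges2[[nm]]$clipped), tolerance = 1e-9)
    expect_equal(ranges[[nm]]$hull, ranges2[[nm]]$hull)
  }

  # a label with 2 records is skipped with a warning
  tiny <- geo[1:2, ]
  tiny$voucher_id <- c("RARE01", "RARE02")
  tiny$subspecies <- "rarethon"
  both <- record_set(rbind(as.data.frame(geo), as.data.frame(tiny)))
  suppressWarnings(
    expect_warning(r3 <- infer_ranges(both, raster, group_by = "subspecies"),
                   "rarethon"))
  expect_true("rarethon" %in% attr(r3, "skipped"))
})

test_that("range polygons survive a GeoJSON round trip", {
  g <- matrix(1L, 10, 10)
  r <- class_raster(g, origin = c(-5e5, -5e5), cell_m = 1e5)
  pts <- with_local_seed(85, cbind(runif(10, -4e5, 4e5),
                                   runif(10, -4e5, 4e5)))
  rp <- clip_by_occupied_classes(convex_hull(pts), r, pts, taxon = "demo")
  path <- withr::local_tempfile(fileext = ".geojson")
  ranges_to_geojson(list(demo = rp), path)
  back <- read_geojson_polygons(path)
  expect_named(back, "demo")
  expect_equal(polygon_area(back$demo), polygon_area(rp$clipped),
               tolerance = 1e-4 * polygon_area(rp$clipped))
})
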