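#' Convex hull of occurrence points
#'
#' Minimal convex polygon containing all points (the "minimum bounding
#' geometry" first-pass range estimate). Vertices are returned
#' counter-clockwise, starting at the lowest-y (then lowest-x) vertex, without
#' a repeated closing vertex. Fewer than 3 points, or an all-collinear set, is
#' a degenerate hull and an error.
#'
#' @param xy two-column matrix of projected points (metres).
#' @return two-column matrix of hull vertices.
#' @export
convex_hull <- function(xy) {
  xy <- unique(as.matrix(xy)[, 1:2, drop = FALSE])
  if (nrow(xy) < 3) stop("degenerate hull: fewer than 3 distinct points")
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  hull <- xy[idx, , drop = FALSE]
  if (nrow(hull) < 3 || abs(signed_area(hull)) < .Machine$double.eps) {
    stop("degenerate hull: points are collinear")
  }
  if (signed_area(hull) < 0) hull <- hull[nrow(hull):1, , drop = FALSE]
  start <- order(hull[, 2], hull[, 1])[1]
  hull <- hull[c(start:nrow(hull), seq_len(start - 1)), , drop = FALSE]
  dimnames(hull) <- list(NULL, c("x", "y"))
  hull
}

# shoelace; positive for counter-clockwise rings
signed_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a polygon or polygon set
#'
#' @param poly a two-column vertex matrix, or a list of such matrices
#'   (multipart polygon).
#' @return area in square metres.
#' @export
polygon_area <- function(poly) {
  if (is.list(poly) && !is.matrix(poly)) {
    return(sum(vapply(poly, polygon_area, numeric(1))))
  }
  abs(signed_area(as.matrix(poly)))
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle.
# Returns a vertex matrix (possibly with 0 rows).
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      prev <- pts[if (i == 1) n else i - 1, ]
      cin <- inside(cur)
      pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  lerp_x <- function(p, q, x0) {
    t <- (x0 - p[1]) / (q[1] - p[1])
    c(x0, p[2] + t * (q[2] - p[2]))
  }
  lerp_y <- function(p, q, y0) {
    t <- (y0 - p[2]) / (q[2] - p[2])
    c(p[1] + t * (q[1] - p[1]), y0)
  }
  pts <- as.matrix(poly)
  pts <- clip_edge(pts, function(p) p[1] >= xmin,
                   function(p, q) lerp_x(p, q, xmin))
  pts <- clip_edge(pts, function(p) p[1] <= xmax,
                   function(p, q) lerp_x(p, q, xmax))
  pts <- clip_edge(pts, function(p) p[2] >= ymin,
                   function(p, q) lerp_y(p, q, ymin))
  pts <- clip_edge(pts, function(p) p[2] <= ymax,
                   function(p, q) lerp_y(p, q, ymax))
  if (nrow(pts) > 0) dimnames(pts) <- list(NULL, c("x", "y"))
  pts
}

#' Clip a range hull to the environmental classes its occurrences occupy
#'
#' The occupied classes are those extracted at the occurrence points
#' (nodata excluded); the clipped range is the intersection of the hull with
#' the union of all raster cells whose class is occupied. Exact cell-polygon
#' geometry is used (no rasterised approximation): horizontal runs of occupied
#' cells are merged into rectangles and each rectangle is intersected with the
#' hull. Every occurrence point lies in the clipped polygon (its own cell is
#' occupied by construction) and the clipped area never exceeds the hull area.
#'
#' @param hull a convex-hull vertex matrix (see [convex_hull]), or a list of
#'   polygon parts to be re-clipped (the operation is idempotent).
#' @param raster a [class_raster]; every occurrence point must fall in its
#'   extent.
#' @param points two-column matrix of the occurrence points (projected
#'   metres).
#' @param taxon label stored on the result.
#' @return a `range_polygon`: list with `taxon`, `hull`, `clipped` (list of
#'   convex parts), `occupied_classes`.
#' @export
clip_by_occupied_classes <- function(hull, raster, points, taxon = NA_character_) {
  points <- as.matrix(points)
  cls <- extract_class(raster, points)
  occupied <- sort(setdiff(unique(cls), raster$nodata))
  if (length(occupied) == 0) {
    stop("no occurrence falls in a data cell: occupied class set is empty")
  }
  parts <- if (is.list(hull) && !is.matrix(hull)) hull else list(as.matrix(hull))
  hull_poly <- if (is.list(hull) && !is.matrix(hull)) NULL else as.matrix(hull)

  g <- raster$grid
  nr <- nrow(g)
  nc <- ncol(g)
  cell <- raster$cell_m
  x0 <- raster$origin[1]
  y0 <- raster$origin[2]

  bbox <- do.call(rbind, parts)
  cmin <- max(1L, floor((min(bbox[, 1]) - x0) / cell) + 1)
  cmax <- min(nc, floor((max(bbox[, 1]) - x0) / cell) + 1)
  rfb_min <- max(1L, floor((min(bbox[, 2]) - y0) / cell) + 1)
  rfb_max <- min(nr, floor((max(bbox[, 2]) - y0) / cell) + 1)
  if (cmax < cmin || rfb_max < rfb_min) {
    stop("hull does not intersect the raster extent")
  }

  clipped <- list()
  for (rfb in rfb_min:rfb_max) {
    row <- nr - rfb + 1
    occ <- g[row, cmin:cmax] %in% occupied
    if (!any(occ)) next
    # merge horizontal runs of occupied cells into single rectangles
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ylo <- y0 + (rfb - 1) * cell
    yhi <- ylo + cell
    for (k in which(r$values)) {
      xlo <- x0 + (cmin + starts[k] - 2) * cell
      xhi <- x0 + (cmin + ends[k] - 1) * cell
      for (part in parts) {
        piece <- clip_polygon_rect(part, xlo, xhi, ylo, yhi)
        if (nrow(piece) >= 3 && polygon_area(piece) > 0) {
          clipped[[length(clipped) + 1L]] <- piece
        }
      }
    }
  }
  if (length(clipped) == 0) {
    stop("clipping removed the entire hull; no occupied-class cell intersects it")
  }
  structure(
    list(taxon = taxon, hull = hull_poly, clipped = clipped,
         occupied_classes = occupied),
    class = "range_polygon"
  )
}

#' @export
print.range_polygon <- function(x, ...) {
  cat("Range polygon", if (!is.na(x$taxon)) paste0("for '", x$taxon, "'") else "",
      "\n")
  if (!is.null(x$hull)) {
    cat(sprintf("  hull: %d vertices, area %.0f km^2\n", nrow(x$hull),
                polygon_area(x$hull) / 1e6))
  }
  cat(sprintf("  clipped: %d part(s), area %.0f km^2\n", length(x$clipped),
              polygon_area(x$clipped) / 1e6))
  cat("  occupied classes:", paste(x$occupied_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Infer range polygons per taxon
#'
#' For each level of the grouping field (subspecies or morph group) with at
#' least three non-collinear localities, builds the convex hull of its
#' occurrence points and clips it to the environmental classes occupied by
#' those points. Taxa with too few or collinear points are skipped with a
#' warning. Results are independent of record order.
#'
#' @param rs a geocoded [record_set].
#' @param raster a [class_raster] (already at the analysis resolution; see
#'   [block_downsample]).
#' @param group_by `"subspecies"` or `"morph_group"`.
#' @param params projection parameters.
#' @return named list of `range_polygon` objects; skipped taxa are recorded in
#'   attribute `skipped`.
#' @export
infer_ranges <- function(rs, raster, group_by = c("subspecies", "morph_group"),
                         params = albers_africa()) {
  group_by <- match.arg(group_by)
  labels <- rs[[group_by]]
  keep <- labels != ""
  rs2 <- rs[keep, , drop = FALSE]
  labels <- labels[keep]
  pp <- project_points(rs2$latitude, rs2$longitude, params)
  xy <- as.matrix(pp)[, 1:2, drop = FALSE]
  out <- list()
  skipped <- character(0)
  for (lab in sort(unique(labels))) {
    pts <- unique(xy[labels == lab, , drop = FALSE])
    rp <- tryCatch({
      hull <- convex_hull(pts)
      clip_by_occupied_classes(hull, raster, pts, taxon = lab)
    }, error = function(e) {
      warning("taxon '", lab, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(rp)) skipped <- c(skipped, lab) else out[[lab]] <- rp
  }
  attr(out, "skipped") <- skipped
  out
}

#' Export range polygons as GeoJSON
#'
#' Polygons are inverse-projected to WGS84; each `range_polygon` becomes a
#' MultiPolygon feature with its taxon and occupied classes as properties.
#'
#' @param ranges a `range_polygon` or list of them.
#' @param path output path.
#' @param params projection parameters used for the inverse mapping.
#' @return `path`, invisibly.
#' @export
ranges_to_geojson <- function(ranges, path, params = albers_africa()) {
  if (inherits(ranges, "range_polygon")) ranges <- list(ranges)
  feats <- lapply(ranges, function(rp) {
    polys <- lapply(rp$clipped, function(part) {
      ring <- rbind(part, part[1, , drop = FALSE])
      ll <- inverse_project(ring, params)
      list(lapply(seq_len(nrow(ll)), function(i) {
        c(round(ll$lon[i], 8), round(ll$lat[i], 8))
      }))
    })
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = polys),
         properties = list(
           taxon = rp$taxon,
           occupied_classes = rp$occupied_classes,
           area_km2 = polygon_area(rp$clipped) / 1e6
         ))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons back from a GeoJSON file
#'
#' Reads Polygon/MultiPolygon features written by [ranges_to_geojson] and
#' re-projects them into the analysis plane.
#'
#' @param path GeoJSON file path.
#' @param params projection parameters.
#' @return named list (by feature `taxon` property where present) of lists of
#'   polygon part matrices (projected metres).
#' @export
read_geojson_polygons <- function(path, params = albers_africa()) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (f in gj$features) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type)
    )
    parts <- lapply(rings, function(poly) {
      ring <- poly[[1]]  # outer ring only
      ll <- do.call(rbind, lapply(ring, function(c2) {
        c(lon = c2[[1]], lat = c2[[2]])
      }))
      xy <- project_points(ll[, "lat"], ll[, "lon"], params)
      m <- as.matrix(xy)[, 1:2, drop = FALSE]
      if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    })
    nm <- f$properties$taxon
    if (is.null(nm)) nm <- paste0("feature", length(out) + 1)
    out[[nm]] <- parts
  }
  out
}
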