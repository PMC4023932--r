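#' Point-in-polygon test
#'
#' Even-odd (ray casting) containment test with an inclusive boundary: points
#' lying on an edge or vertex count as inside, a conservative convention for
#' "collected within the extent" statements. For a multipart polygon (a list
#' of vertex matrices) a point is inside when it is inside any part.
#'
#' @param xy two-column matrix of query points.
#' @param poly a polygon vertex matrix (unclosed ring) or a list of parts; a
#'   `range_polygon` is tested against its clipped parts.
#' @param tol boundary snap tolerance in coordinate units (default 1e-9 of
#'   the polygon scale).
#' @return logical vector, one per query point.
#' @export
point_in_polygon <- function(xy, poly, tol = NULL) {
  xy <- matrix(as.numeric(as.matrix(xy)), ncol = 2)
  if (inherits(poly, "range_polygon")) poly <- poly$clipped
  parts <- if (is.list(poly) && !is.matrix(poly)) poly else list(poly)
  parts <- lapply(parts, function(p) {
    p <- as.matrix(p)
    if (!is.numeric(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop("invalid polygon: need a numeric matrix of at least 3 vertices")
    }
    if (any(!is.finite(p))) stop("invalid polygon: non-finite vertex")
    p
  })
  if (is.null(tol)) {
    scale <- max(abs(do.call(rbind, parts)), 1)
    tol <- 1e-9 * scale
  }
  inside <- rep(FALSE, nrow(xy))
  for (p in parts) {
    todo <- which(!inside)
    if (length(todo) == 0) break
    inside[todo] <- .pip_one_part(xy[todo, , drop = FALSE], p, tol)
  }
  inside
}

.pip_one_part <- function(xy, poly, tol) {
  n <- nrow(poly)
  px <- poly[, 1]
  py <- poly[, 2]
  qx <- poly[c(2:n, 1), 1]
  qy <- poly[c(2:n, 1), 2]
  vapply(seq_len(nrow(xy)), function(k) {
    x <- xy[k, 1]
    y <- xy[k, 2]
    # boundary: distance from point to each edge segment
    dx <- qx - px
    dy <- qy - py
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0, ((x - px) * dx + (y - py) * dy) / len2, 0)
    t <- pmin(1, pmax(0, t))
    d2 <- (px + t * dx - x)^2 + (py + t * dy - y)^2
    if (any(d2 <= tol^2)) return(TRUE)
    # even-odd ray cast toward +x
    crosses <- ((py > y) != (qy > y)) &
      (x < px + (y - py) * (qx - px) / (qy - py))
    sum(crosses) %% 2 == 1
  }, logical(1))
}

#' Overlay imperfect-mimic records on a range polygon
#'
#' Selects the geocoded records whose morph is an imperfect mimic (see
#' [is_imperfect]), projects them, and counts how many fall inside versus
#' outside the given polygon (typically the union of the transitional
#' subspecies' clipped ranges: a point inside any part counts once). Reports a
#' per-morph breakdown and the voucher ids of outside specimens. The counting
#' unit is specimens.
#'
#' @param rs a geocoded [record_set].
#' @param reg a [morph_registry].
#' @param poly polygon set: a `range_polygon`, a list of them, or a list of
#'   vertex matrices.
#' @param polygon_label label stored on the result.
#' @param params projection parameters.
#' @return an `overlay_result`: list with `polygon_label`, `n_points`,
#'   `n_inside`, `n_outside`, `outside_ids`, `per_morph` (data frame morph,
#'   inside, outside).
#' @export
overlay_imperfect <- function(rs, reg = default_morph_registry(), poly,
                              polygon_label = "transitional",
                              params = albers_africa()) {
  sel <- is_imperfect(rs$morph, reg) &
    !is.na(rs$latitude) & !is.na(rs$longitude)
  sub <- rs[sel, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no geocoded imperfect-mimic records in this record set")
    return(structure(
      list(polygon_label = polygon_label, n_points = 0L, n_inside = 0L,
           n_outside = 0L, outside_ids = character(0),
           per_morph = data.frame(morph = character(), inside = integer(),
                                  outside = integer())),
      class = "overlay_result"))
  }
  parts <- .polygon_parts(poly)
  pp <- project_points(sub$latitude, sub$longitude, params)
  inside <- point_in_polygon(as.matrix(pp)[, 1:2, drop = FALSE], parts)
  morphs <- normalise_morph(sub$morph)
  per <- do.call(rbind, lapply(sort(unique(morphs)), function(m) {
    data.frame(morph = m,
               inside = sum(inside & morphs == m),
               outside = sum(!inside & morphs == m))
  }))
  rownames(per) <- NULL
  structure(
    list(polygon_label = polygon_label,
         n_points = nrow(sub),
         n_inside = sum(inside),
         n_outside = sum(!inside),
         outside_ids = sub$voucher_id[!inside],
         per_morph = per),
    class = "overlay_result"
  )
}

# normalise the many accepted polygon inputs to a flat list of vertex matrices
.polygon_parts <- function(poly) {
  if (inherits(poly, "range_polygon")) return(poly$clipped)
  if (is.matrix(poly)) return(list(poly))
  if (is.list(poly)) {
    parts <- lapply(poly, function(p) {
      if (inherits(p, "range_polygon")) p$clipped else list(as.matrix(p))
    })
    return(do.call(c, parts))
  }
  stop("cannot interpret polygon input")
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf(
    "Overlay vs '%s': %d imperfect specimen(s), %d inside, %d outside\n",
    x$polygon_label, x$n_points, x$n_inside, x$n_outside))
  if (x$n_points > 0) {
    cat(sprintf("  inside fraction: %.3f\n", x$n_inside / x$n_points))
  }
  invisible(x)
}

#' Write an overlay result to JSON and CSV
#'
#' @param res an `overlay_result`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the result.
#' @export
write_overlay <- function(res, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(polygon_label = res$polygon_label, n_points = res$n_points,
           n_inside = res$n_inside, n_outside = res$n_outside,
           inside_fraction = if (res$n_points > 0) {
             res$n_inside / res$n_points
           } else NA,
           outside_ids = res$outside_ids, per_morph = res$per_morph),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(res$per_morph, csv_path, row.names = FALSE)
  }
  invisible(res)
}

#' Permutation test of the imperfect/polygon association
#'
#' An optional significance test beyond the raw overlay counts: shuffles the
#' imperfect/ordinary morph labels over the geocoded records and recomputes
#' the inside count, giving a permutation p-value for the observed
#' concentration of imperfect mimics inside the polygon.
#'
#' @param rs a geocoded [record_set].
#' @param reg a [morph_registry].
#' @param poly polygon set (see [overlay_imperfect]).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed.
#' @param params projection parameters.
#' @return list with `observed_inside`, `n_imperfect`, `p_value`,
#'   `null_inside` (the permutation distribution).
#' @export
overlay_permutation_test <- function(rs, reg = default_morph_registry(), poly,
                                     n_perm = 999, seed = 1,
                                     params = albers_africa()) {
  keep <- !is.na(rs$latitude) & !is.na(rs$longitude)
  sub <- rs[keep, , drop = FALSE]
  imp <- is_imperfect(sub$morph, reg)
  if (!any(imp)) stop("no imperfect-mimic records to test")
  parts <- .polygon_parts(poly)
  pp <- project_points(sub$latitude, sub$longitude, params)
  inside <- point_in_polygon(as.matrix(pp)[, 1:2, drop = FALSE], parts)
  obs <- sum(inside & imp)
  k <- sum(imp)
  null_inside <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(inside[sample.int(length(inside), k)])
    }, numeric(1))
  })
  p <- (1 + sum(null_inside >= obs)) / (n_perm + 1)
  list(observed_inside = obs, n_imperfect = k, p_value = p,
       null_inside = null_inside)
}
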