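#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and afterwards restores the caller's
#' RNG state, so that package randomness never perturbs global state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Axis-aligned rectangle polygon
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds (metres).
#' @return a 4-vertex counter-clockwise polygon matrix.
#' @export
rect_poly <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# TRUE when a polygon is an axis-aligned rectangle (fast containment path)
is_rect <- function(poly) {
  poly <- as.matrix(poly)
  nrow(poly) == 4 && length(unique(poly[, 1])) == 2 &&
    length(unique(poly[, 2])) == 2
}

# containment with a rectangle fast path; boundary-inclusive
contains_points <- function(poly, xy) {
  xy <- as.matrix(xy)
  if (is_rect(poly)) {
    xs <- range(poly[, 1])
    ys <- range(poly[, 2])
    return(xy[, 1] >= xs[1] & xy[, 1] <= xs[2] &
             xy[, 2] >= ys[1] & xy[, 2] <= ys[2])
  }
  point_in_polygon(xy, poly)
}

# uniform points inside a polygon, by rejection from its bounding box
runif_in_polygon <- function(n, poly) {
  poly <- as.matrix(poly)
  xs <- range(poly[, 1])
  ys <- range(poly[, 2])
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, xs[1], xs[2]), stats::runif(m, ys[1], ys[2]))
    keep <- contains_points(poly, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# uniform points in the extent but outside a polygon, by rejection
runif_outside_polygon <- function(n, extent, poly) {
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 16)
    cand <- cbind(stats::runif(m, extent[1], extent[2]),
                  stats::runif(m, extent[3], extent[4]))
    keep <- !contains_points(poly, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
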