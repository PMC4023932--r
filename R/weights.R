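#' Binary distance-band spatial weights
#'
#' Neighbourhood structure over projected points: `j` is a neighbour of `i`
#' when the planar Euclidean distance d(i, j) is at most `band_m` (closed
#' band) and `j != i`; when `include_self = TRUE` each point is additionally
#' its own neighbour with weight 1, the convention required by the Gi*
#' statistic (Moran's I uses `include_self = FALSE`). Weights are binary:
#' membership is weight 1. Coincident points (d = 0, different indices) are
#' neighbours.
#'
#' @param xy two-column matrix of projected coordinates in metres (n >= 2).
#' @param band_m positive distance threshold in metres.
#' @param include_self logical; self-neighbour convention (see above).
#' @return a `spatial_weights` object: list with `n`, `band_m`,
#'   `include_self` and `neighbours` (a list of integer vectors).
#' @export
build_weights <- function(xy, band_m, include_self = FALSE) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 points to build weights")
  stopifnot(is.numeric(band_m), length(band_m) == 1L, band_m > 0)
  d <- as.matrix(stats::dist(xy[, 1:2, drop = FALSE]))
  nb <- lapply(seq_len(n), function(i) {
    js <- which(d[i, ] <= band_m)
    if (!include_self) js <- js[js != i]
    as.integer(js)
  })
  structure(
    list(n = n, band_m = band_m, include_self = include_self,
         neighbours = nb),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  deg <- lengths(x$neighbours)
  cat("Spatial weights: binary distance band\n")
  cat(sprintf("  n = %d, band = %.0f m, include_self = %s\n",
              x$n, x$band_m, x$include_self))
  cat(sprintf("  neighbours per point: min %d, mean %.1f, max %d\n",
              min(deg), mean(deg), max(deg)))
  invisible(x)
}

# dense 0/1 matrix form, used by summaries and by tests
weights_matrix <- function(w) {
  m <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) m[i, w$neighbours[[i]]] <- 1
  m
}
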