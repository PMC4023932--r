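#' Aggregate specimen records to unique collection localities
#'
#' Specimens are pinned individuals; the spatial analyses work on unique
#' collection sites carrying the number of specimens collected there. Projected
#' coordinates are rounded to 1 m before grouping, so sites that differ only
#' by sub-metre numerical noise collapse to one locality. Values always sum to
#' the number of input records.
#'
#' @param rs a geocoded [record_set] (apply [filter_geocoded] first).
#' @param pp a `projected_points` matrix aligned with `rs` (from
#'   [project_records]); computed from `rs` when omitted.
#' @return a `locality_set`: data frame with columns `x`, `y` (metres),
#'   `value` (specimen count) and a list-column `members` of voucher ids.
#' @export
aggregate_localities <- function(rs, pp = NULL) {
  if (is.null(pp)) pp <- project_records(rs)
  xy <- round(as.matrix(pp)[, 1:2, drop = FALSE])
  key <- paste(xy[, 1], xy[, 2], sep = "|")
  idx <- split(seq_len(nrow(xy)), factor(key, levels = unique(key)))
  out <- data.frame(
    x = vapply(idx, function(i) xy[i[1], 1], numeric(1)),
    y = vapply(idx, function(i) xy[i[1], 2], numeric(1)),
    value = lengths(idx)
  )
  out$members <- I(lapply(idx, function(i) rs$voucher_id[i]))
  rownames(out) <- NULL
  class(out) <- c("locality_set", "data.frame")
  out
}

#' Circle-count point density surface
#'
#' The density at locality i is the total specimen count (or site count, if
#' `weight_by_count = FALSE`) over all localities within `radius_m` of i,
#' itself included. The default radius of 280 km reproduces the circle size of
#' the collection's published sampling-density heatmap.
#'
#' @param localities a `locality_set` (see [aggregate_localities]).
#' @param radius_m positive circle radius in metres (default 280,000).
#' @param weight_by_count logical; weight each locality by its specimen count
#'   (default) or count sites only.
#' @return numeric vector of density counts, one per locality.
#' @export
point_density <- function(localities, radius_m = 280000,
                          weight_by_count = TRUE) {
  stopifnot(radius_m > 0)
  xy <- as.matrix(localities[, c("x", "y")])
  v <- if (weight_by_count) localities$value else rep(1, nrow(xy))
  d <- as.matrix(stats::dist(xy))
  as.numeric((d <= radius_m) %*% v)
}

#' Equal-frequency quantile classes
#'
#' Partitions values into `k` classes of (as near as possible) equal
#' frequency by rank; ties are assigned to the lower class, so equal values
#' always share a class. When fewer than `k` distinct values exist, empty
#' classes are merged away with a warning and the remaining classes renumbered
#' consecutively. The per-class share is the fraction of the total of `values`
#' falling in each class (the "proportion of density variation" shown in
#' heatmap keys).
#'
#' @param values numeric vector.
#' @param k number of classes (default 7, the heatmap's class count).
#' @return list with `class` (integer ids 1..k'), `share` (named numeric,
#'   sums to 1) and `breaks` (upper class bounds).
#' @export
quantile_classes <- function(values, k = 7) {
  stopifnot(k >= 2, length(values) >= 1)
  n <- length(values)
  s <- sort(values)
  breaks <- s[ceiling(n * seq_len(k) / k)]
  cls <- vapply(values, function(v) which(v <= breaks)[1L], integer(1))
  kept <- sort(unique(cls))
  if (length(kept) < k) {
    warning("fewer than ", k, " distinct classes; merged to ", length(kept))
    cls <- match(cls, kept)
  }
  total <- sum(values)
  share <- vapply(seq_along(sort(unique(cls))), function(c) {
    if (total == 0) 1 / length(unique(cls)) else sum(values[cls == c]) / total
  }, numeric(1))
  names(share) <- as.character(seq_along(share))
  list(class = cls, share = share,
       breaks = breaks[seq_len(max(cls))])
}

#' Full sampling-effort hot-spot pipeline
#'
#' Composition of the collection-density analysis: project the geocoded
#' records, aggregate them to unique localities, choose the neighbourhood
#' scale with [incremental_moran] over the locality specimen counts, and score
#' the localities with [gi_star] on those counts at the chosen band, labelling
#' hot/cold localities at `z_threshold` standard deviations. The Gi*
#' neighbourhood sum of specimen counts is exactly the circle-count density at
#' the chosen scale, so this is a hot-spot analysis of the sampling-density
#' layer with a calibrated permutation null (feeding Gi* an already-smoothed
#' density attribute instead would break that null: neighbouring values share
#' most of their circles, and far more than the nominal fraction of localities
#' exceeds any z cut even on completely random data). The 280-km circle-count
#' density surface and its quantile classes are computed alongside as the
#' heatmap product.
#'
#' @param rs a geocoded [record_set].
#' @param radius_m density circle radius in metres (default 280,000).
#' @param k_quantiles number of density quantile classes (default 7).
#' @param z_threshold hot/cold z cut (default 2.5).
#' @param bands optional band sweep (metres); default [default_band_sweep].
#' @param params projection parameters.
#' @param weight_by_count passed to [point_density].
#' @return list with `localities` (with added columns `density`, `z`, `label`,
#'   `class`), `gi` (the [gi_star] result), `moran` (the [incremental_moran]
#'   result), `band_m`, `density_share`.
#' @export
hotspot_pipeline <- function(rs, radius_m = 280000, k_quantiles = 7,
                             z_threshold = 2.5, bands = NULL,
                             params = albers_africa(),
                             weight_by_count = TRUE) {
  if (nrow(rs) == 0) stop("no geocoded records to analyse")
  pp <- project_records(rs, params)
  loc <- aggregate_localities(rs, pp)
  if (nrow(loc) < 4) stop("need at least 4 distinct localities")
  inc <- incremental_moran(loc, bands = bands)
  dens <- point_density(loc, radius_m = radius_m,
                        weight_by_count = weight_by_count)
  w <- build_weights(as.matrix(loc[, c("x", "y")]), inc$best_band,
                     include_self = TRUE)
  gi <- gi_star(loc$value, w, threshold_sd = z_threshold)
  qc <- quantile_classes(dens, k = k_quantiles)
  loc$density <- dens
  loc$z <- gi$z_scores
  loc$label <- gi$labels
  loc$class <- qc$class
  list(localities = loc, gi = gi, moran = inc, band_m = inc$best_band,
       density_share = qc$share)
}
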