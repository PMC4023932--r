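#' Global Moran's I with analytical z-score
#'
#' Moran's I over a value x_i observed at n locations with binary symmetric
#' weights w_ij (no self-neighbours):
#'
#'   I = (n / W) * sum_ij w_ij z_i z_j / sum_i z_i^2,   z_i = x_i - mean(x)
#'
#' with W = sum_ij w_ij. Its expectation under the null is E(I) = -1/(n-1).
#' The variance is computed under the randomisation assumption (the usual GIS
#' default: the observed values are permuted over the fixed locations), using
#' the moments S1 = 1/2 sum_ij (w_ij + w_ji)^2, S2 = sum_i (w_i. + w_.i)^2 and
#' the sample kurtosis b2 = n sum z^4 / (sum z^2)^2:
#'
#' ```
#'   Var(I) = [ n((n^2 - 3n + 3) S1 - n S2 + 3 W^2)
#'              - b2((n^2 - n) S1 - 2n S2 + 6 W^2) ]
#'            / [ (n-1)(n-2)(n-3) W^2 ]  -  E(I)^2
#' ```
#'
#' The normality-assumption variance is available via `assumption =
#' "normality"`. The z-score is (I - E(I)) / sqrt(Var(I)).
#'
#' @param values numeric vector of the analysed attribute (e.g. specimens per
#'   locality); must not be constant.
#' @param w a [build_weights] result with `include_self = FALSE` and n >= 4.
#' @param assumption `"randomisation"` (default) or `"normality"`.
#' @return a `moran_result`: list with `I`, `expected_I`, `variance`, `z`,
#'   `n`, `W`, `S1`, `S2`, `b2`, `band_m`, `assumption`.
#' @export
morans_i <- function(values, w, assumption = c("randomisation", "normality")) {
  assumption <- match.arg(assumption)
  stopifnot(inherits(w, "spatial_weights"))
  if (w$include_self) {
    stop("Moran's I requires weights built with include_self = FALSE")
  }
  n <- w$n
  if (length(values) != n) stop("values length must equal number of points")
  if (n < 4) stop("need at least 4 points for the analytical variance")
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("zero variance: all values equal, Moran's I undefined")

  deg <- lengths(w$neighbours)
  W <- sum(deg)
  if (W == 0) stop("empty weights: no point has a neighbour at this band")
  # binary symmetric weights: (w_ij + w_ji)^2 = 4 on each directed link,
  # row sums equal column sums
  S1 <- 2 * W
  S2 <- 4 * sum(deg^2)

  cross <- sum(vapply(seq_len(n), function(i) {
    z[i] * sum(z[w$neighbours[[i]]])
  }, numeric(1)))
  I <- (n / W) * cross / m2
  EI <- -1 / (n - 1)
  b2 <- n * sum(z^4) / m2^2

  if (assumption == "randomisation") {
    num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
      b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)
    V <- num / ((n - 1) * (n - 2) * (n - 3) * W^2) - EI^2
  } else {
    V <- (n^2 * S1 - n * S2 + 3 * W^2) / (W^2 * (n^2 - 1)) - EI^2
  }
  zscore <- if (V > 0) (I - EI) / sqrt(V) else NA_real_
  structure(
    list(I = I, expected_I = EI, variance = V, z = zscore, n = n, W = W,
         S1 = S1, S2 = S2, b2 = b2, band_m = w$band_m,
         assumption = assumption),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (E[I] = %.4f, var = %.3g, z = %.3f; n = %d, band = %.0f m, %s)\n",
    x$I, x$expected_I, x$variance, x$z, x$n, x$band_m, x$assumption))
  invisible(x)
}

#' Incremental distance-band selection by Moran's I z-score
#'
#' Computes Moran's I at each candidate band and selects the band with the
#' highest z-score: the distance at which clustering of the analysed values is
#' strongest, used as the neighbourhood scale for the subsequent density and
#' hot-spot analyses. Bands that yield an empty weights structure are skipped
#' with a warning; ties go to the smallest band.
#'
#' @param localities data frame with columns `x`, `y` (projected metres) and
#'   `value` (see [aggregate_localities]).
#' @param bands ascending numeric vector of distance bands in metres; `NULL`
#'   selects the default sweep of [default_band_sweep].
#' @param assumption passed to [morans_i].
#' @return list with `results` (a data frame: band_m, I, expected_I, variance,
#'   z), `best_band` (metres) and `per_band` (the `moran_result` objects).
#' @export
incremental_moran <- function(localities, bands = NULL,
                              assumption = "randomisation") {
  xy <- as.matrix(localities[, c("x", "y")])
  values <- localities$value
  if (is.null(bands)) bands <- default_band_sweep(xy)
  stopifnot(length(bands) >= 1, all(diff(bands) >= 0))
  per_band <- vector("list", length(bands))
  for (k in seq_along(bands)) {
    res <- tryCatch({
      w <- build_weights(xy, bands[k], include_self = FALSE)
      morans_i(values, w, assumption = assumption)
    }, error = function(e) {
      warning(sprintf("band %.0f m skipped: %s", bands[k],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    per_band[[k]] <- res
  }
  ok <- !vapply(per_band, is.null, logical(1))
  if (!any(ok)) stop("all distance bands were skipped; no usable weights")
  results <- data.frame(
    band_m = bands[ok],
    I = vapply(per_band[ok], `[[`, numeric(1), "I"),
    expected_I = vapply(per_band[ok], `[[`, numeric(1), "expected_I"),
    variance = vapply(per_band[ok], `[[`, numeric(1), "variance"),
    z = vapply(per_band[ok], `[[`, numeric(1), "z")
  )
  best <- results$band_m[which.max(results$z)]  # which.max takes first = smallest band on ties
  list(results = results, best_band = best, per_band = per_band[ok])
}

#' Default distance-band sweep
#'
#' Ten equal steps from the smallest band at which every point has at least
#' one neighbour (the maximum nearest-neighbour distance) up to half the
#' maximum pairwise distance.
#'
#' @param xy two-column matrix of projected coordinates.
#' @param n_bands number of bands (default 10).
#' @return numeric vector of ascending bands in metres.
#' @export
default_band_sweep <- function(xy, n_bands = 10) {
  d <- as.matrix(stats::dist(as.matrix(xy)))
  diag(d) <- Inf
  lo <- max(apply(d, 1, min))
  hi <- max(d[is.finite(d)]) / 2
  if (hi <= lo) hi <- lo * 2
  seq(lo, hi, length.out = n_bands)
}
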