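#' Getis-Ord Gi* hot-spot statistic
#'
#' For each location i, Gi* compares the sum of the attribute over i's
#' neighbourhood (including i itself) to its expectation under a random
#' arrangement of the observed values, standardised to a z-score:
#'
#'   Gi* = [ sum_j w_ij x_j - Xbar sum_j w_ij ] /
#'         ( S * sqrt( [ n sum_j w_ij^2 - (sum_j w_ij)^2 ] / (n - 1) ) )
#'
#' with Xbar = mean(x) and S = sqrt(mean(x^2) - Xbar^2) (population standard
#' deviation). With binary weights, sum_j w_ij^2 = sum_j w_ij. A location is
#' labelled `hot` when its z exceeds `threshold_sd` standard deviations and
#' `cold` below `-threshold_sd`; the default 2.5 matches the density-outlier
#' cut used in the sampling-effort maps. No multiple-testing correction is
#' applied by default; `fdr = TRUE` instead labels at a Benjamini-Hochberg
#' adjusted two-sided normal p < 0.05 (an optional stricter mode).
#'
#' @param values numeric attribute per location (e.g. density counts); must
#'   not be constant.
#' @param w a [build_weights] result with `include_self = TRUE` and n >= 3.
#' @param threshold_sd positive z cut for labelling (default 2.5).
#' @param fdr logical; apply Benjamini-Hochberg labelling instead of the
#'   plain z cut (default `FALSE`).
#' @return a `gistar_result`: list with `z_scores`, `labels`
#'   (`hot`/`cold`/`none`), `threshold_sd`, `band_m`.
#' @export
gi_star <- function(values, w, threshold_sd = 2.5, fdr = FALSE) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!w$include_self) {
    stop("Gi* requires weights built with include_self = TRUE (w_ii = 1)")
  }
  n <- w$n
  if (length(values) != n) stop("values length must equal number of points")
  if (n < 3) stop("need at least 3 points")
  stopifnot(threshold_sd > 0)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  if (S == 0) stop("zero variance: all values equal, Gi* undefined")

  z <- numeric(n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    nb <- w$neighbours[[i]]
    sw <- length(nb)           # sum_j w_ij, binary incl. self
    swx <- sum(values[nb])
    den2 <- (n * sw - sw^2) / (n - 1)   # sum w^2 = sw for binary weights
    if (den2 <= 0) {
      # neighbourhood is the entire data set: numerator and denominator vanish
      z[i] <- 0
      degenerate <- TRUE
    } else {
      z[i] <- (swx - xbar * sw) / (S * sqrt(den2))
    }
  }
  if (degenerate) {
    warning("some neighbourhoods span the entire data set; their z set to 0")
  }
  if (fdr) {
    p <- 2 * stats::pnorm(-abs(z))
    padj <- stats::p.adjust(p, method = "BH")
    labels <- ifelse(padj < 0.05 & z > 0, "hot",
                     ifelse(padj < 0.05 & z < 0, "cold", "none"))
  } else {
    labels <- ifelse(z > threshold_sd, "hot",
                     ifelse(z < -threshold_sd, "cold", "none"))
  }
  structure(
    list(z_scores = z, labels = labels, threshold_sd = threshold_sd,
         band_m = w$band_m, fdr = fdr),
    class = "gistar_result"
  )
}

#' @export
print.gistar_result <- function(x, ...) {
  cat(sprintf(
    "Gi* hot-spot result: %d locations, band = %.0f m, threshold = %.1f sd%s\n",
    length(x$z_scores), x$band_m, x$threshold_sd,
    if (isTRUE(x$fdr)) " (BH-adjusted)" else ""))
  cat(sprintf("  hot: %d, cold: %d, none: %d\n",
              sum(x$labels == "hot"), sum(x$labels == "cold"),
              sum(x$labels == "none")))
  invisible(x)
}
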