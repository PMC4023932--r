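#' Albers equal-area conic projection for Africa
#'
#' The analyses run in a projected plane so that distances are metres and
#' areas are preserved (equal-area is essential both for density circles and
#' for range-polygon areas). The conventional Africa configuration is used:
#' central meridian 25 degrees E, standard parallels 20 degrees N and 23
#' degrees S, latitude of origin 0, no false easting/northing. The projection
#' is the spherical Albers equal-area conic on the authalic sphere
#' (R = 6371007.181 m), which preserves area exactly on that sphere.
#'
#' @param lat0 latitude of origin (degrees).
#' @param lon0 central meridian (degrees).
#' @param sp1,sp2 standard parallels (degrees).
#' @param radius_m sphere radius in metres.
#' @return a parameter object of class `albers_params`.
#' @export
albers_africa <- function(lat0 = 0, lon0 = 25, sp1 = 20, sp2 = -23,
                          radius_m = 6371007.181) {
  stopifnot(abs(sp1) < 90, abs(sp2) < 90, sp1 != -sp2)
  p1 <- sp1 * pi / 180
  p2 <- sp2 * pi / 180
  n <- (sin(p1) + sin(p2)) / 2
  C <- cos(p1)^2 + 2 * n * sin(p1)
  rho0 <- radius_m * sqrt(C - 2 * n * sin(lat0 * pi / 180)) / n
  structure(
    list(lat0 = lat0, lon0 = lon0, sp1 = sp1, sp2 = sp2,
         radius_m = radius_m, n = n, C = C, rho0 = rho0,
         crs_tag = sprintf("aea:lat0=%g;lon0=%g;sp1=%g;sp2=%g;R=%.3f",
                           lat0, lon0, sp1, sp2, radius_m)),
    class = "albers_params"
  )
}

#' Project geographic coordinates to the equal-area plane
#'
#' @param lat,lon numeric vectors of WGS84 decimal degrees; `lat` in
#'   (-90, 90), `lon` in `[-180, 180]`. Latitudes at a pole are rejected (the
#'   projection is singular there).
#' @param params an [albers_africa] parameter object.
#' @return a `projected_points` object: a two-column matrix (`x`, `y`, metres)
#'   with attributes `crs_tag` and `source_index`.
#' @export
project_points <- function(lat, lon, params = albers_africa()) {
  stopifnot(length(lat) == length(lon))
  if (any(is.na(lat) | is.na(lon))) {
    stop("cannot project missing coordinates; filter records first")
  }
  if (any(abs(lat) >= 90)) stop("latitude at or beyond a pole")
  if (any(abs(lon) > 180)) stop("longitude outside [-180, 180]")
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  lam0 <- params$lon0 * pi / 180
  dl <- lam - lam0
  # wrap to (-pi, pi] so points either side of the antimeridian stay finite
  dl <- atan2(sin(dl), cos(dl))
  rho <- params$radius_m * sqrt(params$C - 2 * params$n * sin(phi)) / params$n
  theta <- params$n * dl
  xy <- cbind(x = rho * sin(theta), y = params$rho0 - rho * cos(theta))
  structure(xy,
            crs_tag = params$crs_tag,
            params = params,
            source_index = seq_along(lat),
            class = c("projected_points", class(xy)))
}

#' Inverse projection back to geographic coordinates
#'
#' @param xy two-column matrix of projected metres.
#' @param params an [albers_africa] parameter object (defaults to the one the
#'   points were projected with, if present).
#' @return data frame with columns `lat`, `lon` (degrees).
#' @export
inverse_project <- function(xy, params = NULL) {
  if (is.null(params)) params <- attr(xy, "params")
  if (is.null(params)) params <- albers_africa()
  xy <- as.matrix(xy)
  x <- xy[, 1]
  y <- xy[, 2]
  # when the cone constant n is negative (standard parallels straddling the
  # equator, as in the Africa configuration) the signs of x, y and rho0 are
  # reversed before taking rho and theta
  sgn <- if (params$n < 0) -1 else 1
  rho <- sgn * sqrt(x^2 + (params$rho0 - y)^2)
  theta <- atan2(sgn * x, sgn * (params$rho0 - y))
  s <- (params$C - (rho * params$n / params$radius_m)^2) / (2 * params$n)
  s <- pmin(1, pmax(-1, s))
  phi <- asin(s)
  lam <- params$lon0 * pi / 180 + theta / params$n
  lam <- atan2(sin(lam), cos(lam))
  data.frame(lat = phi * 180 / pi, lon = lam * 180 / pi)
}

#' Project the geocoded records of a record set
#'
#' @param rs a [record_set]; all records must have coordinates (apply
#'   [filter_geocoded] first).
#' @param params an [albers_africa] parameter object.
#' @return a `projected_points` matrix aligned with the rows of `rs`.
#' @export
project_records <- function(rs, params = albers_africa()) {
  project_points(rs$latitude, rs$longitude, params)
}

#' Export projected points as a GeoJSON point layer
#'
#' Coordinates are inverse-projected to WGS84 longitude/latitude as GeoJSON
#' requires; `properties` columns (if given) are attached per feature.
#'
#' @param xy a `projected_points` matrix (or plain two-column matrix plus
#'   `params`).
#' @param path output file path.
#' @param properties optional data frame, one row per point.
#' @param params projection parameters when `xy` carries none.
#' @return `path`, invisibly.
#' @export
points_to_geojson <- function(xy, path, properties = NULL, params = NULL) {
  ll <- inverse_project(xy, params)
  feats <- lapply(seq_len(nrow(ll)), function(i) {
    props <- if (is.null(properties)) {
      stats::setNames(list(), character(0))
    } else {
      as.list(properties[i, , drop = FALSE])
    }
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(round(ll$lon[i], 8),
                                         round(ll$lat[i], 8))),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
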