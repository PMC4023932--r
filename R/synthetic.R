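#' Synthetic collection scenarios
#'
#' The generator emulates the statistical structure the spatial analyses
#' assume, so that every pipeline stage can be exercised and calibrated
#' without the external collection database: spatially clustered collection
#' sites of strongly varying density over a uniform background, per-region
#' female morph compositions (with imperfect-mimic forms concentrated in one
#' designated "transitional" region, leaking outside it with probability
#' `imperfect_leak`), per-site specimen counts, geocode errors drawn uniformly
#' on `[0, 60]` km so the default 40 km filter has bite, and a class-structured
#' environmental raster in which the occurrences occupy only a subset of
#' classes. All randomness flows from the single `seed`.
#'
#' @param seed integer seed driving all draws.
#' @param extent numeric length-4 `c(xmin, xmax, ymin, ymax)` in projected
#'   metres: the window collection sites are placed in.
#' @param n_background number of background (uniform, CSR) collection sites.
#' @param background_mean_extra Poisson mean of extra specimens per background
#'   site (site count = 1 + Poisson).
#' @param clusters list of cluster specs: each a list with `centre` (x, y),
#'   `radius_m`, `n_sites`, `mean_extra` (Poisson mean of extra specimens per
#'   site; oversampled clusters have larger values).
#' @param regions list of region specs, first match wins: each a list with
#'   `polygon` (vertex matrix), `subspecies`, `country`, `morph_freq` (a
#'   named numeric vector of female morph frequencies summing to 1), and
#'   optionally `transitional = TRUE` marking it part of the transitional
#'   area where imperfect morphs belong (several regions may carry the flag;
#'   their polygons must be disjoint).
#' @param imperfect_leak fraction of imperfect-morph specimens placed outside
#'   the transitional area (in `[0, 1]`).
#' @param female_fraction fraction of specimens sexed female.
#' @param error_km_range range of the uniform geocode-error draw (km).
#' @param raster raster spec: list with `extent`, `cell_m`, `nodata` and
#'   `classes` (list of `list(id, polygon)`, first match wins).
#' @param exclusion optional polygon of uninhabitable area (e.g. an arid
#'   block): no collection site is placed inside it, so its raster class
#'   stays unoccupied while convex hulls may still span it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed, extent, n_background,
                             background_mean_extra = 0.5,
                             clusters = list(), regions = list(),
                             imperfect_leak = 0.1,
                             female_fraction = 0.464,
                             error_km_range = c(0, 60),
                             raster = NULL, exclusion = NULL) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            n_background >= 0, imperfect_leak >= 0, imperfect_leak <= 1,
            female_fraction >= 0, female_fraction <= 1)
  for (r in regions) {
    if (abs(sum(r$morph_freq) - 1) > 1e-8) {
      stop("morph frequencies for region '", r$subspecies, "' must sum to 1")
    }
  }
  for (cl in clusters) stopifnot(cl$n_sites >= 0, cl$radius_m > 0)
  structure(
    list(seed = seed, extent = extent, n_background = n_background,
         background_mean_extra = background_mean_extra, clusters = clusters,
         regions = regions,
         imperfect_leak = imperfect_leak, female_fraction = female_fraction,
         error_km_range = error_km_range, raster = raster,
         exclusion = exclusion),
    class = "synthetic_config"
  )
}

#' Transitional-area polygons of a scenario
#'
#' @param cfg a [synthetic_config].
#' @return list of the polygons of regions flagged `transitional`.
#' @export
transitional_polygons <- function(cfg) {
  out <- list()
  for (r in cfg$regions) {
    if (isTRUE(r$transitional)) out[[length(out) + 1L]] <- r$polygon
  }
  out
}

#' Reference scenario
#'
#' The documented configuration that drives the calibration and acceptance
#' suites: a 4000 x 3400 km window with three heavily over-collected clusters
#' of 100 km radius whose centres lie more than 900 km apart (the planted
#' spatial scale is therefore the 200 km disc diameter), over-sampled at
#' 1 + Poisson(3) specimens per site against a uniform background of 250
#' sites at 1 + Poisson(0.3) - echoing, conservatively, the concentration of
#' collecting effort around Lake Victoria; five regions (two transitional
#' sub-regions for ssp. meseres and ssp. polytrophus whose disjoint union
#' hosts the imperfect forms at 30% of female draws, plus western, eastern
#' and island regions) with their own female morph compositions; a leak
#' fraction of 0.1 (about 1 imperfect specimen in 10 collected outside the
#' transitional area, echoing the observed 14 of 145); and a four-class 20 km
#' environmental raster whose central arid block is uninhabitable: no
#' collection site falls in it, so its class must be clipped out of any range
#' hull spanning it.
#'
#' @param seed integer seed.
#' @param size scale multiplier on site counts (1 = default scenario).
#' @return a [synthetic_config].
#' @export
reference_scenario <- function(seed = 42, size = 1) {
  regions <- list(
    list(polygon = rect_poly(3e5, 5.5e5, -3e5, 3e5),
         subspecies = "meseres", country = "Uganda", transitional = TRUE,
         morph_freq = c(hippocoonides = 0.30, cenea = 0.15, meseres = 0.15,
                        trophonius = 0.05, planemoides = 0.05,
                        trimeni = 0.10, lamborni = 0.08, mixtoides = 0.07,
                        "proto-cenea" = 0.05)),
    list(polygon = rect_poly(5.5e5, 8e5, -3e5, 3e5),
         subspecies = "polytrophus", country = "Kenya", transitional = TRUE,
         morph_freq = c(hippocoonides = 0.30, cenea = 0.15, meseres = 0.10,
                        poultoni = 0.08, planemoides = 0.07, trimeni = 0.08,
                        lamborni = 0.07, swynnertoni = 0.05,
                        carpenteri = 0.05, mixtoides = 0.05)),
    list(polygon = rect_poly(-2e6, 3e5, -2e6, 1.4e6),
         subspecies = "dardanus", country = "Cameroon",
         morph_freq = c(hippocoon = 0.45, dionysos = 0.20,
                        planemoides = 0.15, trophonius = 0.10, niobe = 0.05,
                        natalica = 0.05)),
    list(polygon = rect_poly(3e5, 1.6e6, -2e6, 1.4e6),
         subspecies = "tibullus", country = "Tanzania",
         morph_freq = c(hippocoonides = 0.40, cenea = 0.25,
                        trophonius = 0.15, natalica = 0.10, salaami = 0.05,
                        poultoni = 0.05)),
    list(polygon = rect_poly(1.6e6, 2e6, -2e6, 1.4e6),
         subspecies = "meriones", country = "Madagascar",
         morph_freq = c(meriones = 1))
  )
  # central arid block: uninhabitable, so its class has zero occurrences
  # while convex hulls of the surrounding regions still span it
  arid <- rect_poly(6e5, 1.1e6, 6e5, 1.4e6)
  raster <- list(
    extent = c(-2e6, 2e6, -2e6, 1.5e6), cell_m = 20000, nodata = -9999L,
    classes = list(
      list(id = 3L, polygon = arid),                               # arid: unoccupied
      list(id = 2L, polygon = rect_poly(-2e6, 1e5, -2e6, 1.5e6)),  # western forest
      list(id = 4L, polygon = rect_poly(1.6e6, 2e6, -2e6, 1.5e6)), # island
      list(id = 1L, polygon = rect_poly(-2e6, 2e6, -2e6, 1.5e6))   # savanna elsewhere
    )
  )
  synthetic_config(
    seed = seed,
    extent = c(-2e6, 2e6, -2e6, 1.4e6),
    n_background = round(250 * size),
    background_mean_extra = 0.3,
    clusters = list(
      list(centre = c(4.5e5, 0.5e5), radius_m = 100000,   # Lake Victoria
           n_sites = round(100 * size), mean_extra = 3),
      list(centre = c(1.3e6, -4e5), radius_m = 100000,    # east coast
           n_sites = round(100 * size), mean_extra = 3),
      list(centre = c(2.5e5, -1.4e6), radius_m = 100000,  # south
           n_sites = round(100 * size), mean_extra = 3)
    ),
    regions = regions,
    imperfect_leak = 0.1,
    female_fraction = 0.464,
    error_km_range = c(0, 60),
    raster = raster,
    exclusion = arid
  )
}

#' Default distance-band sweep of the reference analysis
#'
#' Round-number bands from 100 to 1000 km in 100 km steps, the sweep an
#' analyst would use at continental extent; the planted 200 km cluster scale
#' lies one band step inside its lower end.
#'
#' @return numeric vector of bands in metres.
#' @export
reference_bands <- function() {
  seq(1e5, 1e6, by = 1e5)
}

#' Generate a synthetic specimen record set
#'
#' Places background sites uniformly on the extent (complete spatial
#' randomness) and cluster sites uniformly in their discs; draws 1 + Poisson
#' specimens per site; sexes each specimen; draws female morphs from the
#' containing region's frequency table (subspecies and country follow the
#' region); then places every imperfect-morph specimen at a collection site
#' inside the transitional area with probability `1 - imperfect_leak` and at
#' a site outside it otherwise (attached to an existing site so the locality
#' structure is preserved, or to a fresh uniform location if the area holds
#' no site), so the inside count of imperfect mimics is exactly
#' Binomial(n, 1 - leak). Geocode errors are drawn per site. Fully
#' reproducible from `cfg$seed`.
#'
#' The returned record set carries a `truth` attribute (data frame with one
#' row per specimen: `site_id`, `cluster` (0 = background), `region`,
#' `imperfect_inside`) for calibration studies.
#'
#' @param cfg a [synthetic_config].
#' @return a [record_set] with coordinates in WGS84 degrees.
#' @export
generate_records <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  params <- albers_africa()
  with_local_seed(cfg$seed, {
    ext <- cfg$extent
    habitable <- function(pts) {
      if (is.null(cfg$exclusion)) rep(TRUE, nrow(pts))
      else !contains_points(cfg$exclusion, pts)
    }
    sites <- matrix(numeric(0), 0, 2)
    cluster_id <- integer(0)
    mean_extra <- numeric(0)
    if (cfg$n_background > 0) {
      bg <- matrix(numeric(0), 0, 2)
      while (nrow(bg) < cfg$n_background) {
        m <- max(2 * (cfg$n_background - nrow(bg)), 16)
        cand <- cbind(stats::runif(m, ext[1], ext[2]),
                      stats::runif(m, ext[3], ext[4]))
        bg <- rbind(bg, cand[habitable(cand), , drop = FALSE])
      }
      sites <- rbind(sites, bg[seq_len(cfg$n_background), , drop = FALSE])
      cluster_id <- c(cluster_id, rep(0L, cfg$n_background))
      mean_extra <- c(mean_extra, rep(cfg$background_mean_extra,
                                      cfg$n_background))
    }
    for (k in seq_along(cfg$clusters)) {
      cl <- cfg$clusters[[k]]
      if (cl$n_sites == 0) next
      pts <- matrix(numeric(0), 0, 2)
      while (nrow(pts) < cl$n_sites) {
        m <- max(2 * (cl$n_sites - nrow(pts)), 16)
        # uniform in the disc: sqrt-radius trick
        r <- cl$radius_m * sqrt(stats::runif(m))
        a <- stats::runif(m, 0, 2 * pi)
        cand <- cbind(cl$centre[1] + r * cos(a), cl$centre[2] + r * sin(a))
        pts <- rbind(pts, cand[habitable(cand), , drop = FALSE])
      }
      sites <- rbind(sites, pts[seq_len(cl$n_sites), , drop = FALSE])
      cluster_id <- c(cluster_id, rep(as.integer(k), cl$n_sites))
      mean_extra <- c(mean_extra, rep(cl$mean_extra, cl$n_sites))
    }
    n_sites <- nrow(sites)
    if (n_sites == 0) stop("config generates no collection sites")
    site_err <- stats::runif(n_sites, cfg$error_km_range[1],
                             cfg$error_km_range[2])
    n_spec_per_site <- 1L + stats::rpois(n_sites, mean_extra)

    site_of <- rep(seq_len(n_sites), n_spec_per_site)
    xy <- sites[site_of, , drop = FALSE]
    n <- length(site_of)
    sex <- ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")

    region_of_point <- function(pts) {
      reg <- rep(NA_integer_, nrow(pts))
      for (k in seq_along(cfg$regions)) {
        todo <- is.na(reg)
        if (!any(todo)) break
        hit <- contains_points(cfg$regions[[k]]$polygon,
                               pts[todo, , drop = FALSE])
        reg[which(todo)[hit]] <- k
      }
      reg
    }
    region <- region_of_point(xy)
    if (any(is.na(region))) {
      warning(sum(is.na(region)),
              " point(s) fall outside every region; labels left empty")
    }

    morph <- rep("", n)
    fem <- which(sex == "female" & !is.na(region))
    for (k in seq_along(cfg$regions)) {
      rows <- fem[region[fem] == k]
      if (length(rows) == 0) next
      freq <- cfg$regions[[k]]$morph_freq
      morph[rows] <- sample(names(freq), length(rows), replace = TRUE,
                            prob = freq)
    }

    # Relocate imperfect-morph specimens in/out of the transitional area.
    # Each such specimen is collected, with probability 1 - leak, at a site
    # inside the transitional union, otherwise at a site outside it; it is
    # attached to an existing collection site there (specimens are collected
    # at collection localities, so the locality structure is preserved) or,
    # if no such site exists, to a fresh uniform location in the area.
    reg0 <- default_morph_registry()
    imp <- which(is_imperfect(morph, reg0))
    imperfect_inside <- rep(NA, n)
    err <- site_err[site_of]
    cluster_of_spec <- rep(cluster_id, n_spec_per_site)
    trans <- transitional_polygons(cfg)
    if (length(imp) > 0 && length(trans) > 0) {
      site_in_trans <- rep(FALSE, n_sites)
      for (tp in trans) site_in_trans <- site_in_trans | contains_points(tp, sites)
      go_inside <- stats::runif(length(imp)) < 1 - cfg$imperfect_leak
      place <- function(rows, pool, fresh_point) {
        if (length(rows) == 0) return()
        if (length(pool) > 0) {
          dest <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
          xy[imp[rows], ] <<- sites[dest, , drop = FALSE]
          err[imp[rows]] <<- site_err[dest]
          site_of[imp[rows]] <<- dest
          cluster_of_spec[imp[rows]] <<- cluster_id[dest]
        } else {
          xy[imp[rows], ] <<- fresh_point(length(rows))
          err[imp[rows]] <<- stats::runif(length(rows), cfg$error_km_range[1],
                                          cfg$error_km_range[2])
          cluster_of_spec[imp[rows]] <<- 0L
        }
      }
      place(which(go_inside), which(site_in_trans), function(m) {
        areas <- vapply(trans, polygon_area, numeric(1))
        part <- sample.int(length(trans), m, replace = TRUE, prob = areas)
        dest <- matrix(0, m, 2)
        for (k in seq_along(trans)) {
          rows <- which(part == k)
          if (length(rows) > 0) dest[rows, ] <- runif_in_polygon(length(rows),
                                                                 trans[[k]])
        }
        dest
      })
      place(which(!go_inside), which(!site_in_trans), function(m) {
        out <- matrix(numeric(0), 0, 2)
        while (nrow(out) < m) {
          cand <- cbind(stats::runif(2 * m, ext[1], ext[2]),
                        stats::runif(2 * m, ext[3], ext[4]))
          in_any <- !habitable(cand)
          for (tp in trans) in_any <- in_any | contains_points(tp, cand)
          out <- rbind(out, cand[!in_any, , drop = FALSE])
        }
        out[seq_len(m), , drop = FALSE]
      })
      imperfect_inside[imp] <- go_inside
      region <- region_of_point(xy)
    }

    ssp <- ifelse(is.na(region), "",
                  vapply(region, function(k) {
                    if (is.na(k)) "" else cfg$regions[[k]]$subspecies
                  }, character(1)))
    country <- ifelse(is.na(region), "",
                      vapply(region, function(k) {
                        if (is.na(k)) "" else cfg$regions[[k]]$country
                      }, character(1)))
    grp <- morph_group_of(morph, reg0)
    grp[is.na(grp) | morph == ""] <- ""

    ll <- inverse_project(xy, params)
    df <- data.frame(
      voucher_id = sprintf("SYN%06d", seq_len(n)),
      sex = sex,
      morph = morph,
      morph_group = grp,
      subspecies = ssp,
      country = country,
      locality = sprintf("synthetic site %d", site_of),
      latitude = ll$lat,
      longitude = ll$lon,
      geocode_error_km = err,
      stringsAsFactors = FALSE
    )
    rs <- record_set(df, provenance = sprintf("synthetic scenario (seed %d)",
                                              cfg$seed))
    attr(rs, "truth") <- data.frame(
      voucher_id = df$voucher_id,
      site_id = site_of,
      cluster = cluster_of_spec,
      region = ifelse(is.na(region), NA_character_,
                      vapply(region, function(k) {
                        if (is.na(k)) NA_character_ else
                          cfg$regions[[k]]$subspecies
                      }, character(1))),
      imperfect_inside = imperfect_inside,
      stringsAsFactors = FALSE
    )
    rs
  })
}

#' Generate the scenario's environmental class raster
#'
#' Each cell takes the id of the first class polygon containing its centre;
#' cells outside every class polygon are nodata. Overlapping class polygons
#' are resolved first-listed-wins.
#'
#' @param cfg a [synthetic_config] with a `raster` spec.
#' @return a [class_raster].
#' @export
generate_raster <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), !is.null(cfg$raster))
  spec <- cfg$raster
  ext <- spec$extent
  cell <- spec$cell_m
  nc <- round((ext[2] - ext[1]) / cell)
  nr <- round((ext[4] - ext[3]) / cell)
  cx <- ext[1] + (seq_len(nc) - 0.5) * cell
  cy <- ext[3] + (seq_len(nr) - 0.5) * cell
  centres <- cbind(rep(cx, times = nr), rep(cy, each = nc))
  cls <- rep(as.integer(spec$nodata), nrow(centres))
  assigned <- rep(FALSE, nrow(centres))
  for (cp in spec$classes) {
    todo <- !assigned
    if (!any(todo)) break
    hit <- contains_points(cp$polygon, centres[todo, , drop = FALSE])
    cls[which(todo)[hit]] <- as.integer(cp$id)
    assigned[which(todo)[hit]] <- TRUE
  }
  # centres were enumerated bottom row first; grid wants row 1 = top
  grid <- matrix(cls, nrow = nr, ncol = nc, byrow = TRUE)
  grid <- grid[nr:1, , drop = FALSE]
  class_raster(grid, origin = c(ext[1], ext[3]), cell_m = cell,
               nodata = spec$nodata)
}

#' Complete spatial randomness point pattern
#'
#' Uniform independent points on a rectangular extent: the null model for
#' hot-spot calibration.
#'
#' @param n number of points (>= 1).
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param seed integer seed.
#' @return n x 2 matrix of projected coordinates.
#' @export
generate_csr <- function(n, extent, seed) {
  stopifnot(n >= 1, length(extent) == 4)
  with_local_seed(seed, {
    cbind(x = stats::runif(n, extent[1], extent[2]),
          y = stats::runif(n, extent[3], extent[4]))
  })
}
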