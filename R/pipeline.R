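#' Run configuration
#'
#' Bundles every tunable of the analysis pipeline with the published defaults:
#' 40 km geocode-error cut, 280 km density radius, 7 quantile classes, 2.5 sd
#' hot-spot threshold, 20 km raster blocks.
#'
#' @param records path to the specimen CSV (written by the `simulate` stage if
#'   absent).
#' @param raster path to the environmental-class ASCII grid.
#' @param outdir output directory for stage artifacts.
#' @param max_error_km geocode filter threshold (km).
#' @param radius_m density circle radius (m).
#' @param k_quantiles density quantile classes.
#' @param z_threshold hot/cold z cut (standard deviations).
#' @param block_m raster block size for downsampling (m).
#' @param bands optional explicit band sweep (m); `NULL` for the default.
#' @param group_by grouping field for range inference.
#' @param overlay_taxa taxa whose clipped ranges form the overlay polygon.
#' @param seed integer seed (used by `simulate`).
#' @param scenario_size size multiplier passed to [reference_scenario].
#' @return a `run_config` list.
#' @export
run_config <- function(records = "records.csv", raster = "raster.asc",
                       outdir = "output", max_error_km = 40,
                       radius_m = 280000, k_quantiles = 7, z_threshold = 2.5,
                       block_m = 20000, bands = NULL,
                       group_by = "subspecies",
                       overlay_taxa = c("meseres", "polytrophus"),
                       seed = 42, scenario_size = 1) {
  stopifnot(max_error_km > 0, radius_m > 0, k_quantiles >= 2,
            z_threshold > 0, block_m > 0)
  structure(
    list(records = records, raster = raster, outdir = outdir,
         max_error_km = max_error_km, radius_m = radius_m,
         k_quantiles = k_quantiles, z_threshold = z_threshold,
         block_m = block_m, bands = bands, group_by = group_by,
         overlay_taxa = overlay_taxa, seed = seed,
         scenario_size = scenario_size),
    class = "run_config"
  )
}

#' Read a run configuration from a key=value file
#'
#' Plain declarative format: one `key = value` per line, `#` comments allowed.
#' Numeric values are parsed; `bands` and `overlay_taxa` may be
#' comma-separated lists. Unknown keys are an error.
#'
#' @param path config file path.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  defaults <- run_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    if (key %in% c("bands", "overlay_taxa")) {
      parts <- trimws(strsplit(val, ",")[[1]])
      num <- suppressWarnings(as.numeric(parts))
      args[[key]] <- if (any(is.na(num))) parts else num
    } else if (key %in% c("records", "raster", "outdir", "group_by")) {
      args[[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("expected a number for key ", key, ", got: ", val)
      args[[key]] <- num
    }
  }
  do.call(run_config, args)
}

# deterministic CSV writer used by every stage
write_stage_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (col in names(df)[num]) df[[col]] <- format_num(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a record CSV and class raster, writing stage
#' artifacts and a machine-readable `manifest.json` (configuration echo,
#' package version, seed, and record counts through every filter) into
#' `cfg$outdir`:
#'
#' * `simulate` - generate the reference scenario's records and raster at
#'   `cfg$seed` and write them to `cfg$records` / `cfg$raster`.
#' * `summarise` - validate, filter, and tabulate records by country, sex,
#'   morph group and subspecies (two-column CSVs).
#' * `hotspots` - band selection, density surface, Gi* labels
#'   (`moran_bands.csv`, `hotspots.csv`, `hotspots.geojson`).
#' * `ranges` - per-taxon clipped range polygons (`ranges.geojson`,
#'   `ranges_summary.csv`).
#' * `overlay` - imperfect-mimic overlay against the union of the
#'   `overlay_taxa` polygons from a prior `ranges` stage (`overlay.json`,
#'   `overlay_per_morph.csv`).
#' * `all` - summarise, hotspots, ranges, overlay in order.
#'
#' Reruns with the same seed and config produce byte-identical tabular
#' outputs. Any stage error is recorded in the manifest before being raised.
#'
#' @param command one of `"simulate"`, `"summarise"`, `"hotspots"`,
#'   `"ranges"`, `"overlay"`, `"all"`.
#' @param cfg a [run_config].
#' @return invisibly, a list of stage results.
#' @export
run_pipeline <- function(command = c("summarise", "hotspots", "ranges",
                                     "overlay", "simulate", "all"),
                         cfg = run_config()) {
  command <- match.arg(command)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    command = command,
    config = cfg[setdiff(names(cfg), NULL)],
    package_version = as.character(utils::packageVersion("mimicmaps")),
    seed = cfg$seed,
    counts = list(),
    status = "running"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  results <- list()
  stages <- switch(command,
    all = c("summarise", "hotspots", "ranges", "overlay"),
    command
  )
  on_fail <- function(e, stage) {
    manifest$status <<- paste0("failed at stage '", stage, "': ",
                               conditionMessage(e))
    write_manifest()
    stop(e)
  }

  for (stage in stages) {
    res <- tryCatch(switch(stage,
      simulate = {
        scen <- reference_scenario(seed = cfg$seed, size = cfg$scenario_size)
        rs <- generate_records(scen)
        write_records(rs, cfg$records)
        r <- generate_raster(scen)
        write_ascii_grid(r, cfg$raster)
        manifest$counts$simulated_records <- nrow(rs)
        list(records = rs, raster = r)
      },
      summarise = {
        rs <- read_records(cfg$records)
        manifest$counts$records_read <- nrow(rs)
        geo <- filter_geocoded(rs, cfg$max_error_km)
        manifest$counts$records_geocoded <- nrow(geo)
        tabs <- list()
        for (by in c("country", "sex", "morph_group", "subspecies")) {
          tab <- tabulate_records(rs, by)
          write_stage_csv(tab, file.path(cfg$outdir,
                                         paste0("counts_by_", by, ".csv")))
          tabs[[by]] <- tab
        }
        tabs
      },
      hotspots = {
        rs <- read_records(cfg$records)
        geo <- filter_geocoded(rs, cfg$max_error_km)
        manifest$counts$records_read <- nrow(rs)
        manifest$counts$records_geocoded <- nrow(geo)
        hp <- hotspot_pipeline(geo, radius_m = cfg$radius_m,
                               k_quantiles = cfg$k_quantiles,
                               z_threshold = cfg$z_threshold,
                               bands = cfg$bands)
        manifest$counts$localities <- nrow(hp$localities)
        manifest$counts$hot_localities <- sum(hp$localities$label == "hot")
        manifest$best_band_m <- hp$band_m
        write_stage_csv(hp$moran$results,
                        file.path(cfg$outdir, "moran_bands.csv"))
        out <- hp$localities
        out$id <- seq_len(nrow(out))
        out <- out[, c("id", "x", "y", "value", "density", "z", "label",
                       "class")]
        write_stage_csv(out, file.path(cfg$outdir, "hotspots.csv"))
        points_to_geojson(as.matrix(hp$localities[, c("x", "y")]),
                          file.path(cfg$outdir, "hotspots.geojson"),
                          properties = out)
        hp
      },
      ranges = {
        rs <- read_records(cfg$records)
        geo <- filter_geocoded(rs, cfg$max_error_km)
        manifest$counts$records_geocoded <- nrow(geo)
        raster <- read_ascii_grid(cfg$raster)
        if (raster$cell_m < cfg$block_m) {
          raster <- block_downsample(raster, cfg$block_m)
        }
        ranges <- suppressWarnings(
          infer_ranges(geo, raster, group_by = cfg$group_by))
        manifest$counts$taxa_with_range <- length(ranges)
        manifest$counts$taxa_skipped <- length(attr(ranges, "skipped"))
        ranges_to_geojson(ranges, file.path(cfg$outdir, "ranges.geojson"))
        summ <- data.frame(
          taxon = names(ranges),
          n_parts = vapply(ranges, function(r) length(r$clipped), integer(1)),
          hull_area_km2 = vapply(ranges, function(r) {
            polygon_area(r$hull) / 1e6
          }, numeric(1)),
          clipped_area_km2 = vapply(ranges, function(r) {
            polygon_area(r$clipped) / 1e6
          }, numeric(1)),
          occupied_classes = vapply(ranges, function(r) {
            paste(r$occupied_classes, collapse = ";")
          }, character(1))
        )
        write_stage_csv(summ, file.path(cfg$outdir, "ranges_summary.csv"))
        ranges
      },
      overlay = {
        gj <- file.path(cfg$outdir, "ranges.geojson")
        if (!file.exists(gj)) {
          stop("overlay requires range artifacts: run the 'ranges' stage ",
               "first (missing ", gj, ")")
        }
        polys <- read_geojson_polygons(gj)
        target <- polys[intersect(cfg$overlay_taxa, names(polys))]
        if (length(target) == 0) {
          stop("none of the overlay taxa (",
               paste(cfg$overlay_taxa, collapse = ", "),
               ") have a range polygon in ", gj)
        }
        parts <- do.call(c, unname(target))
        rs <- read_records(cfg$records)
        geo <- filter_geocoded(rs, cfg$max_error_km)
        res <- overlay_imperfect(geo, default_morph_registry(), parts,
                                 polygon_label = paste(cfg$overlay_taxa,
                                                       collapse = "+"))
        manifest$counts$imperfect_geocoded <- res$n_points
        manifest$counts$imperfect_inside <- res$n_inside
        write_overlay(res, json_path = file.path(cfg$outdir, "overlay.json"),
                      csv_path = file.path(cfg$outdir,
                                           "overlay_per_morph.csv"))
        res
      }
    ), error = function(e) on_fail(e, stage))
    results[[stage]] <- res
  }
  manifest$status <- "ok"
  write_manifest()
  invisible(results)
}
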