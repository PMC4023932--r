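#' Integer class rasters
#'
#' A `class_raster` is a regular grid of integer environmental class ids
#' (ecosystem or isobioclimate classes) with a geotransform: the coordinates
#' of the lower-left corner (`origin`, projected metres), a square cell edge
#' length `cell_m`, and a `nodata` sentinel. The grid matrix is stored with
#' row 1 at the top (north), matching the ASCII-grid file layout. Cells are
#' half-open: a cell covers `[x0, x0 + cell) x [y0, y0 + cell)`, so a point on
#' a shared upper edge belongs to the next cell.
#'
#' @param grid integer matrix, row 1 = northernmost row.
#' @param origin numeric length 2: x and y of the lower-left corner (metres).
#' @param cell_m positive cell edge length in metres.
#' @param nodata integer sentinel for cells without a class (default -9999).
#' @return a `class_raster`.
#' @export
class_raster <- function(grid, origin, cell_m, nodata = -9999L) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  stopifnot(length(origin) == 2, is.numeric(origin), cell_m > 0)
  structure(
    list(grid = grid, origin = as.numeric(origin), cell_m = cell_m,
         nodata = as.integer(nodata)),
    class = "class_raster"
  )
}

#' @export
print.class_raster <- function(x, ...) {
  cls <- setdiff(unique(as.vector(x$grid)), x$nodata)
  cat(sprintf("Class raster: %d x %d cells of %.0f m, origin (%.0f, %.0f)\n",
              nrow(x$grid), ncol(x$grid), x$cell_m, x$origin[1], x$origin[2]))
  cat("  classes:", paste(sort(cls), collapse = ", "),
      " nodata:", x$nodata, "\n")
  invisible(x)
}

#' Read / write ESRI ASCII grid files
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' cell values from north to south.
#'
#' @param path file path.
#' @return [read_ascii_grid]: a [class_raster].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header; need: ", paste(need, collapse = ", "))
  }
  vals <- as.integer(scan(text = paste(lines[-(1:6)], collapse = " "),
                          quiet = TRUE))
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid has ", length(vals), " cells, header promises ",
         hdr$ncols * hdr$nrows)
  }
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  class_raster(grid, origin = c(hdr$xllcorner, hdr$yllcorner),
               cell_m = hdr$cellsize, nodata = hdr$nodata_value)
}

#' @param raster a [class_raster].
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.6f", raster$origin[1]),
    sprintf("yllcorner %.6f", raster$origin[2]),
    sprintf("cellsize %.6f", raster$cell_m),
    sprintf("NODATA_value %d", raster$nodata)
  )
  rows <- apply(g, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Extract the class at point locations
#'
#' Returns the class of the cell containing each point under the half-open
#' cell convention. Points outside the raster extent yield the nodata value
#' with a warning.
#'
#' @param raster a [class_raster].
#' @param xy two-column matrix of projected points (metres).
#' @return integer vector of class ids.
#' @export
extract_class <- function(raster, xy) {
  xy <- as.matrix(xy)
  nr <- nrow(raster$grid)
  nc <- ncol(raster$grid)
  col <- floor((xy[, 1] - raster$origin[1]) / raster$cell_m) + 1
  row_from_bottom <- floor((xy[, 2] - raster$origin[2]) / raster$cell_m) + 1
  row <- nr - row_from_bottom + 1
  out <- rep(raster$nodata, nrow(xy))
  inside <- col >= 1 & col <= nc & row >= 1 & row <= nr
  if (any(!inside)) {
    warning(sum(!inside), " point(s) outside raster extent; returned nodata")
  }
  out[inside] <- raster$grid[cbind(row[inside], col[inside])]
  as.integer(out)
}

#' Downsample a class raster by block majority
#'
#' Aggregates blocks of `block_m / cell_m` cells (anchored at the raster
#' origin) to single cells carrying the majority class of the block; ties go
#' to the smallest class id, and nodata cells are ignored unless the whole
#' block is nodata. The default 20 km blocks match the resolution at which the
#' environmental layers are used for range clipping. Partial blocks at the
#' north/east edges aggregate whatever cells they cover.
#'
#' @param raster a [class_raster].
#' @param block_m output cell size; must be a positive integer multiple of
#'   `raster$cell_m`.
#' @return a coarser [class_raster].
#' @export
block_downsample <- function(raster, block_m = 20000) {
  ratio <- block_m / raster$cell_m
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("block_m must be a positive integer multiple of the cell size")
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(raster)
  g <- raster$grid
  nr <- nrow(g)
  nc <- ncol(g)
  nr2 <- ceiling(nr / ratio)
  nc2 <- ceiling(nc / ratio)
  out <- matrix(raster$nodata, nr2, nc2)
  for (br in seq_len(nr2)) {
    # block rows counted from the bottom so blocks stay anchored at the origin
    rfb <- ((br - 1) * ratio + 1):min(br * ratio, nr)
    rows <- nr - rfb + 1
    for (bc in seq_len(nc2)) {
      cols <- ((bc - 1) * ratio + 1):min(bc * ratio, nc)
      vals <- as.vector(g[rows, cols])
      vals <- vals[vals != raster$nodata]
      out[nr2 - br + 1, bc] <- if (length(vals) == 0) {
        raster$nodata
      } else {
        majority_class(vals)
      }
    }
  }
  class_raster(out, origin = raster$origin, cell_m = block_m,
               nodata = raster$nodata)
}

# majority with ties broken toward the smallest class id
majority_class <- function(vals) {
  tab <- table(vals)
  ids <- as.integer(names(tab))
  winners <- ids[tab == max(tab)]
  min(winners)
}
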