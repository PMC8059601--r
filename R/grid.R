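#' Define an analysis grid
#'
#' A `fire_grid` is a regular raster grid in a projected, metric coordinate
#' system: square cells of side `res` metres, `nrow` rows by `ncol` columns,
#' anchored at the lower-left corner (`xmin`, `ymin`). Grid values are stored
#' as ordinary matrices with row 1 at the top (north) edge, matching the
#' on-disk row order of ASCII grids.
#'
#' @param xmin,ymin Coordinates of the lower-left corner, metres.
#' @param res Cell size, metres.
#' @param nrow,ncol Grid dimensions.
#' @param crs_units Unit of the coordinate system; only `"m"` is supported.
#'   Analyses that need areas (patch delineation, hectare conversion) refuse
#'   non-metric grids.
#' @return An object of class `fire_grid`.
#' @export
fire_grid <- function(xmin, ymin, res, nrow, ncol, crs_units = "m") {
  stopifnot(is.numeric(xmin), is.numeric(ymin), res > 0, nrow >= 1, ncol >= 1)
  structure(
    list(xmin = xmin, ymin = ymin, res = res,
         nrow = as.integer(nrow), ncol = as.integer(ncol),
         crs_units = crs_units),
    class = "fire_grid"
  )
}

#' @export
print.fire_grid <- function(x, ...) {
  cat(sprintf("<fire_grid> %d x %d cells, %g %s resolution, origin (%g, %g)\n",
              x$nrow, x$ncol, x$res, x$crs_units, x$xmin, x$ymin))
  invisible(x)
}

#' Cell centre coordinates of a grid
#'
#' Returns centres in R matrix (column-major) order, so row `i` of the result
#' corresponds to linear cell index `i` of a value matrix on the same grid.
#'
#' @param grid A [fire_grid()].
#' @return A two-column matrix of (x, y) centres with `nrow * ncol` rows.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "fire_grid"))
  rows <- rep(seq_len(grid$nrow), times = grid$ncol)
  cols <- rep(seq_len(grid$ncol), each = grid$nrow)
  cbind(
    x = grid$xmin + (cols - 0.5) * grid$res,
    y = grid$ymin + (grid$nrow - rows + 0.5) * grid$res
  )
}

#' Cell area in hectares
#' @param grid A [fire_grid()].
#' @return Scalar hectares per cell.
#' @export
cell_area_ha <- function(grid) {
  if (!identical(grid$crs_units, "m")) {
    stop("grid must be in a metric (projected) coordinate system")
  }
  grid$res^2 / 1e4
}

grid_extent <- function(grid) {
  c(xmin = grid$xmin, ymin = grid$ymin,
    xmax = grid$xmin + grid$ncol * grid$res,
    ymax = grid$ymin + grid$nrow * grid$res)
}

#' Construct a polygon
#'
#' Polygons are stored as a list of rings; each ring is a two-column numeric
#' matrix of vertices (x, y), implicitly closed. The first ring is the outer
#' boundary; any further rings are holes. Coordinates must be projected
#' (metric); longitude/latitude-looking input is rejected because no
#' reprojection machinery is bundled.
#'
#' @param ... One or more rings (two-column matrices or data frames).
#' @return An object of class `fire_polygon`.
#' @export
fire_polygon <- function(...) {
  rings <- lapply(list(...), function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    storage.mode(r) <- "double"
    colnames(r) <- c("x", "y")
    r
  })
  structure(rings, class = "fire_polygon")
}

#' Axis-aligned rectangle polygon helper
#' @param xmin,ymin,xmax,ymax Rectangle bounds (metres).
#' @return A [fire_polygon()].
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  fire_polygon(rbind(c(xmin, ymin), c(xmax, ymin),
                     c(xmax, ymax), c(xmin, ymax)))
}

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))  # previous vertex
  sum(x[j] * y - x * y[j]) / 2
}

#' Polygon area
#'
#' Outer ring area minus hole areas, by the shoelace formula.
#'
#' @param poly A [fire_polygon()].
#' @return Area in square coordinate units (m^2).
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "fire_polygon"))
  a <- abs(shoelace(poly[[1]]))
  if (length(poly) > 1) {
    a <- a - sum(vapply(poly[-1], function(r) abs(shoelace(r)), numeric(1)))
  }
  a
}

polygon_bbox <- function(poly) {
  xs <- unlist(lapply(poly, function(r) r[, 1]))
  ys <- unlist(lapply(poly, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

looks_geographic <- function(poly) {
  bb <- polygon_bbox(poly)
  all(abs(bb[c("xmin", "xmax")]) <= 360) && all(abs(bb[c("ymin", "ymax")]) <= 90)
}

# Boundary matrix for mgcv::in.out: closed rings separated by NA rows.
poly_boundary_matrix <- function(poly) {
  parts <- lapply(poly, function(r) {
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    r
  })
  out <- parts[[1]]
  if (length(parts) > 1) {
    for (p in parts[-1]) out <- rbind(out, c(NA, NA), p)
  }
  out
}

#' Test points for polygon inclusion
#'
#' Even-odd inclusion test (holes excluded) using `mgcv::in.out`.
#'
#' @param poly A [fire_polygon()].
#' @param pts Two-column matrix of point coordinates.
#' @return Logical vector, `TRUE` for points inside.
#' @export
points_in_polygon <- function(poly, pts) {
  stopifnot(inherits(poly, "fire_polygon"))
  pts <- as.matrix(pts)
  mgcv::in.out(poly_boundary_matrix(poly), pts)
}

#' Rasterize a polygon onto a grid by the cell-centre rule
#'
#' A cell belongs to the polygon exactly when its centre falls inside;
#' this is the unambiguous standard for 30 m burn products.
#'
#' @param poly A [fire_polygon()].
#' @param grid A [fire_grid()].
#' @return Logical matrix of dimension `nrow x ncol`.
#' @export
rasterize_polygon <- function(poly, grid) {
  cc <- cell_centers(grid)
  bb <- polygon_bbox(poly)
  # prefilter by bbox; in.out on the remainder
  cand <- cc[, 1] >= bb["xmin"] & cc[, 1] <= bb["xmax"] &
    cc[, 2] >= bb["ymin"] & cc[, 2] <= bb["ymax"]
  inside <- logical(nrow(cc))
  if (any(cand)) inside[cand] <- points_in_polygon(poly, cc[cand, , drop = FALSE])
  matrix(inside, nrow = grid$nrow, ncol = grid$ncol)
}

#' A raster: values on a grid
#'
#' Thin container pairing a value matrix with its [fire_grid()].
#'
#' @param values Numeric matrix, dimensions matching `grid`.
#' @param grid A [fire_grid()].
#' @return An object of class `fire_raster`.
#' @export
fire_raster <- function(values, grid) {
  values <- as.matrix(values)
  stopifnot(inherits(grid, "fire_grid"),
            nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  structure(list(values = values, grid = grid), class = "fire_raster")
}

#' Nearest-neighbour resampling of a raster onto a target grid
#'
#' Each target cell takes the value of the source cell containing its centre;
#' target cells outside the source extent become `NA`.
#'
#' @param src A [fire_raster()].
#' @param grid Target [fire_grid()].
#' @return Numeric matrix on the target grid.
#' @export
resample_nearest <- function(src, grid) {
  stopifnot(inherits(src, "fire_raster"))
  sg <- src$grid
  cc <- cell_centers(grid)
  col <- floor((cc[, 1] - sg$xmin) / sg$res) + 1L
  row <- sg$nrow - floor((cc[, 2] - sg$ymin) / sg$res)
  ok <- col >= 1L & col <= sg$ncol & row >= 1L & row <= sg$nrow
  out <- rep(NA_real_, nrow(cc))
  out[ok] <- src$values[cbind(row[ok], col[ok])]
  matrix(out, nrow = grid$nrow, ncol = grid$ncol)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows north to south.
#'
#' @param raster A [fire_raster()] or a matrix (with `grid` supplied).
#' @param path Output file path (conventionally `.asc`).
#' @param grid Grid definition when `raster` is a bare matrix.
#' @param nodata No-data sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, grid = NULL, nodata = -9999) {
  if (inherits(raster, "fire_raster")) {
    grid <- raster$grid
    values <- raster$values
  } else {
    stopifnot(inherits(grid, "fire_grid"))
    values <- as.matrix(raster)
  }
  values[is.na(values)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$res),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  utils::write.table(values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return A [fire_raster()]; no-data cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  g <- fire_grid(h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]],
                 h[["nrows"]], h[["ncols"]])
  values <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(values) <- NULL
  nodata <- h[["nodata_value"]]
  values[values == nodata] <- NA_real_
  fire_raster(values, g)
}
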