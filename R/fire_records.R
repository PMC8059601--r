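#' A single fire event
#'
#' Bundles a fire's perimeter, timing and severity surface. Severity is a
#' composite burn index (CBI) raster on its own grid (often finer or coarser
#' than the analysis grid); values outside \[0, 3\] are clipped with a
#' warning, since remotely sensed CBI models can slightly overshoot the
#' field scale.
#'
#' @param fire_id Unique identifier string.
#' @param year Calendar year of the burn.
#' @param ig_date Ignition date (ISO-8601 string or `Date`); alternatively
#'   supply `ignition_doy` directly.
#' @param perimeter A [fire_polygon()] in a projected metric CRS.
#' @param severity A [fire_raster()] of CBI values (0--3).
#' @param ignition_doy Integer day-of-year 1--366; computed from `ig_date`
#'   when omitted.
#' @param area_ha Burned area in hectares; computed from the perimeter when
#'   omitted, and validated against it (0.5% tolerance) when supplied.
#' @return An object of class `fire_event`.
#' @export
fire_event <- function(fire_id, year, ig_date = NULL, perimeter, severity,
                       ignition_doy = NULL, area_ha = NULL) {
  stopifnot(inherits(perimeter, "fire_polygon"),
            inherits(severity, "fire_raster"))
  if (looks_geographic(perimeter)) {
    stop("perimeter of fire ", fire_id, " looks geographic (lon/lat); ",
         "reproject inputs to a metric CRS first")
  }
  if (is.null(ignition_doy)) {
    if (is.null(ig_date)) stop("supply ig_date or ignition_doy for fire ", fire_id)
    d <- as.Date(ig_date)
    if (is.na(d)) stop("unparseable ignition date for fire ", fire_id, ": ", ig_date)
    ignition_doy <- as.integer(format(d, "%j"))
  }
  if (ignition_doy < 1L || ignition_doy > 366L) {
    stop("ignition_doy out of range for fire ", fire_id)
  }
  poly_ha <- polygon_area(perimeter) / 1e4
  if (is.null(area_ha)) {
    area_ha <- poly_ha
  } else if (abs(area_ha - poly_ha) > 0.005 * poly_ha) {
    stop(sprintf("area_ha (%.1f) of fire %s differs from polygon area (%.1f) by >0.5%%",
                 area_ha, fire_id, poly_ha))
  }
  v <- severity$values
  n_out <- sum(v < 0 | v > 3, na.rm = TRUE)
  if (n_out > 0) {
    warning(sprintf("fire %s: %d severity values outside [0, 3] clipped", fire_id, n_out))
    severity$values <- pmin(pmax(v, 0), 3)
  }
  structure(
    list(fire_id = as.character(fire_id), year = as.integer(year),
         ignition_doy = as.integer(ignition_doy), perimeter = perimeter,
         severity = severity, area_ha = area_ha),
    class = "fire_event"
  )
}

#' An ordered collection of fire events on a common analysis grid
#'
#' Events are kept sorted chronologically by (year, ignition day-of-year,
#' fire id), so downstream trait construction is invariant to input order.
#'
#' @param events List of [fire_event()] objects.
#' @param record_start,record_end First and last calendar year of the record
#'   window (e.g. 1985 and 2018 for an MTBS-style record).
#' @param grid The analysis [fire_grid()].
#' @return An object of class `fire_record_set`.
#' @export
fire_record_set <- function(events, record_start, record_end, grid) {
  stopifnot(inherits(grid, "fire_grid"), record_start <= record_end)
  years <- vapply(events, function(e) e$year, integer(1))
  if (length(events)) {
    if (record_start > min(years) || record_end < max(years)) {
      stop("record window [", record_start, ", ", record_end,
           "] does not contain all event years")
    }
    doys <- vapply(events, function(e) e$ignition_doy, integer(1))
    ids <- vapply(events, function(e) e$fire_id, character(1))
    events <- events[order(years, doys, ids)]
  }
  structure(
    list(events = events, record_start = as.integer(record_start),
         record_end = as.integer(record_end), grid = grid),
    class = "fire_record_set"
  )
}

#' @export
print.fire_record_set <- function(x, ...) {
  cat(sprintf("<fire_record_set> %d events, record %d-%d\n",
              length(x$events), x$record_start, x$record_end))
  invisible(x)
}

#' Number of events in a record set
#' @param x A [fire_record_set()].
#' @param ... Unused.
#' @export
length.fire_record_set <- function(x) length(x$events)

geojson_polygon_to_fire_polygon <- function(geometry) {
  if (identical(geometry$type, "Polygon")) {
    rings <- geometry$coordinates
  } else if (identical(geometry$type, "MultiPolygon")) {
    # flatten: first ring of each part is an outer ring; holes follow it.
    rings <- do.call(c, geometry$coordinates)
  } else {
    stop("unsupported GeoJSON geometry type: ", geometry$type)
  }
  do.call(fire_polygon, lapply(rings, function(r) {
    do.call(rbind, lapply(r, function(p) as.numeric(p[1:2])))
  }))
}

fire_polygon_to_geojson <- function(poly) {
  list(type = "Polygon",
       coordinates = lapply(unclass(poly), function(r) {
         if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
         lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
       }))
}

#' Read fire perimeters and severity rasters into a record set
#'
#' Perimeters come from a GeoJSON FeatureCollection with properties
#' `fire_id` (string), `year` (integer) and `ig_date` (ISO-8601 date).
#' Severity rasters are ESRI ASCII grids named `<fire_id>.asc` under
#' `severity_dir`. Events outside the record window are dropped with a
#' warning; a missing severity raster is an error naming the fire.
#'
#' @param perimeter_path GeoJSON file of fire perimeters.
#' @param severity_dir Directory of per-fire CBI severity grids.
#' @param record_start,record_end Record window years.
#' @param grid Analysis [fire_grid()]; when `NULL`, a 30 m grid spanning the
#'   union of perimeter bounding boxes is constructed.
#' @return A [fire_record_set()].
#' @export
read_fires <- function(perimeter_path, severity_dir, record_start, record_end,
                       grid = NULL) {
  gj <- jsonlite::fromJSON(perimeter_path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  events <- list()
  for (f in gj$features) {
    pr <- f$properties
    if (is.null(pr$fire_id) || is.null(pr$year)) {
      stop("feature missing fire_id or year property")
    }
    year <- as.integer(pr$year)
    if (year < record_start || year > record_end) {
      warning(sprintf("fire %s (year %d) outside record window; dropped",
                      pr$fire_id, year))
      next
    }
    sev_path <- file.path(severity_dir, paste0(pr$fire_id, ".asc"))
    if (!file.exists(sev_path)) {
      stop("missing severity raster for fire ", pr$fire_id, ": ", sev_path)
    }
    events[[length(events) + 1L]] <- fire_event(
      fire_id = pr$fire_id, year = year, ig_date = pr$ig_date,
      perimeter = geojson_polygon_to_fire_polygon(f$geometry),
      severity = read_ascii_grid(sev_path),
      area_ha = if (!is.null(pr$area_ha)) as.numeric(pr$area_ha)
    )
  }
  if (is.null(grid)) {
    bbs <- lapply(events, function(e) polygon_bbox(e$perimeter))
    if (!length(bbs)) stop("no events and no grid supplied")
    xmin <- min(vapply(bbs, `[[`, numeric(1), "xmin"))
    ymin <- min(vapply(bbs, `[[`, numeric(1), "ymin"))
    xmax <- max(vapply(bbs, `[[`, numeric(1), "xmax"))
    ymax <- max(vapply(bbs, `[[`, numeric(1), "ymax"))
    grid <- fire_grid(xmin, ymin, 30,
                      ceiling((ymax - ymin) / 30), ceiling((xmax - xmin) / 30))
  }
  fire_record_set(events, record_start, record_end, grid)
}

#' Write a record set to disk in the layout [read_fires()] reads
#'
#' Produces `perimeters.geojson`, `severity/<fire_id>.asc` and a plain-text
#' `meta.txt` (record window and grid definition) under `dir`.
#'
#' @param records A [fire_record_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fires <- function(records, dir) {
  dir.create(file.path(dir, "severity"), recursive = TRUE, showWarnings = FALSE)
  features <- lapply(records$events, function(e) {
    list(type = "Feature",
         properties = list(fire_id = e$fire_id, year = e$year,
                           ig_date = doy_to_date(e$year, e$ignition_doy),
                           area_ha = e$area_ha),
         geometry = fire_polygon_to_geojson(e$perimeter))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       file.path(dir, "perimeters.geojson"),
                       auto_unbox = TRUE, digits = NA)
  for (e in records$events) {
    write_ascii_grid(e$severity, file.path(dir, "severity", paste0(e$fire_id, ".asc")))
  }
  g <- records$grid
  writeLines(c(
    sprintf("record_start %d", records$record_start),
    sprintf("record_end %d", records$record_end),
    sprintf("grid %.10g %.10g %.10g %d %d", g$xmin, g$ymin, g$res, g$nrow, g$ncol)
  ), file.path(dir, "meta.txt"))
  invisible(dir)
}

#' Read a record set written by [write_fires()]
#' @param dir Directory holding `perimeters.geojson`, `severity/`, `meta.txt`.
#' @return A [fire_record_set()].
#' @export
read_fire_dir <- function(dir) {
  meta <- strsplit(readLines(file.path(dir, "meta.txt")), "\\s+")
  kv <- stats::setNames(lapply(meta, `[`, -1L), vapply(meta, `[[`, "", 1L))
  g <- as.numeric(kv$grid)
  read_fires(file.path(dir, "perimeters.geojson"), file.path(dir, "severity"),
             as.integer(kv$record_start), as.integer(kv$record_end),
             grid = fire_grid(g[1], g[2], g[3], g[4], g[5]))
}

doy_to_date <- function(year, doy) {
  format(as.Date(doy - 1, origin = paste0(year, "-01-01")), "%Y-%m-%d")
}

#' Keep only large fires
#'
#' MTBS-style records contain only large fires; the conventional cutoff is
#' 404 ha (1000 acres), applied as a strict inequality (area > threshold).
#'
#' @param records A [fire_record_set()].
#' @param min_area_ha Threshold in hectares (default 404).
#' @return A filtered [fire_record_set()]; reports the number dropped.
#' @export
filter_large_fires <- function(records, min_area_ha = 404) {
  stopifnot(inherits(records, "fire_record_set"))
  if (min_area_ha < 0) stop("min_area_ha must be non-negative")
  keep <- vapply(records$events, function(e) e$area_ha > min_area_ha, logical(1))
  n_drop <- sum(!keep)
  if (n_drop > 0) message(n_drop, " fire(s) at or below ", min_area_ha, " ha dropped")
  records$events <- records$events[keep]
  records
}

#' A landscape unit (e.g. a watershed)
#'
#' @param unit_id Identifier string.
#' @param geometry A [fire_polygon()].
#' @param parent_id Identifier of the coarser unit this one nests in (used
#'   as the varying-intercept group in the drivers model).
#' @param forest_fraction Fraction of the unit under forest cover, 0--1.
#' @param flammable_mask Optional logical matrix on the analysis grid;
#'   `TRUE` cells are flammable and evaluated.
#' @return An object of class `landscape_unit`.
#' @export
landscape_unit <- function(unit_id, geometry, parent_id = NA_character_,
                           forest_fraction = 1, flammable_mask = NULL) {
  stopifnot(inherits(geometry, "fire_polygon"),
            forest_fraction >= 0, forest_fraction <= 1)
  structure(
    list(unit_id = as.character(unit_id), geometry = geometry,
         parent_id = as.character(parent_id),
         forest_fraction = forest_fraction, flammable_mask = flammable_mask),
    class = "landscape_unit"
  )
}

#' Drop units with little forest cover
#'
#' Severity estimated from imagery is only reliable in forests, so units
#' below a forest-cover fraction are excluded (strict `<` comparison;
#' default cutoff 0.5).
#'
#' @param units List of [landscape_unit()] objects.
#' @param min_fraction Minimum forest fraction retained.
#' @return Filtered list of units.
#' @export
filter_units_by_forest <- function(units, min_fraction = 0.5) {
  keep <- vapply(units, function(u) u$forest_fraction >= min_fraction, logical(1))
  if (!any(keep)) warning("no units meet the forest-cover threshold")
  units[keep]
}

#' Read landscape units from GeoJSON
#'
#' Expects properties `unit_id` and optionally `parent_id`,
#' `forest_fraction`.
#'
#' @param path GeoJSON FeatureCollection of unit polygons.
#' @return List of [landscape_unit()] objects.
#' @export
read_units <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    pr <- f$properties
    landscape_unit(
      unit_id = pr$unit_id,
      geometry = geojson_polygon_to_fire_polygon(f$geometry),
      parent_id = if (is.null(pr$parent_id)) NA_character_ else pr$parent_id,
      forest_fraction = if (is.null(pr$forest_fraction)) 1 else pr$forest_fraction
    )
  })
}

#' Rasterize one fire event onto the analysis grid
#'
#' The burn mask follows the cell-centre rule; severity is resampled to the
#' grid by nearest neighbour and masked to the perimeter (no-data outside).
#'
#' @param event A [fire_event()].
#' @param grid Target [fire_grid()].
#' @return List with logical `burn_mask` and numeric `severity` matrices.
#' @export
rasterize_event <- function(event, grid) {
  mask <- rasterize_polygon(event$perimeter, grid)
  if (!any(mask)) {
    warning("fire ", event$fire_id, " does not overlap the grid")
    return(list(burn_mask = mask,
                severity = matrix(NA_real_, grid$nrow, grid$ncol)))
  }
  sev <- resample_nearest(event$severity, grid)
  sev[!mask] <- NA_real_
  list(burn_mask = mask, severity = sev)
}
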