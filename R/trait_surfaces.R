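#' Recency weights over a pixel's fire history
#'
#' Fire-history traits are averaged with geometrically decaying weights by
#' event order (not elapsed time, to avoid confounding the weighting with
#' the frequency trait itself). The k-th most recent value gets raw weight
#' `(1 - decay)^(k - 1)`, normalized to sum to one. `decay = 0` weights all
#' events equally, `decay = 0.5` halves the weight of each prior event, and
#' `decay = 1` keeps only the most recent event.
#'
#' @param n_events Number of events (>= 1), most recent first.
#' @param decay Decay rate in \[0, 1\]; default 0.5.
#' @return Numeric vector of weights summing to 1, most recent first.
#' @export
recency_weights <- function(n_events, decay = 0.5) {
  stopifnot(n_events >= 1)
  if (decay < 0 || decay > 1) stop("decay must be in [0, 1]")
  w <- (1 - decay)^(seq_len(n_events) - 1)  # 0^0 = 1 covers decay = 1
  w / sum(w)
}

# Round x to the nearest multiple of step, ties to even (banker's rounding,
# inherited from base round()). Applied after weighted averaging.
round_to <- function(x, step) round(x / step) * step

#' Weighted fire-return-interval trait for one pixel
#'
#' Intervals are the differences between successive burn years, plus the two
#' open intervals against the record's first and final year. They are
#' ordered most-recent-first -- (record_end - y_n), (y_n - y_{n-1}), ...,
#' (y_1 - record_start) -- so the current regime state dominates under
#' recency weighting, then averaged with [recency_weights()] and rounded to
#' whole years. The result is a minimum-frequency estimate: the record
#' window truncates intervals at both ends.
#'
#' @param burn_years Calendar years of burns at this pixel (any order).
#' @param record_start,record_end Record window years.
#' @param decay Recency decay rate.
#' @param precision Rounding step in years (default 1).
#' @return Weighted mean interval, years.
#' @export
fri_trait <- function(burn_years, record_start, record_end, decay = 0.5,
                      precision = 1) {
  stopifnot(length(burn_years) >= 1,
            all(burn_years >= record_start), all(burn_years <= record_end))
  y <- sort(as.numeric(burn_years))
  intervals <- c(record_end - y[length(y)], rev(diff(y)), y[1] - record_start)
  w <- recency_weights(length(intervals), decay)
  round_to(sum(w * intervals), precision)
}

#' Weighted burn-season trait for one pixel
#'
#' Ignition day-of-year is mapped to `cos(2 * pi * (doy - 1) / 365)` so the
#' calendar wraps (day 1 and day 366 coincide at cosine 1), then
#' recency-weighted and rounded to the nearest tenth.
#'
#' @param ignition_doys Days of year, most recent first.
#' @param decay Recency decay rate.
#' @param precision Rounding step in cosine units (default 0.1).
#' @return Weighted mean cosine of ignition date, in \[-1, 1\].
#' @export
season_trait <- function(ignition_doys, decay = 0.5, precision = 0.1) {
  stopifnot(length(ignition_doys) >= 1,
            all(ignition_doys >= 1), all(ignition_doys <= 366))
  v <- cos(2 * pi * (ignition_doys - 1) / 365)
  w <- recency_weights(length(v), decay)
  round_to(sum(w * v), precision)
}

#' Weighted burn-severity trait for one pixel
#'
#' Recency-weighted mean composite burn index, rounded to the nearest
#' 0.5 CBI.
#'
#' @param cbis CBI values in \[0, 3\], most recent first.
#' @param decay Recency decay rate.
#' @param precision Rounding step in CBI units (default 0.5).
#' @return Weighted mean CBI in \[0, 3\].
#' @export
severity_trait <- function(cbis, decay = 0.5, precision = 0.5) {
  stopifnot(length(cbis) >= 1, all(cbis >= 0), all(cbis <= 3))
  w <- recency_weights(length(cbis), decay)
  round_to(sum(w * cbis), precision)
}

# Default CBI class breaks: unchanged [0, 0.1), low [0.1, 1.25),
# moderate [1.25, 2.25), high [2.25, 3].
cbi_class_breaks <- c(0.1, 1.25, 2.25)

# 8-connectivity component labelling of equal-valued cells on a grid.
# cls: integer matrix, NA cells ignored. Returns integer label matrix.
label_components <- function(cls) {
  nr <- nrow(cls); nc <- ncol(cls)
  idx <- which(!is.na(cls))
  if (!length(idx)) return(matrix(NA_integer_, nr, nc))
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- row + s[1]; c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    i <- idx[ok]
    same <- !is.na(cls[j]) & cls[j] == cls[i]
    if (any(same)) edges[[length(edges) + 1L]] <- cbind(i[same], j[same])
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  memb <- igraph::components(g)$membership
  out <- matrix(NA_integer_, nr, nc)
  out[idx] <- memb[idx]
  out
}

#' Delineate severity patches for one fire and assign log patch sizes
#'
#' The severity surface is classified into unchanged, low, moderate and high
#' CBI classes; connected components are found within each class using
#' 8-connectivity (diagonals connect); and each burned cell is assigned the
#' natural log of the hectare area of the component containing it.
#'
#' @param severity CBI matrix on `grid` (one event).
#' @param grid A metric [fire_grid()].
#' @param mask Optional logical burn mask; cells outside it are ignored.
#' @param class_breaks Ascending CBI thresholds splitting the four classes.
#' @param precision Rounding step in log-hectares; `NULL` leaves values
#'   unrounded (as used when rounding is deferred until after recency
#'   weighting).
#' @return Matrix of ln(patch area in ha) for evaluated cells, `NA` elsewhere.
#' @export
delineate_patches <- function(severity, grid, mask = NULL,
                              class_breaks = cbi_class_breaks,
                              precision = NULL) {
  if (!identical(grid$crs_units, "m")) {
    stop("patch delineation requires a metric grid")
  }
  cls <- matrix(findInterval(severity, class_breaks), nrow(severity), ncol(severity))
  cls[is.na(severity)] <- NA_integer_
  if (!is.null(mask)) cls[!mask] <- NA_integer_
  lab <- label_components(cls)
  sizes <- table(lab)
  out <- matrix(NA_real_, nrow(severity), ncol(severity))
  ok <- !is.na(lab)
  out[ok] <- log(as.numeric(sizes[as.character(lab[ok])]) * cell_area_ha(grid))
  if (!is.null(precision)) out <- round_to(out, precision)
  out
}

#' Trait precisions
#'
#' Default discretization steps bounding the size of the fire-history
#' "species" table: whole years for frequency, 0.5 CBI for severity, 0.1
#' cosine units for season, and 0.1 log-hectares for patch size.
#'
#' @param fri,severity,season,patch Rounding steps per trait.
#' @return Named list of precisions.
#' @export
trait_precisions <- function(fri = 1, severity = 0.5, season = 0.1, patch = 0.1) {
  list(fri = fri, severity = severity, season = season, patch = patch)
}

#' Build the four fire-regime trait surfaces
#'
#' Assembles each pixel's fire history from the rasterized events
#' (most-recent-first; events are re-sorted internally so the result is
#' invariant to input order) and computes the recency-weighted frequency,
#' severity, season and patch-size traits. Rounding to each trait's
#' precision happens after weighting. Never-burned pixels carry the
#' record-length fire-return interval (a minimum estimate), severity 0 (no
#' vegetation change) and missing season/patch (no event to characterize);
#' the missing traits are handled downstream by the Gower distance.
#'
#' @param records A [fire_record_set()].
#' @param grid Analysis grid; defaults to the record set's grid.
#' @param decay Recency decay rate (default 0.5).
#' @param precisions See [trait_precisions()].
#' @param class_breaks CBI class breaks for patch delineation.
#' @param unburned_fri Fire-return interval assigned to never-burned pixels;
#'   defaults to `record_end - record_start`.
#' @return An object of class `trait_stack`: matrices `fri`, `severity`,
#'   `season`, `patch` plus the grid, decay, window, precisions and the
#'   fixed patch-size range used for Gower scaling.
#' @export
build_trait_stack <- function(records, grid = records$grid, decay = 0.5,
                              precisions = trait_precisions(),
                              class_breaks = cbi_class_breaks,
                              unburned_fri = NULL) {
  stopifnot(inherits(records, "fire_record_set"))
  if (is.null(unburned_fri)) unburned_fri <- records$record_end - records$record_start
  nr <- grid$nrow; nc <- grid$ncol
  ev <- records$events  # already sorted chronologically

  cells <- integer(0); ev_id <- integer(0); sev <- numeric(0); patch <- numeric(0)
  for (i in seq_along(ev)) {
    ras <- rasterize_event(ev[[i]], grid)
    p <- delineate_patches(ras$severity, grid, mask = ras$burn_mask,
                           class_breaks = class_breaks, precision = NULL)
    ix <- which(ras$burn_mask)
    cells <- c(cells, ix)
    ev_id <- c(ev_id, rep(i, length(ix)))
    sev <- c(sev, ras$severity[ix])
    patch <- c(patch, p[ix])
  }

  fri_m <- matrix(round_to(unburned_fri, precisions$fri), nr, nc)
  sev_m <- matrix(0, nr, nc)
  sea_m <- matrix(NA_real_, nr, nc)
  pat_m <- matrix(NA_real_, nr, nc)

  if (length(cells)) {
    years <- vapply(ev, function(e) e$year, integer(1))
    doys <- vapply(ev, function(e) e$ignition_doy, integer(1))
    by_cell <- split(seq_along(cells), cells)
    for (nm in names(by_cell)) {
      rows <- rev(by_cell[[nm]])  # most recent first (events are chronological)
      cell <- as.integer(nm)
      e <- ev_id[rows]
      n <- length(e)
      w <- recency_weights(n, decay)
      fri_m[cell] <- fri_trait(years[e], records$record_start,
                               records$record_end, decay, precisions$fri)
      # severity values may be NA where the source raster lacked data inside
      # the perimeter; treat such events as missing for severity/patch.
      sv <- sev[rows]
      if (all(is.na(sv))) sev_m[cell] <- NA_real_ else {
        wk <- w * !is.na(sv); wk <- wk / sum(wk)
        sev_m[cell] <- round_to(sum(wk * sv, na.rm = TRUE), precisions$severity)
      }
      sea_m[cell] <- round_to(sum(w * cos(2 * pi * (doys[e] - 1) / 365)),
                              precisions$season)
      pv <- patch[rows]
      if (all(is.na(pv))) pat_m[cell] <- NA_real_ else {
        wk <- w * !is.na(pv); wk <- wk / sum(wk)
        pat_m[cell] <- round_to(sum(wk * pv, na.rm = TRUE), precisions$patch)
      }
    }
  }

  total_ha <- nr * nc * cell_area_ha(grid)
  structure(
    list(fri = fri_m, severity = sev_m, season = sea_m, patch = pat_m,
         grid = grid, decay = decay,
         record_start = records$record_start, record_end = records$record_end,
         record_length = unburned_fri, precisions = precisions,
         patch_range = c(log(cell_area_ha(grid)), log(total_ha))),
    class = "trait_stack"
  )
}

#' @export
print.trait_stack <- function(x, ...) {
  burned <- sum(!is.na(x$season))
  cat(sprintf("<trait_stack> %d x %d cells, decay %g, record %d-%d, %d burned cells\n",
              x$grid$nrow, x$grid$ncol, x$decay, x$record_start, x$record_end, burned))
  invisible(x)
}

#' Write a trait stack as four ASCII grids plus metadata
#'
#' Files `<prefix>_fri.asc`, `<prefix>_severity.asc`, `<prefix>_season.asc`,
#' `<prefix>_patch.asc` and `<prefix>_meta.txt`.
#'
#' @param stack A `trait_stack`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_trait_stack <- function(stack, prefix) {
  for (tr in c("fri", "severity", "season", "patch")) {
    write_ascii_grid(stack[[tr]], paste0(prefix, "_", tr, ".asc"), grid = stack$grid)
  }
  p <- stack$precisions
  writeLines(c(
    sprintf("decay %.10g", stack$decay),
    sprintf("record_start %d", stack$record_start),
    sprintf("record_end %d", stack$record_end),
    sprintf("record_length %.10g", stack$record_length),
    sprintf("precisions %.10g %.10g %.10g %.10g", p$fri, p$severity, p$season, p$patch),
    sprintf("patch_range %.10g %.10g", stack$patch_range[1], stack$patch_range[2])
  ), paste0(prefix, "_meta.txt"))
  invisible(prefix)
}

#' Read a trait stack written by [write_trait_stack()]
#' @param prefix Path prefix used when writing.
#' @return A `trait_stack`.
#' @export
read_trait_stack <- function(prefix) {
  meta <- strsplit(readLines(paste0(prefix, "_meta.txt")), "\\s+")
  kv <- stats::setNames(lapply(meta, function(x) as.numeric(x[-1])),
                        vapply(meta, `[[`, "", 1L))
  layers <- lapply(c("fri", "severity", "season", "patch"), function(tr) {
    read_ascii_grid(paste0(prefix, "_", tr, ".asc"))
  })
  structure(
    list(fri = layers[[1]]$values, severity = layers[[2]]$values,
         season = layers[[3]]$values, patch = layers[[4]]$values,
         grid = layers[[1]]$grid, decay = kv$decay,
         record_start = as.integer(kv$record_start),
         record_end = as.integer(kv$record_end),
         record_length = kv$record_length,
         precisions = as.list(stats::setNames(kv$precisions,
                                              c("fri", "severity", "season", "patch"))),
         patch_range = kv$patch_range),
    class = "trait_stack"
  )
}
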