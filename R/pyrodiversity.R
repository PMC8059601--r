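#' Construct a fire-history table
#'
#' The "community" representation behind pyrodiversity: each unique
#' discretized combination of the four fire-regime traits is a species
#' (a fire history), its abundance is the number of pixels carrying it, and
#' a landscape unit is the community. Trait ranges used for Gower scaling
#' are fixed (not re-estimated per unit) so dispersion values are comparable
#' across landscapes.
#'
#' @param traits Data frame with numeric columns `fri`, `severity`,
#'   `season`, `patch` (missing values allowed in `season`/`patch`).
#' @param abundance Positive integer pixel counts, one per history.
#' @param ranges Named list of `c(min, max)` per trait.
#' @param weights Non-negative trait weights (default equal).
#' @return An object of class `history_table`.
#' @export
history_table <- function(traits, abundance,
                          ranges = list(fri = c(0, 33), severity = c(0, 3),
                                        season = c(-1, 1), patch = c(-3, 12)),
                          weights = c(fri = 1, severity = 1, season = 1, patch = 1)) {
  traits <- as.data.frame(traits)[, c("fri", "severity", "season", "patch")]
  abundance <- as.numeric(abundance)
  stopifnot(nrow(traits) == length(abundance), all(abundance > 0),
            all(weights >= 0), sum(weights) > 0)
  if (anyDuplicated(do.call(paste, traits))) stop("histories must be unique")
  structure(
    list(traits = traits, abundance = abundance, ranges = ranges,
         weights = weights, n_pixels = sum(abundance)),
    class = "history_table"
  )
}

#' @export
print.history_table <- function(x, ...) {
  cat(sprintf("<history_table> %d histories over %d pixels\n",
              nrow(x$traits), as.integer(x$n_pixels)))
  invisible(x)
}

# Cells of `stack` (linear indices) -> history_table
tabulate_cells <- function(stack, cells, label = "selection") {
  if (!length(cells)) stop("no grid cells selected for ", label)
  df <- data.frame(fri = stack$fri[cells], severity = stack$severity[cells],
                   season = stack$season[cells], patch = stack$patch[cells])
  key <- do.call(paste, c(df, sep = "|"))
  first <- !duplicated(key)
  tab <- table(key)
  uniq <- df[first, , drop = FALSE]
  rownames(uniq) <- NULL
  history_table(
    uniq, as.numeric(tab[key[first]]),
    ranges = list(fri = c(0, stack$record_length), severity = c(0, 3),
                  season = c(-1, 1), patch = stack$patch_range)
  )
}

#' Tabulate fire histories within a landscape unit
#'
#' Counts every grid cell whose centre lies inside the unit polygon
#' (intersected with the unit's flammable mask when present) and collapses
#' identical discretized trait tuples into abundances.
#'
#' @param stack A `trait_stack`.
#' @param unit A [landscape_unit()].
#' @return A [history_table()].
#' @export
tabulate_histories <- function(stack, unit) {
  stopifnot(inherits(stack, "trait_stack"), inherits(unit, "landscape_unit"))
  inside <- rasterize_polygon(unit$geometry, stack$grid)
  if (!is.null(unit$flammable_mask)) inside <- inside & unit$flammable_mask
  cells <- which(inside)
  if (!length(cells)) stop("unit ", unit$unit_id, " overlaps no grid cells")
  tabulate_cells(stack, cells, label = paste("unit", unit$unit_id))
}

#' Gower dissimilarity between fire histories
#'
#' Per trait, the absolute difference scaled by that trait's fixed range;
#' averaged over traits with the table's weights. Trait comparisons where
#' either history is missing the trait are dropped and the remaining
#' weights renormalized, so unburned pixels (missing season and patch) are
#' still comparable to burned ones through frequency and severity.
#'
#' @param table A [history_table()].
#' @return Symmetric dissimilarity matrix with values in \[0, 1\].
#' @export
history_distance <- function(table) {
  stopifnot(inherits(table, "history_table"))
  X <- as.matrix(table$traits)
  n <- nrow(X)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (t in colnames(X)) {
    rg <- diff(table$ranges[[t]])
    w <- table$weights[[t]]
    if (w == 0) next
    v <- X[, t]
    ok <- !is.na(v)
    avail <- outer(ok, ok, `&`)
    d <- abs(outer(v, v, `-`)) / rg
    d[!avail] <- 0
    num <- num + w * d
    den <- den + w * avail
  }
  if (any(den == 0 & upper.tri(den))) {
    stop("some history pairs share no non-missing traits and cannot be compared")
  }
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- NULL
  D
}

# Euclidean distance on range-scaled complete-case traits (used as a
# Euclidean-embeddable alternative metric; errors on missing traits).
history_distance_euclidean <- function(table) {
  X <- as.matrix(table$traits)
  if (anyNA(X)) stop("euclidean history distance requires complete cases")
  for (t in colnames(X)) X[, t] <- X[, t] / diff(table$ranges[[t]])
  as.matrix(stats::dist(X))
}

#' Functional dispersion (FDis) of a fire-history table
#'
#' The abundance-weighted mean distance of unique fire histories from the
#' community's abundance-weighted centroid in the ordination of their
#' dissimilarity matrix. The dissimilarity matrix is embedded by principal
#' coordinates (eigendecomposition of the Gower-centred matrix), retaining
#' both positive and negative eigenvalue axes; squared distances to the
#' weighted centroid are the positive-axis part minus the negative-axis
#' part, floored at zero before the square root (the standard signed
#' correction for non-Euclidean dissimilarities). FDis is zero exactly when
#' a single distinct history is present, and is unitless.
#'
#' @param table A [history_table()].
#' @param distance `"gower"` (default) or `"euclidean"` (complete cases
#'   only).
#' @return An object of class `dispersion_result`: `fdis`, per-history
#'   centroid distances `z`, positive/negative-axis centroid coordinates,
#'   `n_histories` and `n_pixels`.
#' @export
fdis <- function(table, distance = c("gower", "euclidean")) {
  stopifnot(inherits(table, "history_table"))
  distance <- match.arg(distance)
  n <- nrow(table$traits)
  w <- table$abundance / sum(table$abundance)
  if (n == 1L) {
    return(structure(list(fdis = 0, z = 0, centroid = numeric(0),
                          n_histories = 1L, n_pixels = table$n_pixels),
                     class = "dispersion_result"))
  }
  D <- switch(distance,
              gower = history_distance(table),
              euclidean = history_distance_euclidean(table))
  A <- -0.5 * D^2
  ones <- rep(1, n)
  G <- A - outer(rowMeans(A), ones) - outer(ones, colMeans(A)) + mean(A)
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-9
  pos <- eg$values > tol
  neg <- eg$values < -tol
  Upos <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), sum(pos))
  Uneg <- eg$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eg$values[neg]), sum(neg))
  cpos <- drop(crossprod(Upos, w))
  cneg <- drop(crossprod(Uneg, w))
  d2pos <- rowSums(sweep(Upos, 2, cpos)^2)
  d2neg <- if (ncol(Uneg)) rowSums(sweep(Uneg, 2, cneg)^2) else 0
  z <- sqrt(pmax(d2pos - d2neg, 0))
  structure(
    list(fdis = sum(w * z), z = z,
         centroid = list(pos = cpos, neg = cneg),
         n_histories = n, n_pixels = table$n_pixels),
    class = "dispersion_result"
  )
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result> FDis = %.6g (%d histories, %d pixels)\n",
              x$fdis, x$n_histories, as.integer(x$n_pixels)))
  invisible(x)
}

#' Pyrodiversity of a landscape unit
#'
#' Composition of [tabulate_histories()] and [fdis()].
#'
#' @param stack A `trait_stack`.
#' @param unit A [landscape_unit()].
#' @return FDis, a non-negative scalar.
#' @export
pyrodiversity_of_unit <- function(stack, unit) {
  fdis(tabulate_histories(stack, unit))$fdis
}

#' Local pyrodiversity around a point
#'
#' FDis over the grid cells whose centres fall within `radius_m` of the
#' point -- the form used around field survey locations.
#'
#' @param stack A `trait_stack`.
#' @param x,y Point coordinates (metres, grid CRS).
#' @param radius_m Disc radius in metres.
#' @return FDis, a non-negative scalar.
#' @export
local_pyrodiversity <- function(stack, x, y, radius_m) {
  cc <- cell_centers(stack$grid)
  cells <- which((cc[, 1] - x)^2 + (cc[, 2] - y)^2 <= radius_m^2)
  if (!length(cells)) stop("no grid-cell centres within the requested disc")
  fdis(tabulate_cells(stack, cells, label = "disc"))$fdis
}

#' Pyrodiversity of many units as a table
#'
#' @param stack A `trait_stack`.
#' @param units List of [landscape_unit()] objects.
#' @return Data frame with `unit_id`, `fdis`, `n_histories`, `n_pixels`.
#' @export
pyrodiversity_table <- function(stack, units) {
  rows <- lapply(units, function(u) {
    r <- fdis(tabulate_histories(stack, u))
    data.frame(unit_id = u$unit_id, fdis = r$fdis,
               n_histories = r$n_histories, n_pixels = r$n_pixels)
  })
  do.call(rbind, rows)
}
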