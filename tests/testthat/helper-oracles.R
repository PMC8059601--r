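# Independent oracles and small fixture builders shared across tests.

# Weighted-centroid dispersion computed directly from a dissimilarity matrix
# by the generalized Huygens theorem: the signed squared distance of point j
# from the abundance-weighted centroid is
#   z_j^2 = sum_k w_k d_jk^2 - (1/2) sum_k sum_l w_k w_l d_kl^2 .
# Pure arithmetic, no eigendecomposition: the brute-force counterpart of the
# ordination-based FDis.
huygens_fdis <- function(D, abundance) {
  w <- abundance / sum(abundance)
  ss <- sum(outer(w, w) * D^2) / 2
  z <- sqrt(pmax(drop(D^2 %*% w) - ss, 0))
  sum(w * z)
}

# Direct FDis in range-scaled trait space under the Euclidean metric:
# abundance-weighted mean Euclidean distance to the abundance-weighted
# centroid. Valid comparison partner for the ordination path only when the
# dissimilarity fed to the ordination is itself Euclidean in that space.
euclid_fdis <- function(traits, abundance, ranges) {
  X <- as.matrix(traits)
  for (t in colnames(X)) X[, t] <- X[, t] / diff(ranges[[t]])
  w <- abundance / sum(abundance)
  centroid <- colSums(w * X)
  z <- sqrt(rowSums(sweep(X, 2, centroid)^2))
  sum(w * z)
}

std_ranges <- list(fri = c(0, 33), severity = c(0, 3),
                   season = c(-1, 1), patch = c(-3, 10))

# Random complete-case history table with integer abundances.
random_history_table <- function(n, ranges = std_ranges) {
  repeat {
    traits <- data.frame(
      fri = sample(0:33, n, replace = TRUE),
      severity = sample(seq(0, 3, 0.5), n, replace = TRUE),
      season = sample(seq(-1, 1, 0.1), n, replace = TRUE),
      patch = round(runif(n, -3, 10), 1)
    )
    if (!anyDuplicated(do.call(paste, traits))) break
  }
  history_table(traits, sample(1:50, n, replace = TRUE), ranges = ranges)
}

# Tiny deterministic record set: two overlapping square fires on a 10x10
# grid of 100 m cells, plus one disjoint fire in the far corner.
toy_records <- function() {
  g <- fire_grid(0, 0, 100, 10, 10)
  sev <- function(val) fire_raster(matrix(val, 10, 10), g)
  ev <- list(
    fire_event("A", 1990, ignition_doy = 150,
               perimeter = rect_polygon(120, 120, 640, 640), severity = sev(1)),
    fire_event("B", 2005, ignition_doy = 250,
               perimeter = rect_polygon(360, 360, 940, 940), severity = sev(2.6)),
    fire_event("C", 2012, ignition_doy = 30,
               perimeter = rect_polygon(840, 60, 980, 160), severity = sev(0.5))
  )
  fire_record_set(ev, 1985, 2018, g)
}
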