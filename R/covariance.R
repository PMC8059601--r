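#' Per-trait dispersion of a landscape unit
#'
#' FDis is the multivariate analogue of the abundance-weighted mean absolute
#' deviation; this computes that univariate deviation separately for each of
#' the four traits over a unit's history table (missing values excluded per
#' trait), together with the number of fires whose perimeter intersects the
#' unit. A fire "intersects" when at least one grid-cell centre falls inside
#' both the fire perimeter and the unit polygon, consistent with the
#' cell-centre rule used everywhere else.
#'
#' @param stack A `trait_stack`.
#' @param unit A [landscape_unit()].
#' @param records The [fire_record_set()] the stack was built from.
#' @return One-row data frame: `unit_id`, `n_fires`, `disp_fri`,
#'   `disp_severity`, `disp_season`, `disp_patch`.
#' @export
trait_dispersions <- function(stack, unit, records) {
  table <- tabulate_histories(stack, unit)
  unit_mask <- rasterize_polygon(unit$geometry, stack$grid)
  if (!is.null(unit$flammable_mask)) unit_mask <- unit_mask & unit$flammable_mask
  n_fires <- sum(vapply(records$events, function(e) {
    any(unit_mask & rasterize_polygon(e$perimeter, stack$grid))
  }, logical(1)))
  disp <- vapply(c("fri", "severity", "season", "patch"), function(t) {
    weighted_mad(table$traits[[t]], table$abundance)
  }, numeric(1))
  data.frame(unit_id = unit$unit_id, n_fires = n_fires,
             disp_fri = disp[["fri"]], disp_severity = disp[["severity"]],
             disp_season = disp[["season"]], disp_patch = disp[["patch"]])
}

# Abundance-weighted mean absolute deviation about the weighted mean,
# missing values excluded. NA when no non-missing values.
weighted_mad <- function(x, a) {
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  x <- x[ok]; a <- a[ok]
  m <- sum(a * x) / sum(a)
  sum(a * abs(x - m)) / sum(a)
}

#' Trait-dispersion correlations swept over minimum fire counts
#'
#' Correlates each pair of trait dispersions across landscape units, then
#' repeats after progressively excluding units with fewer recorded fires
#' than an increasing threshold. Correlations computed on fewer than three
#' units, or on a zero-variance column, are flagged undefined rather than
#' propagated as NaN.
#'
#' @param rows Data frame of [trait_dispersions()] rows (one per unit).
#' @param min_fires Integer thresholds to sweep (default `1:15`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Long data frame: `threshold`, `trait_a`, `trait_b`, `r`,
#'   `n_units`, `defined`. The full per-threshold matrices are attached as
#'   the `"matrices"` attribute (list of 4x4 matrices).
#' @export
correlation_sweep <- function(rows, min_fires = 1:15,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  traits <- c("disp_fri", "disp_severity", "disp_season", "disp_patch")
  stopifnot(all(traits %in% names(rows)), "n_fires" %in% names(rows))
  out <- list()
  mats <- list()
  for (th in min_fires) {
    sub <- rows[rows$n_fires >= th, traits, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    n <- nrow(sub)
    M <- matrix(NA_real_, 4, 4, dimnames = list(traits, traits))
    diag(M) <- 1
    if (n >= 3) {
      sds <- vapply(sub, stats::sd, numeric(1))
      for (i in 1:3) for (j in (i + 1):4) {
        if (sds[i] > 0 && sds[j] > 0) {
          M[i, j] <- M[j, i] <- stats::cor(sub[[i]], sub[[j]], method = method)
        }
      }
    }
    mats[[as.character(th)]] <- M
    pairs <- utils::combn(4, 2)
    out[[length(out) + 1L]] <- data.frame(
      threshold = th,
      trait_a = traits[pairs[1, ]], trait_b = traits[pairs[2, ]],
      r = M[t(pairs)], n_units = n,
      defined = !is.na(M[t(pairs)])
    )
  }
  res <- do.call(rbind, out)
  attr(res, "matrices") <- mats
  res
}
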