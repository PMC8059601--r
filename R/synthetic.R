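#' Parameters of a synthetic fire regime
#'
#' Describes the generative regime emulating an MTBS-style record: annual
#' Poisson ignitions of large fires, log-normal fire sizes, spatially
#' correlated severity surfaces on a metric grid, and a wrapped-normal
#' ignition season.
#'
#' @param ignition_rate Mean fires per year (Poisson).
#' @param size_meanlog,size_sdlog Log-normal fire-size parameters, log-ha.
#' @param severity_mean,severity_sd Mean and sd of the CBI severity field
#'   before clipping to \[0, 3\].
#' @param severity_range_cells Correlation length of the severity field, in
#'   cells.
#' @param season_mean_doy Circular mean ignition day of year.
#' @param season_sd_days Wrapped-normal sd in days (small = concentrated).
#' @param record_start,record_end Record window years.
#' @param grid Analysis [fire_grid()].
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `regime_params`.
#' @export
regime_params <- function(ignition_rate = 0.8,
                          size_meanlog = log(800), size_sdlog = 0.6,
                          severity_mean = 1.5, severity_sd = 0.6,
                          severity_range_cells = 5,
                          season_mean_doy = 213, season_sd_days = 30,
                          record_start = 1985, record_end = 2018,
                          grid = fire_grid(0, 0, 30, 150, 150),
                          seed = 1) {
  stopifnot(ignition_rate >= 0, size_sdlog > 0, severity_sd > 0,
            severity_range_cells > 0, season_sd_days > 0,
            record_start <= record_end, inherits(grid, "fire_grid"))
  structure(as.list(environment()), class = "regime_params")
}

# Spatially correlated standard-normal field via FFT smoothing of white
# noise with a (circulant) Gaussian kernel; wrap-around is harmless for
# synthetic landscapes.
gaussian_field <- function(nrow, ncol, range_cells) {
  noise <- matrix(rnorm(nrow * ncol), nrow, ncol)
  dr <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
  dc <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
  kern <- exp(-outer(dr^2, dc^2, `+`) / (2 * range_cells^2))
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (nrow * ncol)
  (f - mean(f)) / sd(f)
}

# Star-shaped blob polygon: smooth random radial harmonics around a centre,
# rescaled so the polygon area hits the target exactly.
blob_polygon <- function(cx, cy, area_m2, roughness = 0.25, n_vertices = 64) {
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- rep(1, n_vertices)
  for (m in 1:4) {
    r <- r + (roughness / m) * (rnorm(1) * cos(m * phi) + rnorm(1) * sin(m * phi))
  }
  r <- pmax(r, 0.15)
  ring <- cbind(cx + r * cos(phi), cy + r * sin(phi))
  poly <- fire_polygon(ring)
  s <- sqrt(area_m2 / polygon_area(poly))
  fire_polygon(cbind(cx + s * (ring[, 1] - cx), cy + s * (ring[, 2] - cy)))
}

wrapped_normal_doy <- function(n, mean_doy, sd_days) {
  ((round(rnorm(n, mean_doy, sd_days)) - 1) %% 365) + 1
}

#' Simulate a synthetic fire record
#'
#' Per year, a Poisson number of ignitions; each fire is a connected
#' irregular blob perimeter scaled to its log-normal sampled area, with a
#' spatially correlated CBI severity surface (Gaussian field scaled to the
#' regime's mean/sd and clipped to \[0, 3\]) and a wrapped-normal ignition
#' date. Fires whose sampled area exceeds half the grid are resampled (up
#' to 10 attempts) with a warning.
#'
#' @param params A [regime_params()].
#' @return A [fire_record_set()] on the params' grid.
#' @export
simulate_fire_records <- function(params) {
  stopifnot(inherits(params, "regime_params"))
  set.seed(params$seed)
  g <- params$grid
  ext <- grid_extent(g)
  max_ha <- 0.5 * g$nrow * g$ncol * cell_area_ha(g)
  events <- list()
  k <- 0L
  for (year in params$record_start:params$record_end) {
    n_fires <- stats::rpois(1, params$ignition_rate)
    if (n_fires == 0) next
    doys <- wrapped_normal_doy(n_fires, params$season_mean_doy, params$season_sd_days)
    for (i in seq_len(n_fires)) {
      area_ha <- stats::rlnorm(1, params$size_meanlog, params$size_sdlog)
      att <- 1L
      while (area_ha > max_ha && att < 10L) {
        area_ha <- stats::rlnorm(1, params$size_meanlog, params$size_sdlog)
        att <- att + 1L
      }
      if (area_ha > max_ha) {
        warning("sampled fire size repeatedly exceeds the grid; clamped")
        area_ha <- max_ha
      }
      k <- k + 1L
      radius <- sqrt(area_ha * 1e4 / pi)
      cx <- stats::runif(1, ext["xmin"] + 0.2 * radius, ext["xmax"] - 0.2 * radius)
      cy <- stats::runif(1, ext["ymin"] + 0.2 * radius, ext["ymax"] - 0.2 * radius)
      perim <- blob_polygon(cx, cy, area_ha * 1e4)
      sev <- params$severity_mean +
        params$severity_sd * gaussian_field(g$nrow, g$ncol, params$severity_range_cells)
      sev <- pmin(pmax(sev, 0), 3)
      events[[k]] <- fire_event(
        fire_id = sprintf("F%04d", k), year = year, ignition_doy = doys[i],
        perimeter = perim, severity = fire_raster(sev, g)
      )
    }
  }
  fire_record_set(events, params$record_start, params$record_end, g)
}

#' Two-regime landscape fixture with known contrast
#'
#' A landscape split into two halves with deliberately opposed fire
#' regimes: the west half burns often at low severity in small patches, the
#' east half rarely at high severity in large patches. Returns the merged
#' record set and three landscape units (each half plus their union). The
#' union mixes the two regimes, so its pyrodiversity exceeds either half's.
#'
#' @param seed Integer seed.
#' @return List with `records`, `units` (list: west, east, union) and
#'   `grid`.
#' @export
two_regime_fixture <- function(seed = 20) {
  res <- 100  # 1 ha cells keep the fixture fast while staying metric
  nr <- 60; nc <- 120
  grid <- fire_grid(0, 0, res, nr, nc)
  half_w <- fire_grid(0, 0, res, nr, nc / 2)
  half_e <- fire_grid(nc / 2 * res, 0, res, nr, nc / 2)

  west <- simulate_fire_records(regime_params(
    ignition_rate = 2.5, size_meanlog = log(60), size_sdlog = 0.35,
    severity_mean = 0.8, severity_sd = 0.35, severity_range_cells = 3,
    season_mean_doy = 170, season_sd_days = 25, grid = half_w, seed = seed
  ))
  east <- simulate_fire_records(regime_params(
    ignition_rate = 0.5, size_meanlog = log(1100), size_sdlog = 0.3,
    severity_mean = 2.5, severity_sd = 0.35, severity_range_cells = 6,
    season_mean_doy = 250, season_sd_days = 25, grid = half_e, seed = seed + 1
  ))
  records <- fire_record_set(c(west$events, east$events), 1985, 2018, grid)
  mid <- nc / 2 * res
  units <- list(
    west = landscape_unit("west", rect_polygon(0, 0, mid, nr * res)),
    east = landscape_unit("east", rect_polygon(mid, 0, nc * res, nr * res)),
    union = landscape_unit("union", rect_polygon(0, 0, nc * res, nr * res))
  )
  list(records = records, units = units, grid = grid)
}

#' Simulate a driver table with known ground truth
#'
#' Draws standardized covariates (standard normal; wilderness as a
#' standardized proportion), assigns units evenly to parent groups, and
#' simulates burn activity and pyrodiversity from the generative model.
#' The generating [model_spec()] is stored in the `"truth"` attribute.
#'
#' @param spec A [model_spec()] (default [default_model_spec()]).
#' @param n_units Number of landscape units.
#' @param n_groups Number of parent groups (`n_units >= n_groups >= 1`).
#' @param seed Integer seed.
#' @return Standardized driver table with responses; attributes `"truth"`
#'   and `"pb_scaling"`.
#' @export
simulate_driver_table <- function(spec = default_model_spec(), n_units = 500,
                                  n_groups = 5, seed = 1) {
  stopifnot(n_units >= n_groups, n_groups >= 1)
  set.seed(seed)
  std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  d <- data.frame(
    unit_id = sprintf("U%04d", seq_len(n_units)),
    parent_id = sprintf("G%02d", rep_len(seq_len(n_groups), n_units)),
    aet = std(rnorm(n_units)), cwd = std(rnorm(n_units)),
    elev = std(rnorm(n_units)), rough = std(rnorm(n_units)),
    pop_den = std(rnorm(n_units)), wild = std(stats::rbeta(n_units, 1.2, 5))
  )
  simulate_from_model(spec, d, seed = seed + 1L)
}
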