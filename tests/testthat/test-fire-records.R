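test_that("record sets sort events chronologically and enforce the window", {
  rec <- toy_records()
  years <- vapply(rec$events, function(e) e$year, integer(1))
  expect_equal(years, sort(years))
  expect_error(
    fire_record_set(rec$events, 1995, 2018, rec$grid),
    "record window"
  )
})

test_that("severity outside [0, 3] is clipped with a warning", {
  g <- fire_grid(0, 0, 100, 4, 4)
  sev <- matrix(c(-0.5, rep(2, 14), 4.2), 4, 4)
  expect_warning(
    e <- fire_event("X", 2000, ignition_doy = 100,
                    perimeter = rect_polygon(0, 0, 400, 400),
                    severity = fire_raster(sev, g)),
    "clipped"
  )
  expect_true(all(e$severity$values >= 0 & e$severity$values <= 3))
  expect_equal(max(e$severity$values), 3)
})

test_that("area_ha is validated against the perimeter and dates parse to doy", {
  g <- fire_grid(0, 0, 100, 4, 4)
  sq <- rect_polygon(0, 0, 1000, 1000)  # 100 ha
  sev <- fire_raster(matrix(1, 4, 4), g)
  e <- fire_event("X", 2000, ig_date = "2000-02-29", perimeter = sq, severity = sev)
  expect_equal(e$area_ha, 100)
  expect_equal(e$ignition_doy, 60L)  # leap day
  expect_error(fire_event("X", 2000, ignition_doy = 1, perimeter = sq,
                          severity = sev, area_ha = 120), "differs")
  # within 0.5% passes
  expect_silent(fire_event("X", 2000, ignition_doy = 1, perimeter = sq,
                           severity = sev, area_ha = 100.4))
})

test_that("large-fire filter uses a strict 404 ha inequality and is idempotent", {
  g <- fire_grid(0, 0, 30, 5, 5)
  sev <- fire_raster(matrix(1, 5, 5), g)
  mk <- function(id, ha) {
    side <- sqrt(ha * 1e4)
    fire_event(id, 2000, ignition_doy = 10,
               perimeter = rect_polygon(0, 0, side, side), severity = sev)
  }
  rec <- fire_record_set(lapply(c(a = 100, b = 404, c = 405, d = 1000),
                                function(h) mk(paste0("f", h), h)),
                         1985, 2018, g)
  f1 <- suppressMessages(filter_large_fires(rec))
  expect_equal(sort(unname(vapply(f1$events, function(e) e$area_ha, numeric(1)))),
               c(405, 1000))
  f2 <- suppressMessages(filter_large_fires(f1))
  expect_identical(vapply(f2$events, function(e) e$fire_id, character(1)),
                   vapply(f1$events, function(e) e$fire_id, character(1)))
  expect_equal(length(suppressMessages(filter_large_fires(rec, 0))$events), 4L)
  empty <- fire_record_set(list(), 1985, 2018, g)
  expect_equal(length(filter_large_fires(empty)$events), 0L)
  expect_error(filter_large_fires(rec, -1), "non-negative")
})

test_that("forest-cover filter drops units strictly below the threshold", {
  units <- lapply(c(0.4, 0.5, 0.9), function(f) {
    landscape_unit(paste0("u", f), rect_polygon(0, 0, 1, 1), forest_fraction = f)
  })
  kept <- filter_units_by_forest(units)
  expect_equal(vapply(kept, function(u) u$forest_fraction, numeric(1)), c(0.5, 0.9))
  expect_length(filter_units_by_forest(units, 0), 3L)
  expect_warning(res <- filter_units_by_forest(units, 0.95), "no units")
  expect_length(res, 0L)
})

test_that("rasterization follows the cell-centre rule and resamples nearest", {
  g <- fire_grid(0, 0, 100, 6, 6)
  sev <- fire_raster(matrix(2, 6, 6), g)
  e <- fire_event("sq", 2000, ignition_doy = 1,
                  perimeter = rect_polygon(100, 100, 500, 500), severity = sev)
  ras <- rasterize_event(e, g)
  expect_equal(sum(ras$burn_mask), 16L)  # 4x4 block of centres
  expect_true(all(is.na(ras$severity[!ras$burn_mask])))
  expect_true(all(ras$severity[ras$burn_mask] == 2))

  # coarser source raster: nearest value propagates
  g2 <- fire_grid(0, 0, 200, 3, 3)
  src <- fire_raster(matrix(1:9, 3, 3), g2)
  out <- resample_nearest(src, g)
  expect_equal(out[1, 1], src$values[1, 1])
  expect_equal(out[2, 2], src$values[1, 1])
  expect_equal(out[6, 6], src$values[3, 3])

  away <- fire_event("far", 2000, ignition_doy = 1,
                     perimeter = rect_polygon(5000, 5000, 6000, 6000),
                     severity = sev)
  expect_warning(r2 <- rasterize_event(away, g), "overlap")
  expect_false(any(r2$burn_mask))
})

test_that("geographic-looking coordinates are rejected", {
  g <- fire_grid(0, 0, 100, 3, 3)
  expect_error(
    fire_event("ll", 2000, ignition_doy = 1,
               perimeter = rect_polygon(-120, 38, -119.9, 38.1),
               severity = fire_raster(matrix(1, 3, 3), g)),
    "metric"
  )
})

test_that("writing and re-reading a record set preserves events", {
  rec <- toy_records()
  dir <- withr::local_tempdir()
  write_fires(rec, dir)
  back <- read_fire_dir(dir)
  expect_equal(length(back$events), length(rec$events))
  for (i in seq_along(rec$events)) {
    expect_equal(back$events[[i]]$year, rec$events[[i]]$year)
    expect_equal(back$events[[i]]$ignition_doy, rec$events[[i]]$ignition_doy)
    expect_lt(abs(back$events[[i]]$area_ha - rec$events[[i]]$area_ha),
              0.005 * rec$events[[i]]$area_ha)
    expect_equal(back$events[[i]]$severity$values, rec$events[[i]]$severity$values)
  }
  expect_equal(back$grid$res, rec$grid$res)
})

test_that("read_fires drops out-of-window events and errors on missing severity", {
  rec <- toy_records()
  dir <- withr::local_tempdir()
  write_fires(rec, dir)
  expect_warning(
    narrow <- read_fires(file.path(dir, "perimeters.geojson"),
                         file.path(dir, "severity"), 1995, 2018,
                         grid = rec$grid),
    "outside record window"
  )
  expect_equal(length(narrow$events), 2L)
  file.remove(file.path(dir, "severity", "B.asc"))
  expect_error(
    read_fires(file.path(dir, "perimeters.geojson"), file.path(dir, "severity"),
               1985, 2018, grid = rec$grid),
    "missing severity raster for fire B"
  )
})
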