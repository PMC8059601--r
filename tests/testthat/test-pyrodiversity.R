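test_that("history tabulation counts cells and keys on discretized tuples", {
  st <- build_trait_stack(toy_records())
  whole <- landscape_unit("all", rect_polygon(-10, -10, 1010, 1010))
  tab <- tabulate_histories(st, whole)
  expect_equal(tab$n_pixels, 100)
  expect_equal(sum(tab$abundance), 100)
  expect_false(anyDuplicated(do.call(paste, tab$traits)) > 0)
  # a unit covering only unburned ground has a single history
  corner <- landscape_unit("nw", rect_polygon(0, 820, 180, 1000))
  tab2 <- tabulate_histories(st, corner)
  expect_equal(nrow(tab2$traits), 1L)
  expect_error(tabulate_histories(st, landscape_unit("off", rect_polygon(2000, 2000, 3000, 3000))),
               "overlaps no grid cells")
  # flammable mask restricts the community
  mask <- matrix(FALSE, 10, 10); mask[1:5, ] <- TRUE
  half <- landscape_unit("half", rect_polygon(-10, -10, 1010, 1010),
                         flammable_mask = mask)
  expect_equal(tabulate_histories(st, half)$n_pixels, 50)
})

test_that("Gower distance scales by fixed ranges and renormalizes missing traits", {
  rg <- std_ranges
  tr <- data.frame(fri = c(0, 33, 0, 10), severity = c(0, 0, 3, 1),
                   season = c(0.5, 0.5, 0.5, NA), patch = c(1, 1, 1, NA))
  ht <- history_table(tr, c(1, 1, 1, 1), ranges = rg)
  D <- history_distance(ht)
  expect_equal(D[1, 2], 0.25)  # full range in one trait of four
  expect_equal(D[1, 3], 0.25)
  # history 4 misses season+patch: averaged over the two shared traits
  expect_equal(D[1, 4], (10 / 33 + 1 / 3) / 2)
  expect_true(isSymmetric(D) && all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  # identical tuples -> zero distance
  same <- history_table(tr[c(1, 2), ], c(2, 3), ranges = rg)
  expect_equal(history_distance(same)[1, 2], 1 / 4)
})

test_that("incomparable history pairs raise an error", {
  tr <- data.frame(fri = c(1, 2), severity = c(1, 2),
                   season = c(NA, 0), patch = c(NA, 0))
  ht <- history_table(tr, c(1, 1), ranges = std_ranges,
                      weights = c(fri = 0, severity = 0, season = 1, patch = 1))
  expect_error(history_distance(ht), "cannot be compared")
})

test_that("FDis is zero for one history and d/2 for a symmetric pair", {
  one <- history_table(data.frame(fri = 5, severity = 1, season = 0, patch = 2),
                       100, ranges = std_ranges)
  expect_identical(fdis(one)$fdis, 0)
  two <- history_table(data.frame(fri = c(5, 20), severity = c(1, 2.5),
                                  season = c(0, -0.5), patch = c(2, 6)),
                       c(7, 7), ranges = std_ranges)
  d <- history_distance(two)[1, 2]
  expect_equal(fdis(two)$fdis, d / 2, tolerance = 1e-12)
})

test_that("ordination FDis matches the brute-force centroid oracle", {
  set.seed(11)
  for (i in 1:40) {
    ht <- random_history_table(sample(3:12, 1))
    r <- fdis(ht)
    expect_equal(r$fdis, huygens_fdis(history_distance(ht), ht$abundance),
                 tolerance = 1e-10)
    expect_equal(r$fdis, sum(ht$abundance / sum(ht$abundance) * r$z),
                 tolerance = 1e-12)
  }
})

test_that("euclidean-path FDis matches direct trait-space computation", {
  set.seed(12)
  for (i in 1:20) {
    ht <- random_history_table(sample(3:10, 1))
    expect_equal(fdis(ht, distance = "euclidean")$fdis,
                 euclid_fdis(ht$traits, ht$abundance, ht$ranges),
                 tolerance = 1e-10)
  }
})

test_that("FDis is invariant to abundance scaling and history order", {
  set.seed(13)
  ht <- random_history_table(8)
  base <- fdis(ht)$fdis
  scaled <- history_table(ht$traits, ht$abundance * 4, ranges = ht$ranges)
  expect_equal(fdis(scaled)$fdis, base, tolerance = 1e-10)
  perm <- sample(8)
  shuffled <- history_table(ht$traits[perm, ], ht$abundance[perm], ranges = ht$ranges)
  expect_equal(fdis(shuffled)$fdis, base, tolerance = 1e-10)
})

test_that("adding a distant history with small abundance increases FDis", {
  set.seed(14)
  ht <- random_history_table(6)
  base <- fdis(ht)$fdis
  far <- data.frame(fri = 33, severity = 3, season = -1, patch = 10)
  joined <- rbind(ht$traits, far)
  joined <- joined[!duplicated(do.call(paste, joined)), ]
  grown <- history_table(joined, c(ht$abundance, 2), ranges = ht$ranges)
  expect_gt(fdis(grown)$fdis, base)
})

test_that("unit pyrodiversity composes tabulation and FDis", {
  st <- build_trait_stack(toy_records())
  whole <- landscape_unit("all", rect_polygon(-10, -10, 1010, 1010))
  expect_equal(pyrodiversity_of_unit(st, whole),
               fdis(tabulate_histories(st, whole))$fdis)
  # all-unburned unit -> 0
  corner <- landscape_unit("nw", rect_polygon(0, 820, 180, 1000))
  expect_identical(pyrodiversity_of_unit(st, corner), 0)
  # identical history tables -> identical FDis
  st_empty <- build_trait_stack(fire_record_set(list(), 1985, 2018, st$grid))
  u1 <- landscape_unit("a", rect_polygon(0, 0, 500, 500))
  u2 <- landscape_unit("b", rect_polygon(500, 500, 1000, 1000))
  expect_identical(pyrodiversity_of_unit(st_empty, u1),
                   pyrodiversity_of_unit(st_empty, u2))
})

test_that("local pyrodiversity grows with sampled heterogeneity then stabilizes", {
  st <- build_trait_stack(toy_records())
  # single-cell disc is zero
  expect_identical(local_pyrodiversity(st, 450, 450, 10), 0)
  expect_error(local_pyrodiversity(st, -500, -500, 10), "within")
  # two-zone landscape: burned (A-only) vs unburned; FDis non-decreasing as
  # the disc grows from inside one zone to cover both, then stabilizes
  vals <- vapply(c(60, 250, 700, 1500, 3000), function(r) {
    local_pyrodiversity(st, 250, 250, r)
  }, numeric(1))
  expect_true(all(diff(vals[1:3]) >= -1e-12))
  expect_equal(vals[4], vals[5], tolerance = 1e-12)
})
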