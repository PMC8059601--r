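test_that("standardize centres, scales, squares prop_burn and round-trips", {
  tab <- data.frame(unit_id = 1:3, parent_id = "G1",
                    aet = c(1, 2, 3), cwd = c(0, 1, 5), elev = c(2, 4, 9),
                    rough = c(1, 3, 8), pop_den = c(0, 2, 7), wild = c(0, 0.5, 1),
                    prop_burn = c(0, 0.2, 0.9))
  out <- standardize(tab)
  std <- out$table
  expect_equal(std$aet, c(-1, 0, 1))
  for (cl in out$scaling$col) {
    expect_equal(mean(std[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(std[[cl]]), 1, tolerance = 1e-12)
    expect_equal(unstandardize(std[[cl]], out$scaling, cl), tab[[cl]],
                 tolerance = 1e-12)
  }
  expect_equal(std$prop_burn_sq, std$prop_burn^2)
  expect_equal(std$prop_burn_raw, tab$prop_burn)
  # already-standardized input is unchanged
  again <- standardize(std[, !(names(std) %in% c("prop_burn_raw", "prop_burn_sq"))])
  expect_equal(again$table$aet, std$aet, tolerance = 1e-12)
  tab$cwd <- 1
  expect_error(standardize(tab), "zero-variance")
})

test_that("simulation honours the null model, Beta moments and the seed", {
  spec <- default_model_spec()
  null_spec <- spec
  null_spec$alpha0 <- 0
  null_spec$beta[] <- 0
  null_spec$sigma_group <- 0
  null_spec$theta <- 2
  cov <- data.frame(parent_id = rep(c("G1", "G2"), each = 2500),
                    aet = rnorm(5000), cwd = rnorm(5000), elev = rnorm(5000),
                    rough = rnorm(5000), pop_den = rnorm(5000), wild = rnorm(5000))
  d <- simulate_from_model(null_spec, cov, seed = 5)
  # all beta zero, alpha0 zero, sigma 0 -> mean 0.5; theta 2 -> Beta(1, 1)
  expect_equal(mean(d$pyrodiversity), 0.5, tolerance = 0.02)
  ks <- suppressWarnings(stats::ks.test(d$pyrodiversity, "punif"))
  expect_gt(ks$p.value, 0.01)
  # mean-precision identity at fixed mu: var = mu(1-mu)/(1+theta) = 1/12
  expect_lt(abs(stats::var(d$pyrodiversity) - 0.25 / (1 + 2)), 0.005)
  # determinism
  d2 <- simulate_from_model(null_spec, cov, seed = 5)
  expect_identical(d$pyrodiversity, d2$pyrodiversity)
  expect_false(identical(simulate_from_model(null_spec, cov, seed = 6)$pyrodiversity,
                         d$pyrodiversity))
})

test_that("burn submodel recovers its generating coefficients", {
  spec <- default_model_spec()
  d <- suppressMessages(simulate_driver_table(spec, 1200, 5, seed = 41))
  bf <- suppressWarnings(fit_burn_model(d, seed = 1))
  expect_true(bf$diagnostics$converged)
  ci <- coef_intervals(bf, level = 0.95)
  truth <- c(zero = c(spec$burn_zero$alpha0, spec$burn_zero$beta),
             pos = c(spec$burn_pos$alpha0, spec$burn_pos$beta))
  # names: zero.(Intercept), zero.aet, ..., pos.elev:rough (model-matrix order)
  want <- c(spec$burn_zero$alpha0, spec$burn_zero$beta[c("aet", "cwd", "elev",
            "rough", "pop_den", "wild", "aet:cwd", "elev:rough")],
            spec$burn_pos$alpha0, spec$burn_pos$beta[c("aet", "cwd", "elev",
            "rough", "pop_den", "wild", "aet:cwd", "elev:rough")])
  covered <- want >= ci$lower & want <= ci$upper
  expect_gte(mean(covered), 0.8)
  expect_lt(max(abs(ci$estimate - want)), 0.35)
})

test_that("intercept-only burn truth yields near-zero slope estimates", {
  spec <- default_model_spec()
  spec$burn_zero$beta[] <- 0
  spec$burn_pos$beta[] <- 0
  spec$burn_zero$sigma_group <- 0
  spec$burn_pos$sigma_group <- 0
  d <- suppressMessages(simulate_driver_table(spec, 3000, 5, seed = 42))
  bf <- suppressWarnings(fit_burn_model(d, seed = 1))
  slopes <- bf$estimates[!grepl("Intercept", names(bf$estimates))]
  expect_true(all(abs(slopes) < 0.1))
})

test_that("burn fit is invariant to the order of the data rows", {
  d <- suppressMessages(simulate_driver_table(default_model_spec(), 300, 3, seed = 43))
  b1 <- suppressWarnings(fit_burn_model(d, seed = 1))
  set.seed(2)
  b2 <- suppressWarnings(fit_burn_model(d[sample(nrow(d)), ], seed = 1))
  expect_equal(b1$estimates, b2$estimates, tolerance = 1e-8)
})

test_that("pyro model recovers the quadratic burn effect and handles zeros", {
  spec <- default_model_spec()
  d <- simulate_driver_table(spec, 800, 5, seed = 44)
  d$pyrodiversity[1] <- 0  # force the zero-nudge path
  expect_message(pf <- fit_pyro_model(d, seed = 1), "nudged")
  ci <- coef_intervals(pf, level = 0.95, method = "wald")
  for (term in c("prop_burn", "prop_burn_sq")) {
    i <- match(term, ci$term)
    truth <- spec$beta[[term]]
    expect_gt(truth, ci$lower[i] - 0.2)
    expect_lt(truth, ci$upper[i] + 0.2)
  }
  expect_equal(pf$diagnostics$theta, spec$theta, tolerance = 0.25 * spec$theta)
  bad <- d; bad$pyrodiversity[2] <- 1
  expect_error(fit_pyro_model(bad), "below 1")
})

test_that("propagating burn uncertainty widens burn-coefficient intervals", {
  d <- suppressMessages(simulate_driver_table(default_model_spec(), 400, 4, seed = 45))
  bf <- suppressWarnings(fit_burn_model(d, seed = 1))
  plain <- suppressMessages(fit_pyro_model(d, propagate = "none", seed = 2))
  prop <- suppressMessages(suppressWarnings(
    fit_pyro_model(d, burn_fit = bf, propagate = "draws",
                   n_imputations = 5, n_draws = 1000, seed = 2)))
  w <- function(fit) {
    ci <- coef_intervals(fit, level = 0.90)
    ci$upper[ci$term == "prop_burn"] - ci$lower[ci$term == "prop_burn"]
  }
  expect_gt(w(prop), w(plain))
})

test_that("group-intercept shrinkage: zero-sigma truth gives near-zero sigma", {
  spec <- default_model_spec()
  spec$sigma_group <- 0
  d <- suppressMessages(simulate_driver_table(spec, 600, 6, seed = 46))
  pf <- suppressWarnings(suppressMessages(fit_pyro_model(d, seed = 1)))
  expect_lt(pf$diagnostics$sigma_group, 0.1)
})

test_that("derived quantities implement the closed-form vertex and rotation", {
  expect_equal(quadratic_vertex(2.5, -0.78), 2.5 / 1.56)
  # degenerate fit with constant draws isolates the arithmetic
  fake <- structure(list(
    draws = cbind(prop_burn = rep(2.5, 100), prop_burn_sq = rep(-0.78, 100)),
    pb_scaling = c(mean = 0.16, sd = 0.3)
  ), class = "model_fit")
  dq <- derived_quantities(fake, record_years = 34)
  expect_equal(unname(dq$vertex_sd["mean"]), 1.6026, tolerance = 1e-4)
  expect_equal(unname(dq$peak_prop_burn["mean"]), 0.16 + (2.5 / 1.56) * 0.3,
               tolerance = 1e-12)
  expect_equal(unname(dq$fire_rotation_years["mean"]),
               34 / (0.16 + (2.5 / 1.56) * 0.3), tolerance = 1e-12)
  # concavity flag: mostly non-negative quadratic draws -> undefined
  convex <- structure(list(
    draws = cbind(prop_burn = rep(1, 50), prop_burn_sq = rep(0.2, 50)),
    pb_scaling = c(mean = 0.1, sd = 0.2)
  ), class = "model_fit")
  expect_warning(dq2 <- derived_quantities(convex), "undefined")
  expect_false(dq2$defined)
})
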