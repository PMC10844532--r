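test_that("emax_effect honours the Hill identities for all reference sets", {
  ref <- wdd_reference_pkpd()
  for (i in seq_len(nrow(ref))) {
    p <- emax_params(ref$emax[i], ref$ed50[i], ref$gamma[i])
    # exact half-maximum at ED50
    expect_identical(emax_effect(p$ed50, p), p$emax / 2)
    # bounded above by emax, monotone nondecreasing, 0 at C = 0
    grid <- c(0, p$ed50 * 10^seq(-3, 3, by = 0.25))
    eff <- emax_effect(grid, p)
    expect_equal(eff[1], 0)
    # bounded by emax (attained only in the floating-point limit of the
    # far plateau) and strictly below it at moderate concentrations
    expect_true(all(eff <= p$emax))
    expect_lt(emax_effect(2 * p$ed50, p), p$emax)
    expect_true(all(diff(eff) >= 0))
  }
  expect_error(emax_effect(-1, emax_params(1, 1, 1)), "nonnegative")
})

test_that("reference curve values evaluate as expected", {
  tri <- emax_params(0.2378, 242.52, 2.62)
  expect_equal(emax_effect(242.52, tri), 0.1189)
  # direct arithmetic evaluation at C = 100:
  # 0.2378 * 100^2.62 / (242.52^2.62 + 100^2.62)
  expect_equal(emax_effect(100, tri),
               0.2378 * 100^2.62 / (242.52^2.62 + 100^2.62),
               tolerance = 1e-12)
  expect_equal(emax_effect(100, tri), 0.02125, tolerance = 1e-3)
})

test_that("noiseless recovery returns every reference parameter set", {
  ref <- wdd_reference_pkpd()
  for (i in seq_len(nrow(ref))) {
    truth <- emax_params(ref$emax[i], ref$ed50[i], ref$gamma[i])
    d <- recovery_pairs(truth)
    fit <- suppressWarnings(fit_sigmoid_emax(d$concs, d$effects))
    expect_true(fit$converged)
    expect_equal(fit$params$emax, truth$emax, tolerance = 1e-3)
    expect_equal(fit$params$ed50, truth$ed50, tolerance = 1e-3)
    expect_equal(fit$params$gamma, truth$gamma, tolerance = 1e-3)
  }
})

test_that("fit is order-invariant and recovers a unit Hill exponent", {
  truth <- emax_params(0.15, 30, 1)
  d <- recovery_pairs(truth)
  fit <- suppressWarnings(fit_sigmoid_emax(d$concs, d$effects))
  expect_equal(fit$params$gamma, 1, tolerance = 1e-6)
  perm <- sample(length(d$concs))
  fit2 <- suppressWarnings(fit_sigmoid_emax(d$concs[perm],
                                            d$effects[perm]))
  expect_equal(fit2$params$ed50, fit$params$ed50, tolerance = 1e-8)
  # degenerate inputs
  expect_error(fit_sigmoid_emax(d$concs, rep(0, length(d$concs))),
               "no concentration-effect response")
  expect_error(fit_sigmoid_emax(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               "at least 4")
})

test_that("noisy recovery: median ED50 error < 10% at gamma >= 2", {
  truth <- emax_params(0.2, 60, 2.5)
  d <- recovery_pairs(truth)
  errs <- vapply(1:20, function(r) {
    set.seed(500 + r)
    noisy <- d$effects * (1 + rnorm(length(d$effects), 0, 0.05))
    fit <- suppressWarnings(fit_sigmoid_emax(d$concs, pmax(noisy, 0)))
    abs(fit$params$ed50 - truth$ed50) / truth$ed50
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("hysteresis statistic: shoelace area, orientation, degeneracy", {
  # unit square in time order, counterclockwise
  sq <- hysteresis_loop_area(c(1, 2, 2, 1), c(0, 0, 1, 1))
  expect_equal(sq$signed_area, 1)
  expect_equal(sq$direction, "counterclockwise")
  # reversing time order flips the sign
  rev_sq <- hysteresis_loop_area(rev(c(1, 2, 2, 1)), rev(c(0, 0, 1, 1)))
  expect_equal(rev_sq$signed_area, -1)
  expect_equal(rev_sq$direction, "clockwise")
  # lag-free linear link collapses the loop
  prof <- noiseless_profile(spec_1c())
  lin <- hysteresis_loop_area(prof$conc, 0.01 * prof$conc)
  expect_equal(lin$direction, "none")
  expect_equal(lin$signed_area, 0, tolerance = 1e-8)
  expect_error(hysteresis_loop_area(c(1, 2), c(1, 2)), "at least 3")
  expect_error(hysteresis_loop_area(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("an equilibration lag produces a counterclockwise loop", {
  prof <- noiseless_profile(spec_1c())
  p <- emax_params(0.2, 40, 3)
  base <- 1
  lagged <- simulate_effect_series(prof, p, base, noise_sd = 0, lag = 1.5)
  direct <- simulate_effect_series(prof, p, base, noise_sd = 0, lag = 0)
  # effect magnitude = baseline - LPO level
  loop_lag <- hysteresis_loop_area(prof$conc, base - lagged$values)
  loop_dir <- hysteresis_loop_area(prof$conc, base - direct$values)
  expect_equal(loop_lag$direction, "counterclockwise")
  expect_equal(loop_dir$direction, "none")
})

test_that("effect-concentration curve passes the landmarks", {
  p <- emax_params(0.139, 242.52, 13.18)
  grid <- c(0, 100, 242.52, 500, 1000)
  curve <- build_effect_concentration_curve(p, grid)
  expect_equal(curve$effect[curve$conc_ng_per_ml == 242.52], p$emax / 2)
  expect_true(all(diff(curve$effect) >= 0))
  # 10-90% rise ratio is 81^(1/gamma) for any Hill curve
  gl <- emax_params(0.1387, 7.46, 13.46)
  c10 <- gl$ed50 * (1 / 9)^(1 / gl$gamma)
  c90 <- gl$ed50 * 9^(1 / gl$gamma)
  expect_equal(emax_effect(c10, gl), 0.1 * gl$emax, tolerance = 1e-10)
  expect_equal(emax_effect(c90, gl), 0.9 * gl$emax, tolerance = 1e-10)
  expect_equal(c90 / c10, 81^(1 / 13.46), tolerance = 1e-12)
  expect_equal(81^(1 / 13.46), 1.386, tolerance = 1e-3)
})
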