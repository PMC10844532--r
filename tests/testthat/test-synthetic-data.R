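test_that("extravascular closed forms behave at the boundaries", {
  s1 <- spec_1c()
  # C(0) = 0 and C(t -> 0+) -> 0 for any extravascular spec with no lag
  expect_equal(predict_concentration(s1, 0), 0)
  expect_lt(predict_concentration(s1, 1e-8), 1e-5)
  s2 <- spec_2c()
  expect_equal(predict_concentration(s2, 0), 0)
  # Bateman peak: Tmax = ln(ka/ke)/(ka - ke), checked against a dense grid
  tmax_analytic <- log(1 / 0.1) / (1 - 0.1)
  grid <- seq(0.01, 12, by = 1e-4)
  tmax_grid <- grid[which.max(predict_concentration(s1, grid))]
  expect_equal(tmax_analytic, 2.5584, tolerance = 1e-4)
  expect_equal(tmax_grid, tmax_analytic, tolerance = 1e-3)
  # peak height, derived by direct evaluation of the closed form
  expect_equal(predict_concentration(s1, tmax_analytic), 77.4256,
               tolerance = 1e-5)
})

test_that("degenerate and invalid model specs are rejected", {
  expect_error(pk_model_spec("one_compartment_ev", ka = 0.1,
                             coefs = 100, rates = 0.1), "degenerate")
  expect_error(pk_model_spec("two_compartment_ev", ka = 3,
                             coefs = c(80, 20), rates = c(0.08, 1.2)),
               "alpha > beta")
  expect_error(pk_model_spec("one_compartment_ev", ka = -1, coefs = 100,
                             rates = 0.1), "positive")
  expect_error(simulate_pk_profile(spec_1c(), c(-1, 2), seed = 1),
               "positive")
})

test_that("2C prediction with a vanishing second phase nests the 1C form", {
  s1 <- spec_1c()
  s2 <- pk_model_spec("two_compartment_ev", ka = 1,
                      coefs = c(111.11, 1e-12), rates = c(0.1, 0.01))
  expect_equal(predict_concentration(s2, paper_grid),
               predict_concentration(s1, paper_grid), tolerance = 1e-10)
})

test_that("simulated profiles are reproducible and correctly noised", {
  s <- spec_1c()
  p1 <- simulate_pk_profile(s, paper_grid, noise_cv = 0.1, seed = 7)
  p2 <- simulate_pk_profile(s, paper_grid, noise_cv = 0.1, seed = 7)
  expect_identical(p1, p2)
  p3 <- simulate_pk_profile(s, paper_grid, noise_cv = 0.1, seed = 8)
  expect_false(all(p1$conc == p3$conc))
  # noiseless simulation equals the predictor exactly
  p0 <- simulate_pk_profile(s, paper_grid, noise_cv = 0, seed = 1)
  expect_equal(p0$conc, predict_concentration(s, paper_grid))
  # the lognormal multiplier has mean 1: large-sample check
  many <- simulate_pk_profile(s, seq(1, 5000), noise_cv = 0.2, seed = 11)
  ratio <- many$conc / predict_concentration(s, seq(1, 5000))
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(sd(ratio), 0.2, tolerance = 0.02)
})

test_that("doubling the coefficients doubles every noiseless concentration", {
  s <- spec_2c()
  s2x <- pk_model_spec(s$model_kind, s$ka, s$coefs * 2, s$rates)
  expect_equal(predict_concentration(s2x, paper_grid),
               2 * predict_concentration(s, paper_grid))
})

test_that("effect series follows the direct-link Emax model", {
  p <- emax_params(0.2, 50, 3)
  # zero concentration everywhere -> effect at baseline
  prof0 <- conc_profile(paper_grid, rep(0, length(paper_grid)))
  e0 <- simulate_effect_series(prof0, p, baseline = 1, noise_sd = 0)
  expect_equal(e0$values, rep(1, length(paper_grid)))
  # constant C = ED50 -> baseline - emax/2 everywhere
  prof50 <- conc_profile(paper_grid, rep(50, length(paper_grid)))
  e50 <- simulate_effect_series(prof50, p, baseline = 1, noise_sd = 0)
  expect_equal(e50$values, rep(1 - 0.1, length(paper_grid)))
  # noiseless direct link: effect nadir coincides with Tmax
  prof <- noiseless_profile(spec_1c())
  eff <- simulate_effect_series(prof, p, baseline = 1, noise_sd = 0)
  expect_equal(effect_nadir(eff)$time, compute_cmax_tmax(prof)$tmax)
  expect_error(simulate_effect_series(prof, p, 1, noise_sd = -0.1),
               "nonnegative")
})

test_that("generate_study produces the full flagged, reproducible dataset", {
  cfg <- tiny_config(seed = 5)
  ds1 <- generate_study(cfg)
  ds2 <- generate_study(tiny_config(seed = 5))
  expect_identical(ds1, ds2)
  # 2 treated subjects x 2 compounds x 14 times
  expect_equal(nrow(ds1$concentrations), 2 * 2 * 14)
  # control group carries effect records only
  expect_false("MCG" %in% ds1$concentrations$group)
  expect_true(all(c("MCG", "LTG") %in% ds1$effects$group))
  # ground truth registry covers both compounds
  expect_setequal(ds1$ground_truth$compound, c("cmpA", "cmpB"))
  # BLQ flags applied wherever stored concentration fell below LLOQ
  expect_true(all(ds1$concentrations$conc_ng_per_ml[
    ds1$concentrations$blq] == 0))
  expect_true(all(ds1$concentrations$conc_ng_per_ml[
    !ds1$concentrations$blq] >= 0.5))
})

test_that("an LLOQ above the whole curve flags every record BLQ", {
  compounds <- data.frame(compound = "cmpA", lloq = 1e6,
                          stringsAsFactors = FALSE)
  compounds$spec <- list(spec_1c())
  compounds$pd <- list(emax_params(0.2, 60, 2.5))
  groups <- data.frame(name = "LTG", n_subjects = 1L, dose = 2.2,
                       stringsAsFactors = FALSE)
  cfg <- study_config(groups, compounds, paper_grid, seed = 1)
  ds <- generate_study(cfg)
  expect_true(all(ds$concentrations$blq))
})

test_that("duplicate group or compound names are rejected", {
  compounds <- data.frame(compound = c("x", "x"), lloq = 1,
                          stringsAsFactors = FALSE)
  compounds$spec <- list(spec_1c(), spec_2c())
  compounds$pd <- list(emax_params(1, 1, 1), emax_params(1, 1, 1))
  groups <- data.frame(name = c("A", "A"), n_subjects = 1L, dose = 1,
                       stringsAsFactors = FALSE)
  expect_error(study_config(groups, compounds[1, ], paper_grid),
               "duplicate group")
  expect_error(
    study_config(data.frame(name = "A", n_subjects = 1L, dose = 1),
                 compounds, paper_grid),
    "duplicate compound")
})

test_that("the default study reproduces the four-group design", {
  cfg <- default_study_config(seed = 2)
  ds <- generate_study(cfg)
  # 12 treated rats x 10 compounds x 14 sample times
  expect_equal(nrow(ds$concentrations), 12 * 10 * 14)
  # 24 rats x 15 effect times (pre-dose + 14)
  expect_equal(nrow(ds$effects), 24 * 15)
  # generator kinetics hit their NCA anchors on the continuous curve
  truth <- ds$ground_truth
  ref <- wdd_reference_nca()
  ltg <- ref[ref$group == "LTG", ]
  for (i in seq_len(nrow(truth))) {
    coefs <- c(truth$coef_1[i], truth$coef_2[i])
    rates <- c(truth$rate_1[i], truth$rate_2[i])
    keep <- !is.na(coefs)
    spec <- pk_model_spec(truth$model_kind[i], truth$ka[i], coefs[keep],
                          rates[keep])
    peak <- optimize(function(t) predict_concentration(spec, t),
                     c(0, 24), maximum = TRUE, tol = 1e-9)
    anchor <- ltg[ltg$compound == truth$compound[i], ]
    expect_equal(peak$objective, anchor$cmax_ng_per_ml, tolerance = 1e-4)
    # terminal half-life comes from the slowest phase
    expect_equal(log(2) / min(rates[keep]), anchor$t_half_h,
                 tolerance = 1e-6)
  }
})
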