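test_that("cmax/tmax uses the earliest maximum and honest errors", {
  expect_equal(compute_cmax_tmax(conc_profile(c(1, 2, 4, 8),
                                              c(5, 9, 9, 3))),
               list(cmax = 9, tmax = 2))
  expect_equal(compute_cmax_tmax(conc_profile(0.25, 12)),
               list(cmax = 12, tmax = 0.25))
  allblq <- conc_profile(c(1, 2, 3), c(0, 0, 0), blq = rep(TRUE, 3),
                         compound = "naringin", subject = "LTG_2")
  expect_error(compute_cmax_tmax(allblq), "naringin")
  expect_error(compute_cmax_tmax(allblq), "LTG_2")
  # the Bateman profile on the study grid peaks at the grid point just
  # below the analytic 2.5584 h
  prof <- noiseless_profile(spec_1c())
  expect_equal(compute_cmax_tmax(prof)$tmax, 2.5)
})

test_that("lambda_z recovers exact and contaminated terminal slopes", {
  tt <- c(4, 6, 8, 10, 12, 24)
  prof <- conc_profile(tt, 100 * exp(-0.2 * tt))
  lam <- estimate_lambda_z(prof)
  expect_equal(lam$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(lam$r2_adj, 1, tolerance = 1e-10)
  # scale invariance
  lam3 <- estimate_lambda_z(conc_profile(tt, 300 * exp(-0.2 * tt)))
  expect_equal(lam3$lambda_z, lam$lambda_z, tolerance = 1e-12)
  # 2C profile on the study grid: best terminal window lands within 5%
  # of the true beta
  lam2 <- estimate_lambda_z(noiseless_profile(spec_2c()))
  expect_equal(lam2$lambda_z, 0.08, tolerance = 0.05)
  # rising profile has no terminal decline
  expect_error(estimate_lambda_z(conc_profile(1:6, c(1, 2, 3, 4, 5, 6))),
               "decline|after Tmax")
})

test_that("AUC rules match closed forms and are additive", {
  # constant 10 ng/mL over [0, 24] -> rectangle; 'times > 0' so use 1e-9
  prof_const <- conc_profile(c(1e-9, 24), c(10, 10))
  expect_equal(compute_auc(prof_const, "linear"), 240, tolerance = 1e-6)
  # log-trapezoid on a descending segment: (t2-t1)(C1-C2)/ln(C1/C2)
  prof_down <- conc_profile(c(1, 3), c(100, 25))
  expect_equal(compute_auc(prof_down, "linear_up_log_down"),
               2 * 75 / log(4), tolerance = 1e-10)
  # ... which is exact for an exponential segment (fine Riemann check)
  fine <- seq(1, 3, length.out = 20001)
  riemann <- sum(100 * exp(-log(4) / 2 * (fine - 1))) * (3 - 1) / 20000
  expect_equal(compute_auc(prof_down, "linear_up_log_down"), riemann,
               tolerance = 1e-4)
  # linear AUC additivity over adjacent intervals
  prof <- conc_profile(c(1, 2, 5), c(3, 9, 4))
  expect_equal(
    compute_auc(conc_profile(c(1, 2), c(3, 9)), "linear") +
      compute_auc(conc_profile(c(2, 5), c(9, 4)), "linear"),
    compute_auc(prof, "linear"))
  # AUC scales linearly with concentration
  prof5 <- conc_profile(c(1, 2, 5), 5 * c(3, 9, 4))
  expect_equal(compute_auc(prof5), 5 * compute_auc(prof))
})

test_that("nca_summary composes the pieces and extrapolates to infinity", {
  tt <- seq(0.5, 24, by = 0.5)
  prof <- conc_profile(tt, 100 * exp(-0.2 * tt))
  res <- nca_summary(prof)
  expect_s3_class(res, "nca_result")
  expect_equal(res$t_half, log(2) / 0.2, tolerance = 1e-6)
  expect_equal(res$lambda_z, 0.2, tolerance = 1e-8)
  expect_equal(res$auc_0_inf, res$auc_0_t + res$cmax *
                 exp(-0.2 * (24 - 0.5)) / res$lambda_z, tolerance = 1e-6)
  # 2C noiseless: AUC0-inf within 2% of the analytic integral
  prof2 <- noiseless_profile(spec_2c())
  res2 <- nca_summary(prof2)
  auc_inf_true <- 80 / 1.2 + 20 / 0.08 - 100 / 3
  expect_equal(res2$auc_0_inf, auc_inf_true, tolerance = 0.02)
  # error contract: all-BLQ profile gives a stage-labelled error
  allblq <- conc_profile(c(1, 2, 3), c(0, 0, 0), blq = rep(TRUE, 3))
  expect_error(nca_summary(allblq), "\\[cmax/tmax\\]")
})

test_that("NCA on the noiseless 1C truth matches closed forms within 2%", {
  s <- spec_1c()
  prof <- noiseless_profile(s)
  res <- nca_summary(prof)
  cmax_true <- predict_concentration(s, log(10) / 0.9)
  auc_true <- 111.11 * ((1 - exp(-0.1 * 24)) / 0.1 - (1 - exp(-24)) / 1)
  # Tmax is grid-resolution: the grid argmax of the closed form
  grid_cmax <- max(predict_concentration(s, paper_grid))
  expect_equal(res$cmax, grid_cmax)
  expect_equal(res$cmax, cmax_true, tolerance = 0.02)
  expect_equal(res$t_half, log(2) / 0.1, tolerance = 0.02)
  expect_equal(res$auc_0_t, auc_true, tolerance = 0.02)
})
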