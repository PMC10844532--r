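test_that("calibration fitting recovers exact lines and flags degeneracy", {
  x <- c(60, 120, 300, 600, 1500, 3000, 4500, 6000)
  fit <- fit_calibration_line(x, 0.0030 * x + 0.0532)
  expect_equal(fit$slope, 0.0030, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.0532, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$linear_range, c(60, 6000))
  # shifting all responses moves only the intercept
  fit_c <- fit_calibration_line(x, 0.0030 * x + 0.0532 + 2)
  expect_equal(fit_c$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit_c$intercept, fit$intercept + 2, tolerance = 1e-10)
  # constant responses: slope 0, undefined r2, warned
  expect_warning(flat <- fit_calibration_line(x, rep(1, 8)), "identical")
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$r_squared))
  expect_error(fit_calibration_line(c(1, 2), c(1, 2)), "3 distinct")
})

test_that("back-calculation inverts the reference trigonelline line", {
  tri <- calibration_curve(0.0030, 0.0532, c(60, 6000))
  expect_equal(as.numeric(back_calculate(tri, 3.0532)), 1000,
               tolerance = 1e-10)
  expect_equal(as.numeric(back_calculate(tri, 0.0532)), 0)
  # round trip across the linear range, to floating tolerance
  x <- c(60, 120, 300, 600, 1500, 3000, 4500, 6000)
  expect_equal(as.numeric(back_calculate(tri, predict(tri, x))), x,
               tolerance = 1e-12)
  expect_true(all(attr(back_calculate(tri, predict(tri, x)), "in_range")))
  expect_false(attr(back_calculate(tri, predict(tri, 10)), "in_range"))
  expect_error(back_calculate(calibration_curve(0, 1, c(1, 2)), 5),
               "zero")
})

test_that("round trip holds for every reference calibration line", {
  cal <- wdd_reference_calibration()
  for (i in seq_len(nrow(cal))) {
    curve <- calibration_curve(cal$slope[i], cal$intercept[i],
                               c(cal$range_lower[i], cal$range_upper[i]),
                               cal$r_squared[i])
    x <- seq(cal$range_lower[i], cal$range_upper[i], length.out = 7)
    expect_equal(as.numeric(back_calculate(curve, predict(curve, x))), x,
                 tolerance = 1e-9)
  }
})

test_that("RSD and RE match hand-computed values and their invariances", {
  qc <- qc_statistics(c(90, 100, 110), 100)
  expect_equal(qc$rsd_pct, 10)  # sd = 10, mean = 100
  expect_equal(qc$re_pct, 0)
  exact <- qc_statistics(rep(250, 5), 250)
  expect_equal(exact$rsd_pct, 0)
  expect_equal(exact$re_pct, 0)
  # RSD is invariant under uniform scaling
  a <- qc_statistics(c(4, 5, 6), 5)
  b <- qc_statistics(10 * c(4, 5, 6), 50)
  expect_equal(a$rsd_pct, b$rsd_pct)
  expect_error(qc_statistics(c(5), 5), "n >= 2")
  expect_error(qc_statistics(c(-1, 1), 5), "undefined")
})

test_that("QC simulated with proportional CV recovers that RSD", {
  set.seed(42)
  cv <- 0.08
  reps <- replicate(1000, {
    m <- 100 * (1 + rnorm(6, 0, cv))
    qc_statistics(m, 100)$rsd_pct
  })
  expect_equal(mean(reps), 100 * cv, tolerance = 0.05)
})

test_that("ratio metrics are plain percentages with guards", {
  expect_equal(ratio_metric(100, 100), 100)
  expect_equal(ratio_metric(89.23, 100), 89.23)
  expect_equal(ratio_metric(3, 4) * ratio_metric(4, 3), 1e4)
  expect_error(ratio_metric(1, 0), "positive")
})

test_that("qc_summary_table aggregates per compound and level", {
  qc <- data.frame(
    compound = rep(c("naringin", "quercetin"), each = 6),
    level = rep(c(6, 300, 13, 650), each = 3),
    measured = c(5.8, 6.1, 6.3, 290, 310, 305, 13.4, 12.7, 13.1,
                 640, 655, 660))
  tab <- qc_summary_table(qc)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$n, rep(3L, 4))
  row <- tab[tab$compound == "naringin" & tab$level == 6, ]
  expect_equal(row$re_pct, 100 * (mean(c(5.8, 6.1, 6.3)) - 6) / 6)
})
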