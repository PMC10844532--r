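#' Fit a bioanalytical calibration line
#'
#' Ordinary least-squares line of instrument response against nominal
#' concentration, as used to back-calculate plasma concentrations batch by
#' batch. Weighted regression with weights 1/x^2 (common when assay error
#' is proportional) is available via `weighting`.
#'
#' @param nominal_concs Nominal calibration concentrations (ng/mL), >= 3
#'   distinct levels.
#' @param responses Instrument responses (e.g. analyte/IS peak-area
#'   ratio), same length.
#' @param weighting `"none"` (default, plain OLS) or `"1/x2"`.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `linear_range` (c(lower, upper)),
#'   `degenerate` (TRUE when the responses carry no slope information).
#' @examples
#' x <- c(60, 120, 300, 600, 1500, 3000, 4500, 6000)
#' fit_calibration_line(x, 0.0030 * x + 0.0532)
#' @export
fit_calibration_line <- function(nominal_concs, responses,
                                 weighting = c("none", "1/x2")) {
  weighting <- match.arg(weighting)
  if (length(nominal_concs) != length(responses)) {
    stop_arg("nominal_concs and responses must have equal length")
  }
  if (length(unique(nominal_concs)) < 3L) {
    stop_arg("calibration needs at least 3 distinct concentration levels")
  }
  w <- if (weighting == "1/x2") 1 / nominal_concs^2 else NULL
  fit <- lm(responses ~ nominal_concs, weights = w)
  degenerate <- sd(responses) == 0
  r2 <- if (degenerate) {
    NA_real_
  } else {
    # computed directly: summary.lm warns on exact lines
    1 - sum(fit$residuals^2) / sum((responses - mean(responses))^2)
  }
  if (degenerate) {
    warning("all responses identical: slope 0, r-squared undefined",
            call. = FALSE)
  }
  structure(
    list(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
         r_squared = r2,
         linear_range = range(nominal_concs), degenerate = degenerate),
    class = "calibration_curve"
  )
}

#' Construct a calibration curve from known coefficients
#'
#' Wraps published or externally fitted line coefficients in the
#' `calibration_curve` container so [back_calculate()] can use them.
#'
#' @param slope,intercept Line coefficients (response per ng/mL, response).
#' @param linear_range Length-2 numeric, lower < upper (ng/mL).
#' @param r_squared Optional reported coefficient of determination.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, linear_range,
                              r_squared = NA_real_) {
  if (length(linear_range) != 2L || linear_range[1] >= linear_range[2]) {
    stop_arg("linear_range must be c(lower, upper) with lower < upper")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop_arg("r_squared must lie in [0, 1]")
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         linear_range = as.numeric(linear_range), degenerate = slope == 0),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> Y = %.6gX %+.6g (r2 %s), range %g-%g ng/mL\n",
              x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", format(x$r_squared)),
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Back-calculate concentrations from instrument responses
#'
#' Inverts the calibration line: `(response - intercept) / slope`.
#' Results outside the linear range are returned but flagged via the
#' `in_range` attribute.
#'
#' @param curve A `calibration_curve`.
#' @param response Instrument response(s).
#' @return Concentration(s) in ng/mL, with attribute `in_range`.
#' @examples
#' tri <- calibration_curve(0.0030, 0.0532, c(60, 6000))
#' back_calculate(tri, 3.0532)  # 1000 ng/mL
#' @export
back_calculate <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    stop_arg("calibration slope is zero; cannot back-calculate")
  }
  conc <- (response - curve$intercept) / curve$slope
  attr(conc, "in_range") <- conc >= curve$linear_range[1] &
    conc <= curve$linear_range[2]
  conc
}

#' Predict instrument response from a calibration curve
#'
#' @param object A `calibration_curve`.
#' @param conc Concentration(s) in ng/mL.
#' @param ... Unused.
#' @return Predicted response(s).
#' @export
predict.calibration_curve <- function(object, conc, ...) {
  object$intercept + object$slope * conc
}

#' Precision and accuracy of quality-control replicates
#'
#' Relative standard deviation (precision) and relative error (accuracy)
#' of replicate measurements at one nominal level:
#' RSD% = 100 * sd / mean (sample, n-1 denominator) and
#' RE% = 100 * (mean - nominal) / nominal.
#'
#' @param measured Replicate measured concentrations, n >= 2.
#' @param nominal Nominal (spiked) concentration, > 0.
#' @return A list with `level`, `n`, `rsd_pct`, `re_pct`.
#' @examples
#' qc_statistics(c(90, 100, 110), 100)  # RSD 10%, RE 0%
#' @export
qc_statistics <- function(measured, nominal) {
  if (length(measured) < 2L) stop_arg("need n >= 2 replicates for RSD")
  if (!is.numeric(nominal) || length(nominal) != 1L || nominal <= 0) {
    stop_arg("nominal must be a single positive concentration")
  }
  m <- mean(measured)
  if (abs(m) < 1e-12) {
    stop_arg("mean measured value is ~0; RSD is undefined")
  }
  list(level = nominal, n = length(measured),
       rsd_pct = 100 * sd(measured) / m,
       re_pct = 100 * (m - nominal) / nominal)
}

#' Summarise a table of quality-control replicates
#'
#' Applies [qc_statistics()] per (compound, level) to a long table of QC
#' measurements, producing the usual validation summary layout.
#'
#' @param qc_data data.frame with columns `compound`, `level` (nominal
#'   ng/mL) and `measured` (ng/mL), one row per replicate.
#' @return data.frame with one row per compound and level: `n`,
#'   `rsd_pct`, `re_pct`.
#' @export
qc_summary_table <- function(qc_data) {
  check_columns(qc_data, c("compound", "level", "measured"), "QC table")
  parts <- split(qc_data, list(qc_data$compound, qc_data$level),
                 drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    s <- qc_statistics(d$measured, d$level[1])
    data.frame(compound = d$compound[1], level = s$level, n = s$n,
               rsd_pct = s$rsd_pct, re_pct = s$re_pct,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$compound, out$level), ]
  rownames(out) <- NULL
  out
}

#' Ratio metric for recovery and matrix-effect assessment
#'
#' `100 * test_mean / reference_mean`: extraction recovery compares
#' extracted spikes against post-extraction spikes; matrix effect compares
#' matrix-spiked response against neat solution.
#'
#' @param test_mean Mean response of the test condition.
#' @param reference_mean Mean response of the reference condition, > 0.
#' @return Percentage.
#' @examples
#' ratio_metric(89.23, 100)
#' @export
ratio_metric <- function(test_mean, reference_mean) {
  if (!is.numeric(reference_mean) || length(reference_mean) != 1L ||
      reference_mean <= 0) {
    stop_arg("reference_mean must be a single positive number")
  }
  100 * test_mean / reference_mean
}
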