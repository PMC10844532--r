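#' Peak concentration and its time
#'
#' The maximum observed quantifiable concentration and the time at which it
#' occurs; ties are broken by the earliest time (the conventional rule).
#'
#' @param profile A [conc_profile()] with at least one quantifiable point.
#' @return A list with `cmax` (ng/mL) and `tmax` (h).
#' @examples
#' compute_cmax_tmax(conc_profile(c(1, 2, 4, 8), c(5, 9, 9, 3)))
#' @export
compute_cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  q <- quantifiable(profile, 1L, "Cmax/Tmax")
  i <- which.max(q$conc)  # which.max returns the first (earliest) maximum
  list(cmax = q$conc[i], tmax = q$times[i])
}

#' Terminal elimination rate constant by best-fit log-linear regression
#'
#' Estimates lambda_z as the negative slope of a log-linear regression over
#' the terminal portion of the profile. Following the de-facto standard
#' "best fit" rule, every contiguous terminal window of at least
#' `min_points` quantifiable points strictly after Tmax is evaluated and
#' the window with the highest adjusted r-squared wins; windows within
#' 1e-4 of the best are resolved in favour of more points.
#'
#' @param profile A [conc_profile()].
#' @param min_points Minimum points per candidate window (>= 3).
#' @return A list with `lambda_z` (1/h), `r2_adj`, `points_used`, and the
#'   window `times`.
#' @examples
#' t <- c(4, 6, 8, 10, 12, 24)
#' estimate_lambda_z(conc_profile(t, 100 * exp(-0.2 * t)))
#' @export
estimate_lambda_z <- function(profile, min_points = 3L) {
  stopifnot(inherits(profile, "conc_profile"))
  if (min_points < 3L) stop_arg("min_points must be >= 3")
  q <- quantifiable(profile, min_points, "lambda_z estimation")
  tmax <- q$times[which.max(q$conc)]
  keep <- q$times > tmax & q$conc > 0
  tt <- q$times[keep]
  cc <- q$conc[keep]
  n_total <- length(tt)
  if (n_total < min_points) {
    stop_arg("lambda_z estimation needs at least ", min_points,
             " positive points strictly after Tmax; ",
             profile_label(profile), " has ", n_total)
  }
  best <- NULL
  for (start in seq_len(n_total - min_points + 1L)) {
    idx <- start:n_total
    fit <- lm(log(cc[idx]) ~ tt[idx])
    slope <- coef(fit)[[2]]
    if (slope >= 0) next
    # r2 computed directly: summary.lm warns on near-perfect fits
    y <- log(cc[idx])
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    cand <- list(lambda_z = -slope, r2_adj = adj_r2(r2, length(idx)),
                 points_used = length(idx), times = tt[idx])
    if (is.null(best) ||
        cand$r2_adj > best$r2_adj + 1e-4 ||
        (abs(cand$r2_adj - best$r2_adj) <= 1e-4 &&
         cand$points_used > best$points_used)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop_arg("no terminal window with a negative log-linear slope: ",
             profile_label(profile), " shows no terminal decline")
  }
  best
}

# Trapezoid over one segment; log variant is exact when the curve is
# exponential between the two samples.
segment_auc <- function(t1, t2, c1, c2, method) {
  if (method == "linear_up_log_down" && c2 < c1 && c1 > 0 && c2 > 0) {
    (t2 - t1) * (c1 - c2) / log(c1 / c2)
  } else {
    (t2 - t1) * (c1 + c2) / 2
  }
}

#' Area under the concentration-time curve to the last quantifiable sample
#'
#' Trapezoidal AUC from the first to the last quantifiable time. The
#' default `linear_up_log_down` rule uses the linear trapezoid on rising
#' or flat segments and the logarithmic trapezoid on declining segments
#' (exact for exponential decline); `linear` applies the plain trapezoid
#' throughout. Units: ng.h/mL, reported as ug.h/L -- the conversion is the
#' identity (1 ng/mL = 1 ug/L).
#'
#' @param profile A [conc_profile()] with >= 2 quantifiable points.
#' @param method `"linear_up_log_down"` (default) or `"linear"`.
#' @return AUC0-t (ug.h/L).
#' @examples
#' compute_auc(conc_profile(c(1, 3), c(100, 25)))           # log-down
#' compute_auc(conc_profile(c(1, 3), c(100, 25)), "linear") # trapezoid
#' @export
compute_auc <- function(profile,
                        method = c("linear_up_log_down", "linear")) {
  stopifnot(inherits(profile, "conc_profile"))
  method <- match.arg(method)
  q <- quantifiable(profile, 2L, "AUC")
  sum(vapply(seq_len(length(q$times) - 1L), function(i) {
    segment_auc(q$times[i], q$times[i + 1L], q$conc[i], q$conc[i + 1L],
                method)
  }, numeric(1)))
}

#' Noncompartmental summary of a concentration-time profile
#'
#' Composes [compute_cmax_tmax()], [estimate_lambda_z()] and
#' [compute_auc()] into the standard NCA report: Cmax, Tmax, lambda_z,
#' t1/2 = ln(2)/lambda_z, AUC0-t and the extrapolated
#' AUC0-inf = AUC0-t + Clast/lambda_z, with the lambda_z fit diagnostics.
#'
#' @param profile A [conc_profile()].
#' @param auc_method Passed to [compute_auc()].
#' @param min_points Passed to [estimate_lambda_z()].
#' @return An object of class `nca_result` (a list with fields `cmax`,
#'   `tmax`, `lambda_z`, `t_half`, `auc_0_t`, `auc_0_inf`,
#'   `lambda_points`, `lambda_r2_adj`, `compound`, `subject`).
#' @examples
#' t <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24)
#' spec <- pk_model_spec("one_compartment_ev", ka = 1, coefs = 111.11,
#'                       rates = 0.1)
#' nca_summary(conc_profile(t, predict_concentration(spec, t)))
#' @export
nca_summary <- function(profile,
                        auc_method = c("linear_up_log_down", "linear"),
                        min_points = 3L) {
  stopifnot(inherits(profile, "conc_profile"))
  auc_method <- match.arg(auc_method)
  peak <- tryCatch(compute_cmax_tmax(profile), error = function(e) {
    stop_arg("[cmax/tmax] ", conditionMessage(e))
  })
  lam <- tryCatch(estimate_lambda_z(profile, min_points),
                  error = function(e) {
                    stop_arg("[lambda_z] ", conditionMessage(e))
                  })
  auc <- tryCatch(compute_auc(profile, auc_method), error = function(e) {
    stop_arg("[auc] ", conditionMessage(e))
  })
  q <- quantifiable(profile, 1L, "NCA")
  c_last <- q$conc[length(q$conc)]
  structure(
    list(cmax = peak$cmax, tmax = peak$tmax, lambda_z = lam$lambda_z,
         t_half = log(2) / lam$lambda_z, auc_0_t = auc,
         auc_0_inf = auc + c_last / lam$lambda_z,
         lambda_points = lam$points_used, lambda_r2_adj = lam$r2_adj,
         compound = profile$compound, subject = profile$subject),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>", x$compound, "subject", x$subject, "\n")
  cat(sprintf("  Cmax   %10.4g ng/mL at Tmax %.3g h\n", x$cmax, x$tmax))
  cat(sprintf("  lambda_z %8.4g 1/h (t1/2 %.4g h; %d points, adj r2 %.4f)\n",
              x$lambda_z, x$t_half, x$lambda_points, x$lambda_r2_adj))
  cat(sprintf("  AUC0-t %10.6g ug*h/L   AUC0-inf %10.6g ug*h/L\n",
              x$auc_0_t, x$auc_0_inf))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(compound = x$compound, subject = x$subject, cmax = x$cmax,
             tmax = x$tmax, lambda_z = x$lambda_z, t_half = x$t_half,
             auc_0_t = x$auc_0_t, auc_0_inf = x$auc_0_inf,
             lambda_points = x$lambda_points,
             lambda_r2_adj = x$lambda_r2_adj)
}
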