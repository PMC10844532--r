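# Collapse an effects data.frame (columns time_h/lpo, possibly several
# subjects) or an effect_series into a per-time mean series.
as_mean_series <- function(x, group = NA_character_) {
  if (inherits(x, "effect_series")) return(x)
  if (is.data.frame(x)) {
    tcol <- intersect(c("time_h", "times", "time"), names(x))[1]
    vcol <- intersect(c("lpo", "value", "values", "effect"), names(x))[1]
    if (is.na(tcol) || is.na(vcol)) {
      stop_arg("effect data.frame needs a time column (time_h) and a ",
               "value column (lpo)")
    }
    agg <- tapply(x[[vcol]], x[[tcol]], mean)
    tt <- as.numeric(names(agg))
    o <- order(tt)
    if ("group" %in% names(x) && length(unique(x$group)) == 1L) {
      group <- x$group[1]
    }
    return(effect_series(tt[o], as.numeric(agg)[o], group = group))
  }
  stop_arg("expected an effect_series or a data.frame of effect records")
}

#' Control-corrected pharmacodynamic effect series
#'
#' Pointwise subtraction of a control group's biomarker series from a
#' treated group's: delta-LPO(t) = LPO_treated(t) - LPO_control(t). When
#' several subjects are supplied (data.frames of effect records), per-time
#' means are taken first. Time grids must match exactly unless
#' `interpolate = TRUE`, in which case the control mean is linearly
#' interpolated onto the treated grid.
#'
#' An alternative correction against the treated group's own pre-dose
#' level (`reference = "baseline"`) subtracts the value at the earliest
#' time instead of a control series.
#'
#' @param treated,control [effect_series()] objects or data.frames of
#'   effect records (columns `time_h`, `lpo`, optionally `subject`,
#'   `group`). `control` is ignored when `reference = "baseline"`.
#' @param reference `"control"` (default) or `"baseline"`.
#' @param interpolate Allow linear interpolation of the control onto the
#'   treated grid (default `FALSE`).
#' @return An [effect_series()] of delta values.
#' @examples
#' trt <- effect_series(c(1, 2, 4), c(5.0, 4.2, 4.8), group = "LTG")
#' ctl <- effect_series(c(1, 2, 4), c(7.0, 7.1, 6.9), group = "MCG")
#' compute_delta_effect(trt, ctl)
#' @export
compute_delta_effect <- function(treated, control = NULL,
                                 reference = c("control", "baseline"),
                                 interpolate = FALSE) {
  reference <- match.arg(reference)
  trt <- as_mean_series(treated)
  if (reference == "baseline") {
    return(effect_series(trt$times, trt$values - trt$values[1],
                         group = trt$group,
                         reference_group = "baseline"))
  }
  if (is.null(control)) {
    stop_arg("a control series is required for reference = 'control'")
  }
  ctl <- as_mean_series(control)
  if (length(trt$times) == length(ctl$times) &&
      all(trt$times == ctl$times)) {
    cvals <- ctl$values
  } else if (interpolate) {
    overlap <- trt$times >= min(ctl$times) & trt$times <= max(ctl$times)
    if (!all(overlap)) {
      stop_arg("treated times extend beyond the control grid; cannot ",
               "interpolate outside it")
    }
    cvals <- stats::approx(ctl$times, ctl$values, xout = trt$times)$y
  } else {
    stop_arg("treated and control time grids differ; set ",
             "interpolate = TRUE to interpolate the control mean")
  }
  effect_series(trt$times, trt$values - cvals, group = trt$group,
                reference_group = ctl$group)
}

#' Time and value of the effect nadir
#'
#' The minimum of an effect series and the time at which it occurs (ties
#' broken by the earliest time). For a biomarker suppressed by treatment,
#' this is the time of maximal drug effect; under a lag-free direct-link
#' model it coincides with the concentration peak.
#'
#' @param series An [effect_series()].
#' @return A list with `time` (h) and `value`.
#' @examples
#' effect_nadir(effect_series(c(1, 2, 4), c(-1, -3, -2)))
#' @export
effect_nadir <- function(series) {
  stopifnot(inherits(series, "effect_series"))
  i <- which.min(series$values)  # first minimum = earliest tie
  list(time = series$times[i], value = series$values[i])
}
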