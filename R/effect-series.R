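#' Construct an effect-time series
#'
#' A time-ordered series of pharmacodynamic effect values -- either raw
#' biomarker levels (e.g. plasma lipid peroxide, LPO) or control-corrected
#' changes (delta-LPO). Effect units are abstract (assay-kit dependent).
#'
#' @param times Observation times (h), strictly increasing, >= 0 (time 0 is
#'   the pre-dose baseline sample).
#' @param values Effect values, same length as `times`.
#' @param group,reference_group Optional labels; `reference_group` records
#'   which control was subtracted for a corrected series.
#' @return An object of class `effect_series`.
#' @export
effect_series <- function(times, values, group = NA_character_,
                          reference_group = NA_character_) {
  if (!is.numeric(times) || length(times) == 0L || anyNA(times) ||
      any(times < 0)) {
    stop_arg("times must be nonnegative numbers")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop_arg("times must be strictly increasing")
  }
  if (!is.numeric(values) || length(values) != length(times) ||
      anyNA(values)) {
    stop_arg("values must be numeric, NA-free and match times in length")
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         group = as.character(group),
         reference_group = as.character(reference_group)),
    class = "effect_series"
  )
}

#' @export
print.effect_series <- function(x, ...) {
  lab <- if (!is.na(x$reference_group)) {
    paste0(x$group, " - ", x$reference_group)
  } else {
    x$group
  }
  cat("<effect_series>", lab, "-", length(x$times), "time points\n")
  print(data.frame(time_h = x$times, effect = x$values), row.names = FALSE)
  invisible(x)
}
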