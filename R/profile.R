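#' Construct a concentration-time profile
#'
#' A single subject-by-compound time-ordered series of plasma
#' concentrations with below-limit-of-quantification (BLQ) flags. This is
#' the unit of input for noncompartmental and compartmental analysis.
#'
#' @param times Sampling times (h), strictly increasing and positive.
#' @param conc Concentrations (ng/mL), nonnegative, same length as `times`.
#' @param blq Logical BLQ flags, recycled from `FALSE` if omitted.
#' @param compound,subject Optional labels used in error messages and
#'   reports.
#' @return An object of class `conc_profile`.
#' @examples
#' conc_profile(c(0.5, 1, 2, 4), c(40, 70, 77, 60), compound = "naringin")
#' @export
conc_profile <- function(times, conc, blq = NULL, compound = NA_character_,
                         subject = NA_character_) {
  check_times(times)
  if (length(conc) != length(times)) {
    stop_arg("times and conc must have equal length")
  }
  if (!is.numeric(conc) || anyNA(conc) || any(conc < 0)) {
    stop_arg("concentrations must be nonnegative numbers")
  }
  if (is.null(blq)) blq <- rep(FALSE, length(times))
  if (!is.logical(blq) || length(blq) != length(times) || anyNA(blq)) {
    stop_arg("blq must be a logical vector matching times")
  }
  structure(
    list(times = as.numeric(times), conc = as.numeric(conc), blq = blq,
         compound = as.character(compound), subject = as.character(subject)),
    class = "conc_profile"
  )
}

#' @export
print.conc_profile <- function(x, ...) {
  cat("<conc_profile>", x$compound, "subject", x$subject, "-",
      length(x$times), "samples,", sum(x$blq), "BLQ\n")
  print(data.frame(time_h = x$times, conc_ng_per_ml = x$conc, blq = x$blq),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(subject = x$subject, compound = x$compound, time_h = x$times,
             conc_ng_per_ml = x$conc, blq = x$blq)
}

profile_label <- function(profile) {
  paste0(
    if (!is.na(profile$compound)) profile$compound else "compound ?",
    "/",
    if (!is.na(profile$subject)) profile$subject else "subject ?"
  )
}

# Quantifiable (non-BLQ) points of a profile, erroring when fewer than
# `min_n` remain.
quantifiable <- function(profile, min_n = 1L, what = "analysis") {
  keep <- !profile$blq
  if (sum(keep) < min_n) {
    stop_arg(what, " needs at least ", min_n, " quantifiable point(s); ",
             profile_label(profile), " has ", sum(keep))
  }
  list(times = profile$times[keep], conc = profile$conc[keep])
}
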