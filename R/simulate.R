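#' Simulate a plasma concentration-time profile
#'
#' Evaluates the closed-form extravascular prediction of `spec` at `times`
#' and, when `noise_cv > 0`, multiplies each concentration by a lognormal
#' deviate with mean 1 and coefficient of variation `noise_cv`
#' (proportional assay error: plasma LC-MS/MS assays have near-constant
#' relative, not absolute, imprecision). With `noise_cv = 0` the profile is
#' exactly the model prediction.
#'
#' @param spec A [pk_model_spec()].
#' @param times Sampling times (h), strictly increasing and positive.
#' @param noise_cv Proportional noise coefficient of variation, >= 0.
#' @param seed Integer seed; the same (spec, times, noise_cv, seed) always
#'   yields the same profile, and the caller's RNG state is untouched.
#' @param lloq Lower limit of quantification (ng/mL); simulated values
#'   below it are flagged BLQ. Default 0 (no censoring).
#' @param blq_value How a BLQ concentration is stored: `"zero"` (default)
#'   or `"na"`. The flag is carried either way and analysis routines use
#'   only quantifiable points.
#' @param compound,subject Labels carried into the profile.
#' @return A [conc_profile()].
#' @examples
#' spec <- pk_model_spec("one_compartment_ev", ka = 1, coefs = 111.11,
#'                       rates = 0.1)
#' simulate_pk_profile(spec, c(0.5, 1, 2, 4, 8), noise_cv = 0.1, seed = 7)
#' @export
simulate_pk_profile <- function(spec, times, noise_cv = 0, seed = 1L,
                                lloq = 0, blq_value = c("zero", "na"),
                                compound = NA_character_,
                                subject = NA_character_) {
  stopifnot(inherits(spec, "pk_model_spec"))
  check_times(times, "sampling times")
  blq_value <- match.arg(blq_value)
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0) {
    stop_arg("noise_cv must be a single nonnegative number")
  }
  conc <- predict_concentration(spec, times)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- with_seed(seed, rlnorm(length(times), meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog))
    conc <- conc * mult
  }
  blq <- conc < lloq
  conc[blq] <- if (blq_value == "zero") 0 else NA_real_
  out <- conc_profile(times, ifelse(is.na(conc), 0, conc), blq,
                      compound = compound, subject = subject)
  if (blq_value == "na") out$conc[blq] <- NA_real_
  out
}

#' Simulate an effect-time series from a concentration profile
#'
#' Direct-link generative model: the biomarker level at each time is
#' `baseline - emax_effect(C, params) + N(0, noise_sd)`, i.e. the drug
#' *suppresses* the biomarker (here lipid peroxide) by a sigmoid Emax
#' amount of the concurrent concentration. With `lag > 0` the effect is
#' driven by the concentration `lag` hours earlier (linearly interpolated,
#' 0 before dosing), emulating an equilibration delay -- useful for
#' producing hysteresis loops; the default is the lag-free direct link.
#'
#' @param profile A [conc_profile()]; its quantifiable concentrations
#'   drive the effect (BLQ values enter as their stored convention).
#' @param params An [emax_params()] object (ground-truth PD parameters).
#' @param baseline Pre-dose biomarker level (effect units).
#' @param noise_sd Additive Gaussian noise standard deviation, >= 0.
#' @param seed Integer seed (reproducible, RNG-state safe).
#' @param lag Effect delay (h), >= 0, default 0.
#' @return An [effect_series()] of biomarker levels at the profile times.
#' @export
simulate_effect_series <- function(profile, params, baseline,
                                   noise_sd = 0, seed = 1L, lag = 0) {
  stopifnot(inherits(profile, "conc_profile"),
            inherits(params, "emax_params"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_arg("noise_sd must be a single nonnegative number")
  }
  if (!is.numeric(lag) || length(lag) != 1L || lag < 0) {
    stop_arg("lag must be a single nonnegative number")
  }
  conc <- ifelse(is.na(profile$conc), 0, profile$conc)
  if (lag > 0) {
    conc <- stats::approx(x = c(0, profile$times), y = c(0, conc),
                          xout = pmax(profile$times - lag, 0),
                          rule = 2)$y
  }
  values <- baseline - emax_effect(conc, params)
  if (noise_sd > 0) {
    values <- values + with_seed(seed, rnorm(length(values), 0, noise_sd))
  }
  effect_series(profile$times, values)
}
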