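#' Sigmoid Emax (Hill) model parameters
#'
#' Parameter triple for the direct-link sigmoid Emax model
#' \eqn{E = E_{max} C^\gamma / (ED_{50}^\gamma + C^\gamma)}: `emax` is the
#' maximal attainable effect, `ed50` the concentration producing the
#' half-maximal effect (EC50 semantics; the traditional ED50 symbol is kept
#' for continuity with the PK-PD literature), and `gamma` the Hill
#' sigmoidicity exponent.
#'
#' @param emax Maximal effect (effect units), > 0.
#' @param ed50 Half-maximal concentration (ng/mL), > 0.
#' @param gamma Sigmoidicity exponent (unitless), > 0.
#' @return An object of class `emax_params`.
#' @examples
#' emax_params(0.2378, 242.52, 2.62)
#' @export
emax_params <- function(emax, ed50, gamma) {
  vals <- c(emax = emax, ed50 = ed50, gamma = gamma)
  if (!is.numeric(vals) || length(vals) != 3L || any(!is.finite(vals)) ||
      any(vals <= 0)) {
    stop_arg("emax, ed50 and gamma must all be single positive numbers")
  }
  structure(list(emax = emax, ed50 = ed50, gamma = gamma),
            class = "emax_params")
}

#' @export
print.emax_params <- function(x, ...) {
  cat(sprintf("<emax_params> E = %.6g*C^%.6g/(%.6g^%.6g + C^%.6g)\n",
              x$emax, x$gamma, x$ed50, x$gamma, x$gamma))
  invisible(x)
}

#' Evaluate the sigmoid Emax model
#'
#' Computed in log space as
#' \eqn{E_{max} / (1 + e^{\gamma(\log ED_{50} - \log C)})}, which is exact
#' and overflow-free even for very steep curves (gamma > 20 never forms
#' \eqn{C^\gamma} explicitly). `conc = 0` maps to effect 0.
#'
#' @param conc Concentration(s), >= 0 (ng/mL).
#' @param params An [emax_params()] object.
#' @return Effect values in `[0, emax)`.
#' @examples
#' p <- emax_params(0.2378, 242.52, 2.62)
#' emax_effect(242.52, p)  # exactly emax/2
#' @export
emax_effect <- function(conc, params) {
  stopifnot(inherits(params, "emax_params"))
  if (!is.numeric(conc) || anyNA(conc) || any(conc < 0)) {
    stop_arg("conc must be nonnegative")
  }
  out <- numeric(length(conc))
  pos <- conc > 0
  out[pos] <- params$emax /
    (1 + exp(params$gamma * (log(params$ed50) - log(conc[pos]))))
  out
}

#' Fit the sigmoid Emax model to concentration-effect pairs
#'
#' Least-squares fit of \eqn{E = E_{max} C^\gamma/(ED_{50}^\gamma +
#' C^\gamma)} by Levenberg-Marquardt on log-transformed parameters (which
#' enforces positivity without boundary pathologies). Default starting
#' values: `emax` at the largest observed effect, `ed50` at the
#' concentration whose effect is closest to half of that, `gamma = 1`.
#'
#' @param concs Concentrations (ng/mL), >= 0.
#' @param effects Effects, oriented nonnegative (the magnitude convention:
#'   a biomarker *reduction* enters as a positive effect).
#' @param init Optional [emax_params()] starting point.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return A list with elements `params` ([emax_params()]), `ssr`,
#'   `n_obs`, and `converged`.
#' @examples
#' p <- emax_params(0.1387, 58.47, 4.87)
#' cc <- exp(seq(log(5.847), log(584.7), length.out = 50))
#' fit <- fit_sigmoid_emax(cc, emax_effect(cc, p))
#' fit$params
#' @export
fit_sigmoid_emax <- function(concs, effects, init = NULL,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, maxfev = 10000, ftol = 1e-14, ptol = 1e-14)) {
  if (length(concs) != length(effects)) {
    stop_arg("concs and effects must have equal length")
  }
  if (!is.numeric(concs) || anyNA(concs) || any(concs < 0)) {
    stop_arg("concs must be nonnegative")
  }
  if (length(concs) < 4L) {
    stop_arg("need at least 4 concentration-effect pairs to fit 3 ",
             "parameters")
  }
  if (max(abs(effects)) < 1e-12) {
    stop_arg("all effects are ~0: no concentration-effect response to fit")
  }
  if (any(effects < 0)) {
    warning("negative effects supplied; the model fits nonnegative ",
            "magnitudes -- check the sign convention", call. = FALSE)
  }
  if (is.null(init)) {
    emax0 <- max(effects)
    half_idx <- which.min(abs(effects - emax0 / 2))
    ed50_0 <- concs[half_idx]
    if (ed50_0 <= 0) ed50_0 <- median(concs[concs > 0])
    init <- emax_params(emax0, ed50_0, 1)
  } else {
    stopifnot(inherits(init, "emax_params"))
  }
  half <- max(effects) / 2
  if (!any(effects < half) || sum(effects > half) < 2L) {
    warning("effect data do not bracket the half-maximum; the ed50/gamma ",
            "estimates may be poorly identified", call. = FALSE)
  }
  resid_fn <- function(lp) {
    p <- exp(lp)
    pred <- p[1] / (1 + exp(p[3] * (log(p[2]) - log(pmax(concs, 1e-300)))))
    pred[concs == 0] <- 0
    effects - pred
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(init$emax, init$ed50, init$gamma)),
    fn = resid_fn, control = control
  )
  p <- exp(fit$par)
  list(
    params = emax_params(p[1], p[2], p[3]),
    ssr = sum(resid_fn(fit$par)^2),
    n_obs = length(concs),
    converged = fit$info %in% 1:4
  )
}

#' Tabulate an effect-concentration curve
#'
#' Evaluates a fitted (or assumed) sigmoid Emax model over a concentration
#' grid, for plotting or reporting.
#'
#' @param params An [emax_params()] object.
#' @param conc_grid Nonnegative concentration grid (ng/mL).
#' @return A data.frame with columns `conc_ng_per_ml` and `effect`.
#' @export
build_effect_concentration_curve <- function(params, conc_grid) {
  stopifnot(inherits(params, "emax_params"))
  data.frame(conc_ng_per_ml = conc_grid,
             effect = emax_effect(conc_grid, params))
}
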