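#' Reference PK-PD parameter sets for the ten WDD constituents
#'
#' The fitted direct-link sigmoid Emax equations reported for the ten
#' quantified constituents of Wendan Decoction in hyperlipidemic rats
#' (low-dose group), together with the compartmental model kind selected
#' by AIC for each compound. These serve as ground truth for
#' parameter-recovery validation and as generator defaults.
#'
#' Two constituents (trigonelline and tangeretin) carry an identical
#' reported ED50 of 242.52 ng/mL despite very different concentration
#' ranges; the values are used exactly as reported.
#'
#' @return A data.frame with columns `compound`, `model_kind`
#'   (`"one_compartment_ev"`/`"two_compartment_ev"`), `emax`, `ed50`
#'   (ng/mL) and `gamma`.
#' @examples
#' wdd_reference_pkpd()
#' @export
wdd_reference_pkpd <- function() {
  data.frame(
    compound = c("trigonelline", "naringin", "hesperidin", "hesperetin",
                 "quercetin", "naringenin", "glycyrrhizic acid",
                 "isoliquiritigenin", "tangeretin", "glycyrrhetinic acid"),
    model_kind = c("two_compartment_ev", "two_compartment_ev",
                   "one_compartment_ev", "one_compartment_ev",
                   "two_compartment_ev", "one_compartment_ev",
                   "one_compartment_ev", "two_compartment_ev",
                   "two_compartment_ev", "one_compartment_ev"),
    emax  = c(0.2378, 0.1387, 0.1387, 0.1387, 0.1241, 0.1387, 0.1387,
              0.1399, 0.1390, 0.1398),
    ed50  = c(242.52, 13.40, 13.63, 58.47, 10.98, 32.66, 7.46, 3.03,
              242.52, 244.50),
    gamma = c(2.62, 7.41, 8.69, 4.87, 5.72, 7.84, 13.46, 7.10, 13.18,
              2.35),
    stringsAsFactors = FALSE
  )
}

#' Reference calibration lines for the ten WDD constituents
#'
#' The reported plasma calibration lines (peak-area-ratio response Y
#' against nominal concentration X, ng/mL), coefficients of determination
#' and linear ranges for the LC-MS/MS assay of the ten constituents. The
#' lower bound of each linear range is the assay LLOQ.
#'
#' @return A data.frame with columns `compound`, `slope`, `intercept`,
#'   `r_squared`, `range_lower` and `range_upper` (ng/mL).
#' @examples
#' wdd_reference_calibration()
#' @export
wdd_reference_calibration <- function() {
  data.frame(
    compound = c("trigonelline", "naringin", "hesperidin", "hesperetin",
                 "quercetin", "naringenin", "glycyrrhizic acid",
                 "isoliquiritigenin", "tangeretin", "glycyrrhetinic acid"),
    slope = c(0.0030, 0.0026, 0.0018, 0.0070, 0.0014, 0.0128, 0.0448,
              0.0360, 0.1822, 0.0007),
    intercept = c(0.0532, 0.0034, 0.0037, 0.0350, 0.1164, 0.0933,
                  -0.1093, -0.0907, 1.0565, 0.0004),
    r_squared = c(0.9905, 0.9926, 0.9908, 0.9903, 0.9912, 0.9907, 0.9931,
                  0.9904, 0.9910, 0.9908),
    range_lower = c(60, 6, 12, 30, 13, 7, 5, 3, 0.2, 30),
    range_upper = c(6000, 600, 1200, 3000, 1300, 700, 500, 300, 20, 3000),
    stringsAsFactors = FALSE
  )
}

#' Reference noncompartmental summaries for the ten WDD constituents
#'
#' The reported group-mean noncompartmental parameters (half-life, time of
#' peak, peak concentration, exposure) per constituent and dose group.
#' Used to anchor the synthetic-study generator's default kinetics to
#' realistic values.
#'
#' @return A data.frame with columns `compound`, `group`, `t_half_h`,
#'   `tmax_h`, `cmax_ng_per_ml` and `auc_0_t`.
#' @export
wdd_reference_nca <- function() {
  cmp <- c("trigonelline", "naringin", "hesperidin", "hesperetin",
           "quercetin", "naringenin", "glycyrrhizic acid",
           "isoliquiritigenin", "tangeretin", "glycyrrhetinic acid")
  data.frame(
    compound = rep(cmp, each = 2L),
    group = rep(c("LTG", "HTG"), times = 10L),
    t_half_h = c(12.24, 11.75, 6.13, 5.00, 12.11, 4.19, 5.88, 6.24,
                 31.10, 7.75, 12.47, 11.69, 10.80, 15.52, 27.45, 14.61,
                 8.83, 3.21, 2.30, 6.02),
    tmax_h = c(1.50, 2.67, 0.54, 0.25, 0.67, 0.75, 1.42, 0.67, 1.00,
               0.75, 0.75, 0.75, 1.50, 0.25, 0.50, 0.79, 0.50, 0.38,
               0.75, 0.54),
    cmax_ng_per_ml = c(388.39, 536.85, 36.80, 574.53, 34.56, 194.13,
                       222.86, 607.28, 98.36, 114.93, 109.95, 139.03,
                       20.64, 45.13, 16.19, 17.84, 6.80, 25.86,
                       2935.45, 3282.24),
    auc_0_t = c(3555.22, 6013.37, 209.74, 713.43, 171.66, 438.96,
                1028.18, 3892.74, 212.03, 370.18, 587.10, 594.54,
                104.44, 128.19, 48.49, 54.94, 10.81, 22.39,
                8182.79, 10176.26),
    stringsAsFactors = FALSE
  )
}
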