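Package: wddpkpd
Title: Pharmacokinetic-Pharmacodynamic Modelling of Multi-Constituent
    Herbal Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for plasma
    concentration-time and antioxidant effect-time studies of
    multi-constituent herbal extracts such as Wendan Decoction (WDD).
    Provides noncompartmental analysis (Cmax, Tmax, terminal slope,
    half-life, trapezoidal AUC), closed-form one- and two-compartment
    extravascular models with curve-stripping initialisation, nonlinear
    least-squares fitting and AIC-based model selection,
    control-corrected pharmacodynamic effect series, direct-link
    sigmoid Emax (Hill) fitting with hysteresis-loop diagnostics, and
    the bioanalytical validation arithmetic (calibration lines,
    back-calculation, RSD/RE, recovery and matrix-effect ratios).
    A synthetic-study generator reproduces the four-group rat design
    with known ground-truth parameters so the whole pipeline is
    testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
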