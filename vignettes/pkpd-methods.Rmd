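---
title: "Methods: simulation and PK-PD analysis of multi-constituent extract studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and PK-PD analysis of multi-constituent extract studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wddpkpd)
```

## The problem this package addresses

Wendan Decoction (WDD) is a six-herb preparation whose lipid-lowering and
antioxidant activity is studied in hyperlipidemic rats. A typical design
doses rats by gavage, samples plasma at 14 time points over 24 h, and
quantifies ten marker constituents (trigonelline, naringin, hesperidin,
hesperetin, quercetin, naringenin, glycyrrhizic acid, isoliquiritigenin,
tangeretin and glycyrrhetinic acid) by LC-MS/MS, alongside plasma lipid
peroxide (LPO) as the pharmacodynamic biomarker. `wddpkpd` implements the
complete analysis chain for such data — noncompartmental analysis,
compartmental model fitting with AIC selection, control-corrected effect
series, direct-link sigmoid Emax PK-PD fitting and a hysteresis
diagnostic — plus a synthetic-study generator so every stage can be
validated against known ground truth.

## Kinetic models

Concentration curves use the macro-constant (sum-of-exponentials)
extravascular parameterisation, identifiable from concentration data
alone (no bioavailability or volume term is needed):

* one compartment: $C(t) = A\,(e^{-k_e t} - e^{-k_a t})$
* two compartments: $C(t) = A\,e^{-\alpha t} + B\,e^{-\beta t} -
  (A+B)\,e^{-k_a t}$

with all rates positive, $\alpha > \beta$, and $k_a$ distinct from every
elimination rate (the closed form is degenerate at equality, and the
constructor rejects it). `predict_concentration()` evaluates these forms;
`fit_model()` fits them by Levenberg–Marquardt least squares on
log-transformed parameters, which enforces positivity without box
constraints. Starting values come from classical curve stripping
(`initial_estimates()`): a terminal log-linear fit gives the slowest
phase, residual stripping the faster phase(s), and pre-peak residuals the
absorption rate; any stripping step that fails falls back to heuristics
and flags the fit rather than erroring.

Model choice follows the least-squares AIC,
$\mathrm{AIC} = n \ln(\mathrm{SSR}/n) + 2k$ with $k = 3$ (1C) or $k = 5$
(2C). Additive constants are dropped — any monotone variant ranks models
identically at fixed $n$ — and an SSR floor of $10^{-12}$ keeps the value
finite on noiseless self-fits. `select_model()` fits both candidates and
returns the lower-AIC converged fit together with both fits.

## Noncompartmental analysis

`nca_summary()` reports the standard quartet: Cmax/Tmax (earliest-time
tie-break), $\lambda_z$ and $t_{1/2} = \ln 2 / \lambda_z$, and the
trapezoidal AUC. Two deliberately conventional choices, since assay
software manuals differ and the underlying study does not state its
settings:

* $\lambda_z$ windows: every contiguous terminal window of $\ge 3$
  quantifiable points strictly after Tmax is regressed on the log scale;
  the window with the highest adjusted $r^2$ wins, with ties (within
  $10^{-4}$) resolved toward more points. This mirrors the de-facto
  standard "best fit" rule.
* AUC: `linear_up_log_down` by default — linear trapezoid on rising or
  flat segments, logarithmic trapezoid on declines, exact when the curve
  is exponential between samples; plain `linear` is available.

Concentrations are ng/mL and AUC is reported in µg·h/L; the conversion is
the identity (1 ng/mL = 1 µg/L) and is stated rather than computed.

## Pharmacodynamics and the PK-PD link

Treatment effect is the control-corrected biomarker change
$\Delta\mathrm{LPO}(t) = \mathrm{LPO}_{treated}(t) -
\mathrm{LPO}_{control}(t)$ (`compute_delta_effect()`), with per-time means
across subjects. Correction against the treated group's own pre-dose
level is offered as an option (`reference = "baseline"`), since published
trajectories are usually anchored near zero at $t=0$; control subtraction
is the primary definition. LPO units are kit-dependent and treated as
abstract throughout.

The concentration-effect link is the direct sigmoid Emax (Hill) model

$$E = \frac{E_{max}\,C^\gamma}{ED_{50}^\gamma + C^\gamma},$$

where $ED_{50}$ is the concentration at half-maximal effect (EC50
semantics; the traditional symbol is kept) and $\gamma$ the sigmoidicity.
Because treatment *suppresses* LPO, fits use the magnitude convention:
effects enter as nonnegative reductions ($-\Delta\mathrm{LPO}$), and
$E_{max} > 0$. Evaluation is in log space,
$E_{max} / (1 + e^{\gamma(\log ED_{50} - \log C)})$, exact and
overflow-free even for the steepest published curve ($\gamma = 13.46$);
$C^\gamma$ is never formed explicitly. `fit_sigmoid_emax()` uses
Levenberg–Marquardt on log parameters with default starts $E_{max}^0 =
\max E$, $ED_{50}^0$ at the concentration nearest half of that, and
$\gamma^0 = 1$; data that do not bracket the half-maximum trigger a
warning, not an error.

### Hysteresis

The loop traced by (concentration, effect) pairs in time order is
summarised by its shoelace signed area (`hysteresis_loop_area()`);
positive area means counterclockwise traversal, the signature of effect
lagging concentration. The direction is called "none" when the area,
normalised by the bounding box of the data, falls below a tolerance of
0.05. That default is not arbitrary: a lag-free but curved E–C
relationship sampled on the 14-point schedule traces a thin sliver of
about 1% of the box between its ascending and descending chords (a pure
sampling artifact that vanishes on dense grids), while genuine
equilibration delays of 0.5 h or more occupy over 30% of the box. The
pipeline fits the direct-link model regardless of the loop call and
surfaces the statistic as a diagnostic; effect-compartment models are out
of scope.

## The synthetic-study generator

`default_study_config()` encodes the reference design: four groups (NCG,
MCG, LTG, HTG) of six rats, saline for the controls, 2.2 and 6.6 g
extract/100 g body weight for the treatment groups, sampling at 0.25,
0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 10, 12 and 24 h. Ground-truth
kinetics per compound are anchored to the published low-dose
noncompartmental summaries: the slowest rate is $\ln 2 / t_{1/2}$, $k_a$
is solved numerically so the continuous peak sits at the reported Tmax,
and coefficients are scaled to the reported Cmax; two-compartment
compounds use $\alpha/\beta = 15$ and a 4:1 coefficient ratio (chosen
once as clearly biphasic yet realistic). PD ground truth is the published
Emax/ED50/$\gamma$ set; LLOQs are the calibration-range lower bounds.

Noise is proportional lognormal on concentrations (mean-1 multiplier,
default CV 0.10, consistent with reported QC precision of roughly 1–19%
RSD) and additive Gaussian on effects (default SD 0.01 effect units,
about 5–10% of the largest simulated LPO change). Values below the LLOQ
are flagged BLQ and stored as 0 (configurable to NA); analysis routines
use quantifiable points only, which is operationally equivalent to the
common convention of zeroing pre-absorption BLQs and dropping post-peak
ones while keeping one record per scheduled time.

Every stochastic call takes an explicit seed; a study-level seed derives
per-subject, per-compound seeds through a fixed linear-congruential
recurrence, so any subset of the study is reproducible in isolation and
the caller's RNG state is never disturbed.

What the generator does *not* emulate — so what green tests do and do not
show: kinetics scale linearly with dose (real extract kinetics are
visibly nonlinear across dose), there is no between-subject variability
beyond assay noise, the simulated LPO series is driven by a single
configurable compound (default trigonelline) rather than the joint action
of ten, and there is no absorption lag by default. Passing tests
demonstrate that the estimators recover known truth under the stated
noise model, not that the model assumptions hold in any particular rat.

## Numerical choices

* Optimiser: `minpack.lm::nls.lm`, `maxiter = 500`, `maxfev = 10000`,
  `ftol`/`ptol` $10^{-12}$ (PK) or $10^{-14}$ (PK-PD); convergence is the
  optimiser's own criterion and is reported honestly in the `converged`
  flag.
* Near-degenerate $k_a$ during optimisation is nudged by $10^{-8}$
  relative rather than allowed to produce 0/0; the user-facing
  constructor still rejects exact degeneracy.
* Two-compartment phases are re-sorted fastest-first after fitting so the
  labels $\alpha, \beta$ are stable.
* Reports round to 6 significant digits and sort rows, so identical
  inputs give byte-identical CSVs.

## Problem sizes used in validation

The shipped tests run the full default study (4 groups × 6 rats × 10
compounds × 14 times), 20-replicate recovery and model-selection
simulations at 5% noise, and the ten-equation noiseless recovery on 50
log-spaced pairs per compound — sizes chosen to exercise every code path
at desk scale while keeping the whole suite in a few seconds.

## Known limitations

Single-dose extravascular designs only (no IV, steady state, urine or
partial AUCs); two candidate compartment models; direct-link PD only; no
population (mixed-effects) estimation. The published per-compound AIC
values cannot be reproduced without the raw concentration data, which are
not deposited; the package therefore validates the selection *rule* on
synthetic truth instead of those numbers.
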