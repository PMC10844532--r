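# Shared fixtures: the study's 14-point sampling grid and two reference
# ground-truth models used across the suite.
paper_grid <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 10, 12, 24)

spec_1c <- function() {
  pk_model_spec("one_compartment_ev", ka = 1, coefs = 111.11, rates = 0.1)
}

spec_2c <- function() {
  pk_model_spec("two_compartment_ev", ka = 3, coefs = c(80, 20),
                rates = c(1.2, 0.08))
}

noiseless_profile <- function(spec, times = paper_grid, ...) {
  conc_profile(times, predict_concentration(spec, times), ...)
}

# 50 noiseless concentration-effect pairs log-spaced a factor of 10 around
# the half-maximal concentration -- the standard recovery design.
recovery_pairs <- function(params, n = 50L) {
  cc <- exp(seq(log(params$ed50 / 10), log(params$ed50 * 10),
                length.out = n))
  list(concs = cc, effects = emax_effect(cc, params))
}

tiny_config <- function(seed = 1L, ...) {
  compounds <- data.frame(compound = c("cmpA", "cmpB"),
                          lloq = c(0.5, 0.5), stringsAsFactors = FALSE)
  compounds$spec <- list(spec_1c(), spec_2c())
  compounds$pd <- list(emax_params(0.2, 60, 2.5),
                       emax_params(0.14, 20, 5))
  groups <- data.frame(name = c("MCG", "LTG"), n_subjects = 2L,
                       dose = c(0, 2.2), stringsAsFactors = FALSE)
  study_config(groups = groups, compounds = compounds,
               sample_times = paper_grid, seed = seed, ...)
}
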