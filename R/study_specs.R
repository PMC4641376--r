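#' Canonical synthetic evaluation studies
#'
#' The package's fixed evaluation configurations, used by the test suite
#' and the acceptance script.  Each returns a [sim_spec] for a given
#' seed; the parameter choices are documented in the methods vignette
#' and are not meant to be tuned per run.
#'
#' * `spec_null_study()` — pure-noise study (no planted effects, no
#'   pathways) for type-I calibration of the DEG and DEVG tests:
#'   1000 genes, 20 + 20 samples.
#' * `spec_power_study()` — feature-gene power study at the reference
#'   conditions: 2000 genes, 50 + 50 samples, mean shift 2 SD, bimodal
#'   arm separation 3 SD.
#' * `spec_distribution_study()` — gene-distribution comparison of the
#'   joint HT2 ranking against the one-category ORA ranking: 60
#'   pathways of which 15 carry DEG-only signal and 15 mixed signal
#'   (weak mean shift on 10% of members, variance signal on 40%).
#' * `spec_crosstalk_study()` — pathway-map recovery study: 8 disjoint
#'   pathways, 4 with mixed signal, two planted crosstalk pairs wired
#'   through 8 shared dysregulated interactor hubs each.
#' * `spec_subtype_study()` — subtype-factor recovery study: 40 case
#'   samples split into two arms, bimodal DEVGs in two planted
#'   pathways, an `age` index separated by 3 SD between the arms and a
#'   `bmi` index carrying no effect.
#'
#' @param seed RNG seed.
#' @return A [sim_spec].
#' @name study_specs
NULL

#' @rdname study_specs
#' @export
spec_null_study <- function(seed) {
  sim_spec(seed = seed, n_genes = 1000, n_control = 20, n_case = 20,
           deg_fraction = 0, devg_fraction = 0, n_pathways = 0,
           n_deg_pathways = 0, n_mixed_pathways = 0,
           n_crosstalk_pairs = 0)
}

#' @rdname study_specs
#' @export
spec_power_study <- function(seed) {
  sim_spec(seed = seed)
}

#' @rdname study_specs
#' @export
spec_distribution_study <- function(seed) {
  sim_spec(seed = seed, n_genes = 3000, n_pathways = 60,
           n_deg_pathways = 15, n_mixed_pathways = 15,
           frac_deg_only = 0.5, frac_deg_mixed = 0.1,
           frac_devg_mixed = 0.4, pathway_size = c(20, 40),
           n_crosstalk_pairs = 0, deg_fraction = 0.2,
           devg_fraction = 0.13)
}

#' @rdname study_specs
#' @export
spec_crosstalk_study <- function(seed) {
  sim_spec(seed = seed, n_genes = 800, n_pathways = 8,
           n_deg_pathways = 0, n_mixed_pathways = 4,
           frac_deg_mixed = 0.3, frac_devg_mixed = 0.3,
           pathway_size = c(25, 35), n_crosstalk_pairs = 2,
           n_interactors = 8, deg_fraction = 0.08,
           devg_fraction = 0.06)
}

#' @rdname study_specs
#' @export
spec_subtype_study <- function(seed) {
  sim_spec(seed = seed, n_genes = 1000, n_control = 40, n_case = 40,
           n_pathways = 6, n_deg_pathways = 0, n_mixed_pathways = 2,
           frac_deg_mixed = 0.1, frac_devg_mixed = 0.4,
           pathway_size = c(20, 30), n_crosstalk_pairs = 0,
           deg_fraction = 0.05, devg_fraction = 0.05)
}
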