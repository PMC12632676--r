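#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all generators in
#' the synthetic-cohort module. The generator plants a known causal
#' architecture — a cis variant acting on a circulating protein, the protein
#' acting (or not) on a kidney-damage process, an unmeasured confounder of
#' both, and per-person eGFR trajectories — so every downstream stage of the
#' screen can be checked against ground truth.
#'
#' @param n_individuals Number of persons in the cohort (>= 2).
#' @param n_variants_region Number of variants in the simulated cis region.
#' @param maf_range Length-2 numeric, lower/upper bound of variant minor
#'   allele frequencies, both in the open interval (0, 1).
#' @param ld_decay Non-negative correlation-decay parameter for the latent
#'   AR(1) LD model: latent correlation between variants i and j is
#'   `exp(-ld_decay * |i - j|)` (distance in inter-variant spacing units).
#'   `ld_decay = 0` disables LD entirely (independent variants).
#' @param causal_protein_effect Per-allele effect of the causal cis variant on
#'   the protein, in protein-SD units.
#' @param protein_outcome_effect Effect of the protein (per SD) on the
#'   quantitative outcome / latent kidney-damage score.
#' @param shared_causal If `TRUE` the outcome signal in the region flows
#'   through the protein's causal variant (colocalizing architecture); if
#'   `FALSE` the outcome receives a direct effect from a different variant and
#'   none through the protein (distinct-causal architecture).
#' @param confounder_effect Effect of the standard-normal confounder on the
#'   outcome (the confounder always enters the protein with coefficient 1).
#' @param slope_mean,slope_sd Mean and SD of the per-person annualized
#'   relative eGFR slope, in percent per year (`slope_sd >= 0`).
#' @param baseline_egfr_mean,baseline_egfr_sd Mean/SD of baseline eGFR
#'   (mL/min/1.73 m^2).
#' @param damage_egfr_effect Effect of one unit of the latent damage score on
#'   log baseline eGFR (negative = harmful).
#' @param damage_slope_effect Effect of one damage unit on the eGFR slope, in
#'   percent per year (negative = faster decline).
#' @param n_visits Number of creatinine measurements per person.
#' @param followup_years Span of the visit schedule in years.
#' @param scr_cv Coefficient of variation of multiplicative serum-creatinine
#'   measurement noise.
#' @param binary_intercept Intercept of the logistic link generating the
#'   binary outcome (controls prevalence).
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#'
#' @return A list with class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, seed = 1)
#' cfg$maf_range
sim_config <- function(n_individuals = 2000,
                       n_variants_region = 60,
                       maf_range = c(0.05, 0.5),
                       ld_decay = 0.25,
                       causal_protein_effect = 0.4,
                       protein_outcome_effect = 0.3,
                       shared_causal = TRUE,
                       confounder_effect = 0.5,
                       slope_mean = -2,
                       slope_sd = 2,
                       baseline_egfr_mean = 85,
                       baseline_egfr_sd = 18,
                       damage_egfr_effect = -0.12,
                       damage_slope_effect = -1.5,
                       n_visits = 6,
                       followup_years = 8,
                       scr_cv = 0.05,
                       binary_intercept = -2,
                       seed = 1L) {
  assert_that(is.numeric(n_individuals) && n_individuals >= 2,
              "`n_individuals` must be >= 2")
  assert_that(is.numeric(n_variants_region) && n_variants_region >= 1,
              "`n_variants_region` must be a positive count")
  assert_that(length(maf_range) == 2 && all(maf_range > 0) && all(maf_range < 1),
              "`maf_range` frequencies must lie in the open interval (0, 1)")
  assert_that(is.numeric(ld_decay) && ld_decay >= 0, "`ld_decay` must be >= 0")
  assert_that(is.numeric(slope_sd) && slope_sd >= 0, "`slope_sd` must be >= 0")
  assert_that(is.numeric(seed) && length(seed) == 1, "`seed` must be a single integer")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants_region = as.integer(n_variants_region),
    maf_range = as.numeric(maf_range),
    ld_decay = ld_decay,
    causal_protein_effect = causal_protein_effect,
    protein_outcome_effect = protein_outcome_effect,
    shared_causal = isTRUE(shared_causal),
    confounder_effect = confounder_effect,
    slope_mean = slope_mean,
    slope_sd = slope_sd,
    baseline_egfr_mean = baseline_egfr_mean,
    baseline_egfr_sd = baseline_egfr_sd,
    damage_egfr_effect = damage_egfr_effect,
    damage_slope_effect = damage_slope_effect,
    n_visits = as.integer(n_visits),
    followup_years = followup_years,
    scr_cv = scr_cv,
    binary_intercept = binary_intercept,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Predefined simulation scenarios
#'
#' Maps a scenario label to a `sim_config` with the corresponding causal
#' architecture: `"null"` (no protein or outcome effects anywhere),
#' `"causal"` (cis variant -> protein -> outcome, colocalizing),
#' `"coloc-shared"` (same, tuned for strong regional signal on both traits)
#' and `"coloc-distinct"` (protein and outcome driven by different variants).
#'
#' @param scenario One of `"null"`, `"causal"`, `"coloc-shared"`,
#'   `"coloc-distinct"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_config <- function(scenario = c("null", "causal", "coloc-shared",
                                         "coloc-distinct"),
                            seed = 1L, ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    "null" = list(causal_protein_effect = 0.4, protein_outcome_effect = 0,
                  shared_causal = TRUE),
    "causal" = list(causal_protein_effect = 0.6, protein_outcome_effect = 0.8,
                    shared_causal = TRUE),
    "coloc-shared" = list(causal_protein_effect = 0.6,
                          protein_outcome_effect = 0.8, shared_causal = TRUE),
    "coloc-distinct" = list(causal_protein_effect = 0.6,
                            protein_outcome_effect = 0.8, shared_causal = FALSE)
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(sim_config, args)
}
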