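#' Simulate longitudinal eGFR trajectories and serum creatinine
#'
#' Each person receives a true annualized relative slope drawn from
#' `Normal(slope_mean + damage_slope_effect * damage, slope_sd)` (percent per
#' year) and a baseline eGFR shifted on the log scale by
#' `damage_egfr_effect * damage`. The eGFR trajectory is linear on the log
#' scale and inverted through the CKD-EPI equation to serum creatinine, to
#' which multiplicative lognormal measurement noise (CV `scr_cv`) is added.
#' True slopes are returned for recovery testing. Persons with fewer than two
#' visits get their measurements but no true slope; they are flagged in
#' `excluded`.
#'
#' @param config A [sim_config()].
#' @param persons Tibble with `id`, `age`, `sex` and optionally `n_visits`
#'   (defaults to `config$n_visits` for everyone).
#' @param damage Numeric latent kidney-damage score per person (default 0).
#' @param seed Integer seed or `NULL`.
#' @return A list: `labs` (tibble id, day, scr), `truth` (tibble id,
#'   true_slope_pct_year, baseline_egfr), `excluded` (ids with < 2 visits).
#' @export
simulate_longitudinal_egfr <- function(config, persons, damage = 0,
                                       seed = config$seed + 2L) {
  assert_that(config$slope_sd >= 0, "`slope_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(persons)
  damage <- rep_len(damage, n)
  n_visits <- if ("n_visits" %in% names(persons)) persons$n_visits
              else rep(config$n_visits, n)
  baseline <- pmax(15, rnorm(n, config$baseline_egfr_mean,
                             config$baseline_egfr_sd)) *
    exp(config$damage_egfr_effect * damage)
  true_slope <- rnorm(n, config$slope_mean + config$damage_slope_effect * damage,
                      config$slope_sd)
  has_slope <- n_visits >= 2
  true_slope[!has_slope] <- NA_real_

  labs <- purrr::map_dfr(seq_len(n), function(i) {
    k <- n_visits[i]
    days <- if (k == 1) 0L else as.integer(round(
      seq(0, config$followup_years * 365.25, length.out = k)))
    yrs <- days / 365.25
    sl <- if (has_slope[i]) true_slope[i] else 0
    egfr <- pmax(2, baseline[i] * exp(sl / 100 * yrs))
    scr <- invert_ckdepi(egfr, persons$age[i] + yrs, persons$sex[i]) *
      exp(rnorm(k, 0, config$scr_cv))
    tibble::tibble(id = persons$id[i], day = days, scr = scr)
  })
  list(
    labs = labs,
    truth = tibble::tibble(id = persons$id,
                           true_slope_pct_year = true_slope,
                           baseline_egfr = baseline),
    excluded = persons$id[!has_slope]
  )
}

#' Simulate a complete synthetic cohort
#'
#' Assembles genotypes, protein levels, the latent kidney-damage score,
#' demographics (age, sex, ancestry PCs), diabetes status with the code and
#' prescription events backing it, longitudinal creatinine, encounters, and
#' ESKD procedure events (dialysis/transplant, generated from a logistic link
#' on the damage score so both classes are populated at desk-scale n).
#'
#' @param config A [sim_config()].
#' @param n_pcs Number of simulated ancestry principal components.
#' @param variants Optional variant metadata to reuse (replication cohorts).
#' @return A list with elements `persons` (tibble: id, age, sex, diabetes,
#'   PC1..PCk), `dosages`, `variants`, `protein`, `damage`, `confounder`,
#'   `outcome_binary`, `labs`, `procedures`, `encounters`, `diabetes_codes`,
#'   `prescriptions`, `truth`, `causal_index`, `direct_index`, `config`.
#' @export
#' @examples
#' ch <- simulate_cohort(sim_config(n_individuals = 200, seed = 3))
#' names(ch$persons)
simulate_cohort <- function(config, n_pcs = 10, variants = NULL) {
  set.seed(config$seed)
  n <- config$n_individuals
  geno <- simulate_genotypes(config, seed = NULL, variants = variants)
  po <- simulate_protein_and_outcome(geno$dosages, config, seed = NULL)

  persons <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    age = pmin(85, pmax(30, rnorm(n, 62, 12))),
    sex = ifelse(runif(n) < 0.9, "male", "female")
  )
  pcs <- matrix(rnorm(n * n_pcs), n, n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
  persons <- dplyr::bind_cols(persons, tibble::as_tibble(pcs))

  # diabetes driven by the confounder, with backing code/prescription events
  diabetes <- runif(n) < plogis(-1.2 + 0.6 * po$confounder)
  persons$diabetes <- diabetes
  dm_ids <- persons$id[diabetes]
  diabetes_codes <- tibble::tibble(
    id = rep(dm_ids, each = 2),
    day = as.integer(round(runif(2 * length(dm_ids), 0, 1000))),
    code = "E11",
    pcp_visit = rep(c(TRUE, FALSE), length(dm_ids))
  )
  prescriptions <- tibble::tibble(id = dm_ids, drug_class = "diabetes")

  longi <- simulate_longitudinal_egfr(config, persons, damage = po$damage,
                                      seed = NULL)
  procedures <- {
    p_eskd <- plogis(-4 + 0.9 * po$damage)
    hit <- runif(n) < p_eskd
    tibble::tibble(
      id = persons$id[hit],
      day = as.integer(round(runif(sum(hit), 500, config$followup_years * 365))),
      code = sample(c("dialysis", "transplant"), sum(hit), replace = TRUE,
                    prob = c(0.8, 0.2))
    )
  }
  encounters <- dplyr::distinct(longi$labs[, c("id", "day")])

  list(persons = persons, dosages = geno$dosages, variants = geno$variants,
       protein = po$protein, damage = po$damage, confounder = po$confounder,
       outcome_binary = po$outcome_binary, labs = longi$labs,
       procedures = procedures, encounters = encounters,
       diabetes_codes = diabetes_codes, prescriptions = prescriptions,
       truth = longi$truth, causal_index = po$causal_index,
       direct_index = po$direct_index, config = config)
}

#' Write a cohort to delimited text tables
#'
#' Serializes the cohort's tables (persons, dosages in long format, labs,
#' procedures, variant metadata) as tab-delimited files under `dir`. A fixed
#' seed therefore yields byte-identical files.
#'
#' @param cohort From [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    as.data.frame(x), file.path(dir, f), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wt(cohort$persons, "persons.tsv")
  wt(cohort$variants, "variants.tsv")
  dl <- as.data.frame(cohort$dosages)
  names(dl) <- cohort$variants$variant_id
  dl <- tibble::as_tibble(dl)
  dl$id <- cohort$persons$id
  wt(tidyr::pivot_longer(dl, -"id", names_to = "variant_id",
                         values_to = "dosage"), "dosages.tsv")
  wt(cohort$labs, "labs.tsv")
  wt(cohort$procedures, "procedures.tsv")
  invisible(dir)
}

#' Synthetic phecode catalog
#'
#' Builds a phecode catalog across 11 standard clinical domains plus a
#' curated kidney domain (the 12th). Every phecode belongs to exactly one
#' domain.
#'
#' @param n_phecodes Catalog size (default 1020).
#' @param kidney_fraction Fraction of phecodes in the kidney domain.
#' @param seed Integer seed.
#' @return Tibble: phecode, label, domain.
#' @export
make_phecode_catalog <- function(n_phecodes = 1020, kidney_fraction = 0.04,
                                 seed = 11L) {
  set.seed(seed)
  domains11 <- c("infectious", "neoplasms", "endocrine/metabolic",
                 "hematopoietic", "mental", "neurological", "circulatory",
                 "respiratory", "digestive", "dermatologic", "musculoskeletal")
  n_kid <- max(1L, round(n_phecodes * kidney_fraction))
  dom <- c(rep("kidney", n_kid),
           sample(domains11, n_phecodes - n_kid, replace = TRUE))
  tibble::tibble(
    phecode = sprintf("%06.2f", seq(100, by = 0.71, length.out = n_phecodes)),
    label = paste0("phenotype_", seq_len(n_phecodes)),
    domain = dom
  )
}

#' Simulate phecode events for a cohort
#'
#' Each phecode gets a baseline prevalence; kidney-domain phecodes receive an
#' additional logistic effect of the latent damage score, and (optionally)
#' phecodes in `pleiotropy_domains` receive a direct effect of the protein,
#' letting tests plant kidney-specific or pleiotropic architectures.
#' Affected persons contribute two code events (the case rule), and a small
#' fraction of unaffected persons contribute a single stray code (exercising
#' the single-code exclusion).
#'
#' @param cohort From [simulate_cohort()].
#' @param catalog From [make_phecode_catalog()].
#' @param kidney_effect Logistic effect of one damage unit on kidney-domain
#'   phecode liability.
#' @param protein_effect Logistic effect of one protein SD on phecodes in
#'   `pleiotropy_domains`.
#' @param pleiotropy_domains Character vector of extra affected domains.
#' @param base_logit Baseline log-odds of being affected by any phecode.
#' @param stray_rate Probability of a single stray code in unaffected persons.
#' @param seed Integer seed or `NULL`.
#' @return Tibble: id, day, phecode.
#' @export
simulate_phecode_events <- function(cohort, catalog, kidney_effect = 0.8,
                                    protein_effect = 0,
                                    pleiotropy_domains = character(),
                                    base_logit = -2.5, stray_rate = 0.02,
                                    seed = cohort$config$seed + 5L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort$persons)
  purrr::map_dfr(seq_len(nrow(catalog)), function(j) {
    eta <- base_logit
    if (catalog$domain[j] == "kidney") eta <- eta + kidney_effect * cohort$damage
    if (catalog$domain[j] %in% pleiotropy_domains)
      eta <- eta + protein_effect * cohort$protein
    affected <- runif(n) < plogis(eta)
    stray <- !affected & runif(n) < stray_rate
    ids <- c(rep(cohort$persons$id[affected], each = 2),
             cohort$persons$id[stray])
    if (length(ids) == 0) return(NULL)
    tibble::tibble(
      id = ids,
      day = as.integer(round(runif(length(ids), 0, 2000))),
      phecode = catalog$phecode[j]
    )
  })
}

#' Synthetic drug-target and protein-interaction fixture tables
#'
#' Shapes mirror ChEMBL / STRING extracts: a drug-target table
#' (drug, target) and an undirected PPI edge table (protein_a, protein_b,
#' score in \[0, 1\]).
#'
#' @param proteins Character vector of protein (gene) symbols.
#' @param n_drugs Number of distinct drugs to draw.
#' @param direct_fraction Fraction of proteins given a direct drug.
#' @param seed Integer seed.
#' @return A list: `drug_targets`, `ppi`.
#' @export
make_druggability_fixtures <- function(proteins, n_drugs = 20,
                                       direct_fraction = 0.3, seed = 13L) {
  set.seed(seed)
  partners <- paste0("INT", seq_len(2 * length(proteins)))
  ppi <- tibble::tibble(
    protein_a = rep(proteins, each = 2),
    protein_b = sample(partners, 2 * length(proteins), replace = TRUE),
    score = round(runif(2 * length(proteins), 0.4, 0.99), 3)
  )
  ppi <- ppi[ppi$protein_a != ppi$protein_b, , drop = FALSE]
  n_direct <- max(0L, round(direct_fraction * length(proteins)))
  direct_targets <- sample(proteins, n_direct)
  partner_targets <- sample(partners, max(1, n_drugs - n_direct), replace = TRUE)
  drug_targets <- tibble::tibble(
    drug = paste0("DRUG", seq_len(n_direct + length(partner_targets))),
    target = c(direct_targets, partner_targets)
  )
  list(drug_targets = drug_targets, ppi = ppi)
}
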