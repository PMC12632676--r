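#' Phecode case/control assignment
#'
#' Persons with two or more events mapped to the phecode are cases; persons
#' with none are controls; persons with exactly one are excluded.
#'
#' @param events Tibble `id`, `day`, `phecode` of phecode-mapped code events.
#' @param ids All person ids in the cohort.
#' @param phecode The phecode to define.
#' @return Tibble `id`, `status` in `{"case", "control", "excluded"}`.
#' @export
define_case_control <- function(events, ids, phecode) {
  counts <- table(events$id[events$phecode == phecode])
  n_codes <- as.integer(counts[ids])
  n_codes[is.na(n_codes)] <- 0L
  tibble::tibble(
    id = ids,
    status = dplyr::case_when(n_codes >= 2 ~ "case",
                              n_codes == 0 ~ "control",
                              TRUE ~ "excluded")
  )
}

#' Phenome-wide association scan of one variant
#'
#' For every phecode in the catalog: assign case/control status, exclude
#' phecodes with fewer than `min_count` cases or controls (recorded with
#' reason), and fit an additive logistic regression of status on the variant
#' dosage adjusted for age, sex and the first `n_pcs` ancestry principal
#' components. Significance uses the Bonferroni cutoff
#' `alpha / nrow(catalog)` (the loaded-catalog size).
#'
#' @param dosage Numeric dosage vector for the variant (one value per person
#'   in `persons`, same order).
#' @param catalog Phecode catalog ([make_phecode_catalog()]).
#' @param events Phecode event table (`id`, `day`, `phecode`).
#' @param persons Tibble with `id`, `age`, `sex`, `PC1..`.
#' @param min_count Minimum cases and controls (default 200).
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_pcs Number of PCs to adjust for (default 5).
#' @param variant_id Label for the scanned variant.
#' @return A tibble, one row per phecode: `phecode`, `domain`, `n_case`,
#'   `n_control`, `eligible`, `reason`, `beta`, `se`, `pvalue`,
#'   `significant`; the cutoff is in attribute `"cutoff"`.
#' @export
run_phewas <- function(dosage, catalog, events, persons, min_count = 200,
                       alpha = 0.05, n_pcs = 5, variant_id = "variant") {
  cutoff <- bonferroni_threshold(alpha, nrow(catalog))
  pc_cols <- paste0("PC", seq_len(n_pcs))
  pc_cols <- pc_cols[pc_cols %in% names(persons)]
  covs <- data.frame(age = persons$age,
                     sex = as.integer(persons$sex == "female"))
  if (length(pc_cols)) covs <- cbind(covs, persons[, pc_cols, drop = FALSE])

  rows <- purrr::map_dfr(seq_len(nrow(catalog)), function(j) {
    st <- define_case_control(events, persons$id, catalog$phecode[j])
    n_case <- sum(st$status == "case")
    n_control <- sum(st$status == "control")
    base <- tibble::tibble(
      phecode = catalog$phecode[j], domain = catalog$domain[j],
      n_case = n_case, n_control = n_control
    )
    if (n_case < min_count || n_control < min_count) {
      return(dplyr::mutate(base, eligible = FALSE, reason = "min_count",
                           beta = NA_real_, se = NA_real_, pvalue = NA_real_))
    }
    keep <- st$status != "excluded"
    ss <- scan_binary(as.integer(st$status[keep] == "case"),
                      matrix(dosage[keep], ncol = 1), covs[keep, , drop = FALSE],
                      trait_name = catalog$phecode[j])
    dplyr::mutate(base, eligible = TRUE, reason = NA_character_,
                  beta = ss$beta[1], se = ss$se[1], pvalue = ss$pvalue[1])
  })
  rows$significant <- rows$eligible & !is.na(rows$pvalue) & rows$pvalue < cutoff
  rows$variant_id <- variant_id
  attr(rows, "cutoff") <- cutoff
  rows
}

#' Classify a protein's phenome-wide pleiotropy tier
#'
#' The protein-level profile is the union of significant PheWAS hits over its
#' conditionally independent cis instrument variants. Tiers: `kidney_only`
#' (hits confined to the kidney domain), `kidney_plus_k` (kidney plus k
#' extra-renal domains), `extra_renal_only`, and `no_hits` — the last kept
#' distinct from kidney specificity, since absent hits may simply reflect
#' small variant effects.
#'
#' @param phewas_rows PheWAS rows (possibly several variants' worth) for one
#'   protein, as from [run_phewas()].
#' @param protein_id Label.
#' @return A tibble: `protein_id`, `tier`, `n_domains_extra`, `n_hits`,
#'   `domains` (comma-joined).
#' @export
classify_pleiotropy <- function(phewas_rows, protein_id = "protein") {
  hits <- phewas_rows[isTRUE_vec(phewas_rows$significant), , drop = FALSE]
  hit_domains <- unique(hits$domain)
  extra <- setdiff(hit_domains, "kidney")
  tier <- if (nrow(hits) == 0) {
    "no_hits"
  } else if ("kidney" %in% hit_domains && length(extra) == 0) {
    "kidney_only"
  } else if ("kidney" %in% hit_domains) {
    paste0("kidney_plus_", length(extra))
  } else {
    "extra_renal_only"
  }
  tibble::tibble(
    protein_id = protein_id, tier = tier,
    n_domains_extra = length(extra),
    n_hits = dplyr::n_distinct(hits$phecode),
    domains = paste(sort(hit_domains), collapse = ",")
  )
}

#' Pyramid summary of pleiotropy tiers
#'
#' Counts proteins per tier, ordered from the kidney-specific apex outward.
#'
#' @param profiles Row-bound output of [classify_pleiotropy()].
#' @return Tibble `tier`, `n_proteins`.
#' @export
pleiotropy_pyramid <- function(profiles) {
  dplyr::count(profiles, .data$tier, name = "n_proteins") |>
    dplyr::arrange(.data$tier)
}
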