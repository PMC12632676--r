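#' Pipeline run configuration
#'
#' Bundles the simulation scenario and every analytic threshold of the
#' screen. All thresholds default to the screen's operating values: 500 kb
#' cis window, MAF > 1%, proxy r^2 >= 0.9 with MAF tolerance 0.02, ACAT
#' Bonferroni at alpha 0.05, per-endpoint direction threshold 0.0125
#' (0.05/4), PP4 > 0.8, interaction score >= 0.9, and 5 PheWAS PCs.
#'
#' @param scenario Simulation scenario (see [scenario_config()]).
#' @param seed Integer seed for the whole run.
#' @param n_individuals Cohort size per cohort.
#' @param n_proteins Number of protein regions screened (protein 1 carries
#'   the scenario's causal architecture; the rest are null).
#' @param n_variants_region Variants per cis region.
#' @param window_bp,maf_min,r2_min,maf_tol,r2_clump,p_instrument Instrument
#'   selection/harmonization thresholds.
#' @param alpha,endpoint_alpha,pp4_min,score_min Gate thresholds.
#' @param phewas_pc_count PCs adjusted for in PheWAS (default 5).
#' @param n_phecodes Size of the synthetic phecode catalog used by the
#'   PheWAS stage.
#' @param phewas_min_count Minimum cases and controls per phecode.
#' @param out_dir Optional output directory for tables and the manifest.
#' @param ... Extra overrides forwarded to [scenario_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = "causal", seed = 1L, n_individuals = 3000,
                       n_proteins = 3, n_variants_region = 40,
                       window_bp = 5e5, maf_min = 0.01, r2_min = 0.9,
                       maf_tol = 0.02, r2_clump = 0.1, p_instrument = 5e-8,
                       alpha = 0.05, endpoint_alpha = 0.0125, pp4_min = 0.8,
                       score_min = 0.9, phewas_pc_count = 5, n_phecodes = 24,
                       phewas_min_count = 200, out_dir = NULL, ...) {
  structure(list(
    scenario = scenario, seed = as.integer(seed),
    n_individuals = n_individuals, n_proteins = n_proteins,
    n_variants_region = n_variants_region, window_bp = window_bp,
    maf_min = maf_min, r2_min = r2_min, maf_tol = maf_tol,
    r2_clump = r2_clump, p_instrument = p_instrument, alpha = alpha,
    endpoint_alpha = endpoint_alpha, pp4_min = pp4_min,
    score_min = score_min, phewas_pc_count = phewas_pc_count,
    n_phecodes = n_phecodes, phewas_min_count = phewas_min_count,
    out_dir = out_dir, sim_overrides = list(...)
  ), class = "run_config")
}

zscale <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)

endpoint_binary_status <- function(status) {
  ifelse(status == "case", 1L, ifelse(status == "control", 0L, NA_integer_))
}

# four covariate-adjusted endpoint scans over one region's dosages;
# quantitative endpoints are standardized so downstream effect-size priors
# (colocalization) are on the trait-SD scale
endpoint_scans <- function(endpoints, dosages, variants, covs) {
  scans <- list(
    egfr = scan_quantitative(zscale(endpoints$baseline_egfr), dosages, covs,
                             variants, trait_name = "egfr"),
    slope = scan_quantitative(zscale(endpoints$egfr_slope), dosages, covs,
                              variants, trait_name = "slope")
  )
  for (ep in c("ckd", "eskd")) {
    y <- endpoint_binary_status(endpoints[[paste0(ep, "_status")]])
    keep <- !is.na(y)
    scans[[ep]] <- if (sum(y[keep] == 1) >= 10 && sum(y[keep] == 0) >= 10) {
      scan_binary(y[keep], dosages[keep, , drop = FALSE],
                  covs[keep, , drop = FALSE], variants, trait_name = ep)
    } else NULL
  }
  scans
}

# MR of one protein against the four endpoint scans
mr_against_endpoints <- function(exposure, scans, ld, cfg, protein_id) {
  cand <- select_cis_pqtls(exposure,
                           list(gene = protein_id,
                                chrom = exposure$chrom[1],
                                tss = round(mean(exposure$pos))),
                           maf_min = cfg$maf_min, window_bp = cfg$window_bp)
  instr_exp <- clump_instruments(cand, ld, r2_max = cfg$r2_clump,
                                 p_max = cfg$p_instrument)
  if (nrow(instr_exp) == 0) return(NULL)
  rows <- purrr::map_dfr(names(scans), function(ep) {
    if (is.null(scans[[ep]])) {
      return(tibble::tibble(protein_id = protein_id, endpoint = ep,
                            beta = NA_real_, se = NA_real_, pvalue = NA_real_,
                            n_snp = 0L, Q_pvalue = NA_real_,
                            egger_intercept_p = NA_real_))
    }
    hm <- harmonize(instr_exp, scans[[ep]], r2_min = cfg$r2_min,
                    maf_tol = cfg$maf_tol)
    keep <- !is.na(hm$beta_out) & !is.na(hm$se_out)
    hm <- hm[keep, , drop = FALSE]
    if (nrow(hm) == 0) {
      return(tibble::tibble(protein_id = protein_id, endpoint = ep,
                            beta = NA_real_, se = NA_real_, pvalue = NA_real_,
                            n_snp = 0L, Q_pvalue = NA_real_,
                            egger_intercept_p = NA_real_))
    }
    res <- run_mr(hm, protein_id = protein_id, outcome_name = ep)
    tibble::tibble(protein_id = protein_id, endpoint = ep, beta = res$beta,
                   se = res$se, pvalue = res$pvalue, n_snp = res$n_snp,
                   Q_pvalue = res$Q_pvalue,
                   egger_intercept_p = res$egger_intercept_p)
  })
  list(mr = rows, instruments = instr_exp)
}

# replication-cohort endpoint analogs: cross-sectional eGFR, CKD, CKDi25
# (>= 25% eGFR decline with follow-up eGFR < 60), Rapid3 (absolute decline
# >= 3 mL/min/1.73m^2 per year)
replication_endpoints <- function(cohort) {
  persons <- cohort$persons
  labs <- dplyr::inner_join(tibble::as_tibble(cohort$labs),
                            persons[, c("id", "age", "sex")], by = "id")
  labs$egfr <- ckdepi_egfr(labs$scr, labs$age + labs$day / 365.25, labs$sex)
  labs <- dplyr::arrange(labs, .data$id, .data$day)
  per <- labs |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      first_egfr = .data$egfr[1], last_egfr = .data$egfr[dplyr::n()],
      years = (max(.data$day) - min(.data$day)) / 365.25,
      abs_slope = unname(coef(lm(egfr ~ I(day / 365.25)))[2]),
      .groups = "drop"
    )
  series_by_id <- split(labs[, c("day", "egfr")], labs$id)
  ckd <- vapply(persons$id, function(pid) call_ckd(series_by_id[[pid]]),
                character(1))
  tibble::tibble(
    id = per$id,
    egfr = per$first_egfr,
    ckd = endpoint_binary_status(ckd[per$id]),
    ckdi25 = as.integer(per$last_egfr <= 0.75 * per$first_egfr &
                          per$last_egfr < 60),
    rapid3 = as.integer(per$abs_slope <= -3)
  )
}

#' Run the proteome-to-phenome screen end to end
#'
#' Executes the stages in order: simulate the discovery cohort (protein 1
#' carries the scenario's architecture, remaining proteins are null) ->
#' derive the four kidney endpoints -> covariate-adjusted endpoint and
#' protein GWAS per region -> cis-instrument selection and harmonization ->
#' two-sample MR per endpoint -> ACAT aggregation, Bonferroni significance
#' and direction gates -> colocalization of each protein's region with the
#' eGFR signal -> replication in an independently simulated cohort ->
#' PheWAS-based pleiotropy profiling of significant proteins -> druggability
#' and evidence-network assembly. Every stage is a pure function of
#' (config, seed); rerunning the same config yields identical tables.
#'
#' @param config A [run_config()].
#' @return A list: `verdicts`, `mr_table`, `coloc`, `replication`,
#'   `het_diabetes`, `phewas`, `pleiotropy`, `druggability`, `network`,
#'   `report` (gate accounting), `manifest`, plus the discovery `cohort`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }
  cfg <- config
  sim_cfg <- do.call(scenario_config, c(
    list(scenario = cfg$scenario, seed = cfg$seed,
         n_individuals = cfg$n_individuals,
         n_variants_region = cfg$n_variants_region),
    cfg$sim_overrides))

  cohort <- stage("simulate", simulate_cohort(sim_cfg))
  protein_ids <- paste0("PROT", seq_len(cfg$n_proteins))

  # null protein regions on other chromosomes
  regions <- list(list(dosages = cohort$dosages, variants = cohort$variants,
                       protein = cohort$protein))
  if (cfg$n_proteins > 1) {
    for (k in 2:cfg$n_proteins) {
      null_cfg <- sim_cfg
      null_cfg$protein_outcome_effect <- 0
      g <- simulate_genotypes(null_cfg, seed = cfg$seed + 1000L + k,
                              chrom = as.character(k))
      po <- simulate_protein_and_outcome(g$dosages, null_cfg,
                                         seed = cfg$seed + 2000L + k)
      regions[[k]] <- list(dosages = g$dosages, variants = g$variants,
                           protein = po$protein)
    }
  }

  endpoints <- stage("phenotype", derive_endpoints(cohort))
  endpoints <- endpoints[match(cohort$persons$id, endpoints$id), ]
  pc_cols <- grep("^PC", names(cohort$persons), value = TRUE)
  covs <- data.frame(age = cohort$persons$age,
                     sex = as.integer(cohort$persons$sex == "female"),
                     cohort$persons[, pc_cols])

  mr_rows <- list(); instruments <- list(); scans_by_protein <- list()
  for (k in seq_len(cfg$n_proteins)) {
    rg <- regions[[k]]
    scans <- stage("scan", endpoint_scans(endpoints, rg$dosages,
                                          rg$variants, covs))
    expo <- stage("scan", scan_quantitative(rg$protein, rg$dosages, covs,
                                            rg$variants,
                                            trait_name = protein_ids[k]))
    out <- stage("mr", mr_against_endpoints(expo, scans, rg$dosages, cfg,
                                            protein_ids[k]))
    scans_by_protein[[k]] <- list(scans = scans, exposure = expo)
    if (!is.null(out)) {
      mr_rows[[k]] <- out$mr
      instruments[[protein_ids[k]]] <- out$instruments
    }
  }
  mr_table <- dplyr::bind_rows(mr_rows)
  assert_that(nrow(mr_table) > 0, "no protein yielded instruments")

  # colocalization: protein region vs the eGFR endpoint signal
  coloc_tab <- purrr::map_dfr(seq_len(cfg$n_proteins), function(k) {
    sp <- scans_by_protein[[k]]
    if (is.null(sp$scans$egfr)) return(NULL)
    reg_exp <- extract_region(sp$exposure, window_bp = cfg$window_bp)
    reg_out <- sp$scans$egfr[sp$scans$egfr$variant_id %in%
                               reg_exp$variant_id, ]
    cr <- colocalize(reg_exp, reg_out, pp4_min = cfg$pp4_min)
    tibble::tibble(protein_id = protein_ids[k], n_snps = cr$n_snps,
                   pp3 = cr$pp3, pp4 = cr$pp4, passed = cr$passed)
  })

  # replication: independent cohort at the same variants and architecture
  rep_cfg <- sim_cfg
  rep_cfg$seed <- sim_cfg$seed + 5000L
  rep_cohort <- stage("replication",
                      simulate_cohort(rep_cfg, variants = cohort$variants))
  rep_ep <- replication_endpoints(rep_cohort)
  rep_pc <- grep("^PC", names(rep_cohort$persons), value = TRUE)
  rep_covs <- data.frame(age = rep_cohort$persons$age,
                         sex = as.integer(rep_cohort$persons$sex == "female"),
                         rep_cohort$persons[, rep_pc])
  rep_scans <- list(
    egfr = scan_quantitative(zscale(rep_ep$egfr), rep_cohort$dosages, rep_covs,
                             rep_cohort$variants, trait_name = "rep_egfr"))
  for (ep in c("ckd", "ckdi25", "rapid3")) {
    y <- rep_ep[[ep]]
    keep <- !is.na(y)
    rep_scans[[ep]] <- if (sum(y[keep] == 1, na.rm = TRUE) >= 10 &&
                           sum(y[keep] == 0, na.rm = TRUE) >= 10) {
      scan_binary(y[keep], rep_cohort$dosages[keep, , drop = FALSE],
                  rep_covs[keep, , drop = FALSE], rep_cohort$variants,
                  trait_name = paste0("rep_", ep))
    } else NULL
  }
  # replication is attempted for protein 1 (the one sharing the replication
  # cohort's region); null proteins have no instruments there by design
  replication <- {
    instr <- instruments[[protein_ids[1]]]
    if (is.null(instr) || nrow(instr) == 0) {
      tibble::tibble(protein_id = protein_ids[1],
                     replication_acat_p = NA_real_, replicated = NA)
    } else {
      pvals <- purrr::map_dbl(rep_scans, function(sc) {
        if (is.null(sc)) return(NA_real_)
        hm <- harmonize(instr, sc, r2_min = cfg$r2_min, maf_tol = cfg$maf_tol)
        hm <- hm[!is.na(hm$beta_out), , drop = FALSE]
        if (nrow(hm) == 0) return(NA_real_)
        run_mr(hm)$pvalue
      })
      rp <- replicate_protein(pvals[!is.na(pvals)],
                              n_proteins_attempted = cfg$n_proteins,
                              alpha = cfg$alpha)
      tibble::tibble(protein_id = protein_ids[1],
                     replication_acat_p = rp$replication_acat_p,
                     replicated = rp$replicated)
    }
  }

  verdicts <- stage("aggregate", protein_verdicts(
    mr_table, n_proteins_tested = cfg$n_proteins, coloc_results = coloc_tab,
    replication = replication, alpha = cfg$alpha,
    endpoint_alpha = cfg$endpoint_alpha, pp4_min = cfg$pp4_min,
    dataset_label = cfg$scenario))

  # diabetes effect modification on baseline eGFR for significant proteins
  het_diabetes <- purrr::map_dfr(
    which(protein_ids %in% verdicts$protein_id[verdicts$significant]),
    function(k) {
      rg <- regions[[k]]
      instr <- instruments[[protein_ids[k]]]
      if (is.null(instr)) return(NULL)
      strat <- tryCatch(
        stratified_scan(endpoints$baseline_egfr, rg$dosages, covs,
                        stratum = cohort$persons$diabetes,
                        type = "quantitative", variants = rg$variants),
        error = function(e) NULL)
      if (is.null(strat)) return(NULL)
      fits <- lapply(strat, function(sc) {
        hm <- harmonize(instr, sc)
        run_mr(hm[!is.na(hm$beta_out), ], protein_id = protein_ids[k])
      })
      hz <- heterogeneity_z(fits[[1]], fits[[2]])
      tibble::tibble(protein_id = protein_ids[k], z = hz$z,
                     pvalue = hz$pvalue)
    })

  # PheWAS + pleiotropy for significant proteins (top instrument per protein)
  catalog <- make_phecode_catalog(cfg$n_phecodes, seed = cfg$seed + 7L)
  phe_events <- simulate_phecode_events(cohort, catalog, seed = NULL)
  sig_idx <- which(protein_ids %in% verdicts$protein_id[verdicts$significant])
  phewas_tab <- NULL; pleiotropy <- NULL
  if (length(sig_idx) > 0) {
    res <- purrr::map(sig_idx, function(k) {
      instr <- instruments[[protein_ids[k]]]
      rows <- purrr::map_dfr(instr$variant_id, function(v) {
        j <- match(v, regions[[k]]$variants$variant_id)
        run_phewas(regions[[k]]$dosages[, j], catalog, phe_events,
                   cohort$persons, min_count = cfg$phewas_min_count,
                   alpha = cfg$alpha, n_pcs = cfg$phewas_pc_count,
                   variant_id = v)
      })
      rows$protein_id <- protein_ids[k]
      rows
    })
    phewas_tab <- dplyr::bind_rows(res)
    pleiotropy <- purrr::map_dfr(split(phewas_tab, phewas_tab$protein_id),
                                 function(df) classify_pleiotropy(df, df$protein_id[1]))
  }

  # druggability + evidence network for significant proteins
  sig_proteins <- verdicts$protein_id[verdicts$significant]
  drugfix <- make_druggability_fixtures(protein_ids, seed = cfg$seed + 9L)
  druggability <- tibble::tibble(
    protein_id = protein_ids,
    druggability = vapply(protein_ids, classify_druggability,
                          character(1), drug_targets = drugfix$drug_targets,
                          ppi = drugfix$ppi, score_min = cfg$score_min))
  network <- NULL
  if (length(sig_proteins) > 0) {
    mr_betas <- stats::setNames(
      mr_table$beta[mr_table$endpoint == "egfr"][
        match(sig_proteins, mr_table$protein_id[mr_table$endpoint == "egfr"])],
      sig_proteins)
    hits <- if (!is.null(phewas_tab)) {
      ph <- phewas_tab[isTRUE_vec(phewas_tab$significant), ]
      ph[, c("protein_id", "phecode", "beta")]
    } else NULL
    network <- build_network(verdicts[verdicts$significant, ], mr_betas,
                             hits, drugfix$drug_targets, drugfix$ppi,
                             score_min = cfg$score_min)
  }

  report <- tibble::tibble(
    gate = c("proteins_screened", "significant", "consistent_direction",
             "colocalized", "replicated", "passes_all"),
    n = c(cfg$n_proteins, sum(verdicts$significant),
          sum(verdicts$significant &
                verdicts$direction %in% c("protective", "detrimental")),
          sum(verdicts$significant & isTRUE_vec(verdicts$pp4 > cfg$pp4_min)),
          sum(verdicts$significant & isTRUE_vec(verdicts$replicated)),
          sum(verdicts$passes_all))
  )
  manifest <- list(seed = cfg$seed, scenario = cfg$scenario,
                   config_hash = rlang::hash(unclass(cfg)),
                   package_version = as.character(utils::packageVersion("nephromr")))

  out <- list(verdicts = verdicts, mr_table = mr_table, coloc = coloc_tab,
              replication = replication, het_diabetes = het_diabetes,
              phewas = phewas_tab, pleiotropy = pleiotropy,
              druggability = druggability, network = network,
              report = report, manifest = manifest, cohort = cohort)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) if (!is.null(x)) utils::write.table(
    as.data.frame(x), file.path(dir, f), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wt(result$verdicts, "verdicts.tsv")
  wt(result$mr_table, "mr_results.tsv")
  wt(result$coloc, "coloc.tsv")
  wt(result$replication, "replication.tsv")
  wt(result$phewas, "phewas.tsv")
  wt(result$pleiotropy, "pleiotropy.tsv")
  wt(result$druggability, "druggability.tsv")
  wt(result$report, "report.tsv")
  writeLines(paste(names(result$manifest),
                   vapply(result$manifest, as.character, character(1)),
                   sep = "="),
             file.path(dir, "manifest.txt"))
  if (!is.null(result$network)) write_network(result$network,
                                              file.path(dir, "network"))
  invisible(dir)
}
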