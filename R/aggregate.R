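#' Aggregated Cauchy association test (ACAT)
#'
#' Combines possibly dependent p-values through the Cauchy transform:
#' `T = sum(w_i * tan((0.5 - p_i) * pi))`, combined
#' `p = 0.5 - atan(T) / pi`. Inputs are clipped to
#' `[1e-15, 1 - 1e-15]` before transforming to keep the tangent finite.
#' Weights are normalized to sum to one; equal weights by default. ACAT is
#' valid under arbitrary dependence among the component tests, which is why
#' it is used to combine the four correlated kidney endpoints.
#'
#' @param pvalues Numeric vector of p-values in (0, 1).
#' @param weights Non-negative weights (default equal).
#' @return The combined p-value.
#' @export
#' @examples
#' acat(c(0.05, 0.05, 0.05, 0.05))  # 0.05
#' acat(c(0.5, 0.5))                # 0.5
acat <- function(pvalues, weights = NULL) {
  assert_that(length(pvalues) >= 1, "empty p-value list")
  assert_that(all(pvalues > 0 & pvalues < 1 | is.na(pvalues)) &&
                !anyNA(pvalues),
              "p-values must lie in (0, 1) and be non-missing")
  w <- weights %||% rep(1, length(pvalues))
  assert_that(all(w >= 0) && sum(w) > 0, "weights must be >= 0, not all zero")
  w <- w / sum(w)
  p <- pmin(pmax(pvalues, 1e-15), 1 - 1e-15)
  t_stat <- sum(w * tan((0.5 - p) * pi))
  0.5 - atan(t_stat) / pi
}

#' Bonferroni per-test cutoff
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 9)     # 5.6e-3 at 2 significant figures
#' bonferroni_threshold(0.05, 1020)  # 4.9e-5
#' bonferroni_threshold(0.05, 4)     # 0.0125
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  assert_that(is.numeric(n_tests) && n_tests >= 1, "`n_tests` must be >= 1")
  alpha / n_tests
}

# orientation of each endpoint's beta onto the common kidney-benefit axis:
# higher eGFR and slower decline are beneficial, higher CKD/ESKD risk harmful
endpoint_orientation <- c(egfr = 1, slope = 1, ckd = -1, eskd = -1)

#' Classify directional consistency across the four kidney endpoints
#'
#' Each endpoint's MR beta is oriented onto a common kidney-benefit axis
#' (eGFR +, slope + meaning slower decline, CKD -, ESKD -). Among endpoints
#' significant at `endpoint_alpha` (default 0.0125 = 0.05/4), the protein is
#' `protective` if all oriented effects are positive, `detrimental` if all
#' negative, `inconsistent` if mixed, and `indeterminate` if no endpoint is
#' significant or any endpoint result is missing.
#'
#' @param endpoint_results Tibble with columns `endpoint` (values among
#'   `"egfr"`, `"slope"`, `"ckd"`, `"eskd"`), `beta`, `pvalue`.
#' @param endpoint_alpha Per-endpoint significance threshold.
#' @return One of `"protective"`, `"detrimental"`, `"inconsistent"`,
#'   `"indeterminate"`.
#' @export
classify_direction <- function(endpoint_results, endpoint_alpha = 0.0125) {
  need <- names(endpoint_orientation)
  if (!all(need %in% endpoint_results$endpoint) ||
      anyNA(endpoint_results$beta[endpoint_results$endpoint %in% need]) ||
      anyNA(endpoint_results$pvalue[endpoint_results$endpoint %in% need])) {
    return("indeterminate")
  }
  er <- endpoint_results[match(need, endpoint_results$endpoint), ]
  oriented <- er$beta * endpoint_orientation[er$endpoint]
  sig <- er$pvalue < endpoint_alpha
  if (!any(sig)) return("indeterminate")
  s <- oriented[sig]
  if (all(s > 0)) "protective" else if (all(s < 0)) "detrimental" else "inconsistent"
}

#' External replication by ACAT over replication-cohort endpoints
#'
#' Combines a protein's MR p-values against the external endpoints with ACAT
#' and declares replication when the combined p falls below
#' `alpha / n_proteins_attempted`.
#'
#' @param endpoint_pvalues MR p-values against the external endpoints
#'   (at least one).
#' @param n_proteins_attempted Number of proteins attempting replication
#'   (Bonferroni denominator).
#' @param alpha Family-wise alpha (default 0.05).
#' @return A list: `replication_acat_p`, `replicated`, `cutoff`.
#' @export
replicate_protein <- function(endpoint_pvalues, n_proteins_attempted,
                              alpha = 0.05) {
  pv <- endpoint_pvalues[!is.na(endpoint_pvalues)]
  if (length(pv) == 0) {
    return(list(replication_acat_p = NA_real_, replicated = NA,
                cutoff = bonferroni_threshold(alpha, n_proteins_attempted)))
  }
  p <- acat(pv)
  cutoff <- bonferroni_threshold(alpha, n_proteins_attempted)
  list(replication_acat_p = p, replicated = p < cutoff, cutoff = cutoff)
}

#' Assemble per-protein verdicts across endpoints and evidence gates
#'
#' Combines the four endpoint MR p-values with ACAT, applies the
#' dataset-level Bonferroni threshold, classifies directional consistency,
#' and merges the heterogeneity/pleiotropy flags, colocalization PP4 and
#' replication results into one row per protein. `passes_all` requires
#' significance, a uniform direction, PP4 above `pp4_min` and replication.
#'
#' @param mr_table Tibble with one row per protein x endpoint: columns
#'   `protein_id`, `endpoint`, `beta`, `se`, `pvalue`, `n_snp`, `Q_pvalue`,
#'   `egger_intercept_p`.
#' @param n_proteins_tested Bonferroni denominator for the dataset (default:
#'   number of distinct proteins in `mr_table`).
#' @param coloc_results Optional tibble `protein_id`, `pp4`.
#' @param replication Optional tibble `protein_id`, `replication_acat_p`,
#'   `replicated`.
#' @param alpha Family-wise alpha (default 0.05).
#' @param endpoint_alpha Per-endpoint threshold for direction (default
#'   0.0125).
#' @param pp4_min Colocalization gate (default 0.8).
#' @param dataset_label Label recorded per row.
#' @return A tibble with one row per protein (the verdict table).
#' @export
protein_verdicts <- function(mr_table, n_proteins_tested = NULL,
                             coloc_results = NULL, replication = NULL,
                             alpha = 0.05, endpoint_alpha = 0.0125,
                             pp4_min = 0.8, dataset_label = "synthetic") {
  n_prot <- n_proteins_tested %||% dplyr::n_distinct(mr_table$protein_id)
  cutoff <- bonferroni_threshold(alpha, n_prot)
  verdicts <- mr_table |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(df, key) {
      ok <- !is.na(df$pvalue)
      tibble::tibble(
        acat_p = if (any(ok)) acat(df$pvalue[ok]) else NA_real_,
        direction = classify_direction(df, endpoint_alpha),
        q_flag = any(df$Q_pvalue < 0.05, na.rm = TRUE),
        egger_flag = any(df$egger_intercept_p < 0.05, na.rm = TRUE)
      )
    }) |>
    dplyr::ungroup()
  verdicts$dataset_label <- dataset_label
  verdicts$significant <- !is.na(verdicts$acat_p) & verdicts$acat_p < cutoff
  if (!is.null(coloc_results)) {
    verdicts <- dplyr::left_join(verdicts,
                                 coloc_results[, c("protein_id", "pp4")],
                                 by = "protein_id")
  } else {
    verdicts$pp4 <- NA_real_
  }
  if (!is.null(replication)) {
    verdicts <- dplyr::left_join(
      verdicts,
      replication[, c("protein_id", "replication_acat_p", "replicated")],
      by = "protein_id")
  } else {
    verdicts$replication_acat_p <- NA_real_
    verdicts$replicated <- NA
  }
  verdicts$passes_all <- verdicts$significant &
    verdicts$direction %in% c("protective", "detrimental") &
    !is.na(verdicts$pp4) & verdicts$pp4 > pp4_min &
    isTRUE_vec(verdicts$replicated)
  attr(verdicts, "bonferroni_cutoff") <- cutoff
  verdicts
}

isTRUE_vec <- function(x) !is.na(x) & x
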