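#' Wakefield approximate Bayes factor (log scale)
#'
#' `log ABF = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W))` with `z = beta/se`,
#' `V = se^2`, and prior effect variance `W` equal to `0.15^2` for
#' quantitative traits and `0.2^2` (log-odds scale) for binary traits —
#' the canonical defaults, overridable through `sd_prior`.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param sd_prior Optional prior effect SD overriding the default.
#' @return Log approximate Bayes factor (vectorized).
#' @export
#' @examples
#' wakefield_abf(0.2, 0.02, "quantitative")
wakefield_abf <- function(beta, se, trait_type = c("quantitative", "binary"),
                          sd_prior = NULL) {
  trait_type <- match.arg(trait_type)
  assert_that(all(se > 0), "`se` must be positive")
  W <- (sd_prior %||% if (trait_type == "quantitative") 0.15 else 0.2)^2
  V <- se^2
  z <- beta / se
  0.5 * (log(V / (V + W)) + z^2 * W / (V + W))
}

#' Bayesian colocalization of two traits in a region
#'
#' Computes per-SNP Wakefield log-ABFs for each trait and the posterior
#' probabilities of the five hypotheses — H0 no association, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant — using the single-causal-variant model with priors
#' `p1`, `p2` (per-SNP association with each trait) and `p12` (per-SNP
#' shared causality). All sums are done in log space. Colocalization is
#' declared when PP4 exceeds `pp4_min`.
#'
#' @param trait1,trait2 `sumstats` tables restricted to the region (the
#'   caller extracts the sentinel +/- 500 kb window; see
#'   [extract_region()]); matched on `variant_id`.
#' @param p1,p2,p12 Prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param pp4_min Decision threshold on PP4 (default 0.8).
#' @param sd_prior1,sd_prior2 Optional prior effect SD overrides.
#' @return A tibble of class `coloc_result` with columns `n_snps`,
#'   `pp0`..`pp4`, `passed`, and the priors as attributes.
#' @export
colocalize <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       pp4_min = 0.8, sd_prior1 = NULL, sd_prior2 = NULL) {
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  assert_that(length(shared) >= 1, "no shared variants between the two traits")
  t1 <- trait1[match(shared, trait1$variant_id), ]
  t2 <- trait2[match(shared, trait2$variant_id), ]
  l1 <- wakefield_abf(t1$beta, t1$se,
                      attr(trait1, "trait_type") %||% "quantitative", sd_prior1)
  l2 <- wakefield_abf(t2$beta, t2$se,
                      attr(trait2, "trait_type") %||% "quantitative", sd_prior2)

  lsum1 <- logsumexp(l1)                # log sum_i L1_i
  lsum2 <- logsumexp(l2)                # log sum_j L2_j
  lsum12 <- logsumexp(l1 + l2)          # log sum_i L1_i L2_i
  lh0 <- 0
  lh1 <- log(p1) + lsum1
  lh2 <- log(p2) + lsum2
  lh4 <- log(p12) + lsum12
  # sum_{i != j} L1_i L2_j = (sum_i L1_i)(sum_j L2_j) - sum_i L1_i L2_i;
  # the cross product always dominates its diagonal, equality iff one SNP
  tot <- lsum1 + lsum2
  lcross <- if (lsum12 >= tot - 1e-12) -Inf else
    tot + log1p(-exp(lsum12 - tot))
  lh3 <- log(p1) + log(p2) + lcross

  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - logsumexp(lh))
  out <- tibble::tibble(
    n_snps = length(shared),
    pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4], pp4 = pp[5],
    passed = pp[5] > pp4_min
  )
  attr(out, "priors") <- c(p1 = p1, p2 = p2, p12 = p12)
  class(out) <- c("coloc_result", class(out))
  out
}

#' Extract a sentinel-centered region from a summary-statistics table
#'
#' Returns the rows within `window_bp` of the sentinel variant (the variant
#' with the smallest p-value unless given explicitly), the regional input to
#' [colocalize()].
#'
#' @param sumstats A `sumstats` table.
#' @param sentinel_id Variant id of the sentinel; default: smallest p-value.
#' @param window_bp Half-width (default 500,000).
#' @return The regional subset (same class and metadata).
#' @export
extract_region <- function(sumstats, sentinel_id = NULL, window_bp = 5e5) {
  sentinel_id <- sentinel_id %||%
    sumstats$variant_id[which.min(sumstats$pvalue)]
  s <- sumstats[sumstats$variant_id == sentinel_id, ]
  assert_that(nrow(s) == 1, "sentinel variant not found")
  keep <- sumstats$chrom == s$chrom & abs(sumstats$pos - s$pos) <= window_bp
  sumstats[keep, , drop = FALSE]
}
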