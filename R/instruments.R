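#' Select cis-pQTL candidate variants for a protein
#'
#' Keeps variants within `window_bp` of the gene's transcription start site
#' (inclusive on both ends, 1-based coordinates) with minor allele frequency
#' strictly greater than `maf_min`.
#'
#' @param exposure A `sumstats` table for the protein.
#' @param gene One-row tibble/list with `gene`, `chrom`, `tss`.
#' @param maf_min MAF lower bound (default 0.01; the filter is MAF > 1%).
#' @param window_bp Half-width of the cis window (default 500,000).
#' @return The filtered `sumstats` rows (possibly empty, in which case the
#'   protein is skipped by callers).
#' @export
select_cis_pqtls <- function(exposure, gene, maf_min = 0.01,
                             window_bp = 5e5) {
  keep <- exposure$chrom == as.character(gene$chrom) &
    abs(exposure$pos - gene$tss) <= window_bp &
    pmin(exposure$eaf, 1 - exposure$eaf) > maf_min
  out <- exposure[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    rlang::warn(paste0("no cis-pQTL candidates for ", gene$gene %||% "gene",
                       "; protein skipped"))
  }
  out
}

#' Greedy LD clumping of candidate instruments
#'
#' Orders candidates by p-value and keeps each variant only if its LD with
#' every already-kept variant is below `r2_max`, yielding approximately
#' conditionally independent cis instruments. Candidates above `p_max` are
#' not considered instruments at all.
#'
#' @param candidates `sumstats` rows from [select_cis_pqtls()].
#' @param ld Either a square correlation matrix (dimnames = variant ids), a
#'   dosage matrix with columns named by variant id (correlation computed
#'   internally), or `NULL` (variants treated as independent).
#' @param r2_max Clumping threshold on r^2 (default 0.1).
#' @param p_max Instrument relevance threshold (default 5e-8).
#' @return The retained `sumstats` rows, p-value ordered.
#' @export
clump_instruments <- function(candidates, ld = NULL, r2_max = 0.1,
                              p_max = 5e-8) {
  cand <- candidates[!is.na(candidates$pvalue) & candidates$pvalue < p_max, ,
                     drop = FALSE]
  if (nrow(cand) <= 1 || is.null(ld)) return(cand[order(cand$pvalue), ])
  if (!isTRUE(nrow(ld) == ncol(ld) && all(abs(ld) <= 1 + 1e-8))) {
    ld <- stats::cor(as.matrix(ld))
  }
  assert_that(!is.null(colnames(ld)),
              "LD reference must carry variant ids as column names")
  cand <- cand[order(cand$pvalue), ]
  kept <- character()
  for (v in cand$variant_id) {
    if (!v %in% colnames(ld)) { kept <- c(kept, v); next }
    r2 <- ld[v, kept[kept %in% rownames(ld)]]^2
    if (length(r2) == 0 || all(r2 < r2_max)) kept <- c(kept, v)
  }
  cand[cand$variant_id %in% kept, , drop = FALSE]
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics into an instrument set
#'
#' Matches variants by id; when outcome alleles are swapped relative to the
#' exposure the outcome beta is negated (and its frequency complemented).
#' Palindromic (A/T, C/G) variants are aligned by allele-frequency comparison
#' when both sides have `|eaf - 0.5| > 0.08`, otherwise dropped as ambiguous.
#' Variants absent from the outcome are substituted by their best LD proxy
#' with `r^2 >= r2_min` and `|MAF difference| <= maf_tol`, flagged
#' `proxy_used`. Unresolvable variants are dropped; the exact accounting
#' (retained / flipped / proxied / dropped) is attached as the
#' `"accounting"` attribute and always sums to the number of input variants.
#'
#' @param exposure,outcome `sumstats` tables.
#' @param ld_proxies Optional tibble (`variant_a`, `variant_b`, `r2`) of LD
#'   proxy pairs (symmetric lookup).
#' @param r2_min Proxy LD threshold (default 0.9).
#' @param maf_tol Maximum MAF difference for a proxy (default 0.02).
#' @param freq_margin Ambiguity zone half-width for palindromic alignment.
#' @return A tibble of class `instrument_set` with columns `variant_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf`, `proxy_used`, and
#'   attributes `accounting`, `exposure_name`, `outcome_name`.
#' @export
harmonize <- function(exposure, outcome, ld_proxies = NULL, r2_min = 0.9,
                      maf_tol = 0.02, freq_margin = 0.08) {
  acc <- c(retained = 0L, flipped = 0L, proxied = 0L, dropped = 0L)
  out_idx <- stats::setNames(seq_len(nrow(outcome)), outcome$variant_id)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    j <- out_idx[ex$variant_id]
    used_proxy <- FALSE
    if (is.na(j) && !is.null(ld_proxies)) {
      # symmetric proxy lookup, best r2 first
      px <- ld_proxies[(ld_proxies$variant_a == ex$variant_id |
                          ld_proxies$variant_b == ex$variant_id) &
                         ld_proxies$r2 >= r2_min, , drop = FALSE]
      if (nrow(px) > 0) {
        px$other <- ifelse(px$variant_a == ex$variant_id,
                           px$variant_b, px$variant_a)
        px <- px[order(-px$r2), ]
        for (cand in px$other) {
          jj <- out_idx[cand]
          if (!is.na(jj)) {
            maf_ex <- pmin(ex$eaf, 1 - ex$eaf)
            maf_ou <- pmin(outcome$eaf[jj], 1 - outcome$eaf[jj])
            if (abs(maf_ex - maf_ou) <= maf_tol) { j <- jj; used_proxy <- TRUE; break }
          }
        }
      }
    }
    if (is.na(j)) { acc["dropped"] <- acc["dropped"] + 1L; next }
    ou <- outcome[j, ]
    same <- ou$effect_allele == ex$effect_allele &&
      ou$other_allele == ex$other_allele
    swapped <- ou$effect_allele == ex$other_allele &&
      ou$other_allele == ex$effect_allele
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    if (pal && (same || swapped)) {
      # frequency-based orientation; ambiguous near 0.5 on either side
      if (abs(ex$eaf - 0.5) <= freq_margin || abs(ou$eaf - 0.5) <= freq_margin) {
        acc["dropped"] <- acc["dropped"] + 1L; next
      }
      freq_concordant <- (ex$eaf > 0.5) == (ou$eaf > 0.5)
      same <- freq_concordant
      swapped <- !freq_concordant
    }
    if (same) {
      b_out <- ou$beta
      if (used_proxy) acc["proxied"] <- acc["proxied"] + 1L
      else acc["retained"] <- acc["retained"] + 1L
    } else if (swapped) {
      b_out <- -ou$beta
      if (used_proxy) acc["proxied"] <- acc["proxied"] + 1L
      else acc["flipped"] <- acc["flipped"] + 1L
    } else {
      acc["dropped"] <- acc["dropped"] + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      variant_id = ex$variant_id, beta_exp = ex$beta, se_exp = ex$se,
      beta_out = b_out, se_out = ou$se, eaf = ex$eaf, proxy_used = used_proxy
    )
  }
  res <- dplyr::bind_rows(rows)
  if (nrow(res) > 0) assert_that(!anyDuplicated(res$variant_id),
                                 "duplicate variants after harmonization")
  attr(res, "accounting") <- acc
  attr(res, "exposure_name") <- attr(exposure, "trait_name")
  attr(res, "outcome_name") <- attr(outcome, "trait_name")
  class(res) <- c("instrument_set", class(res))
  res
}
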