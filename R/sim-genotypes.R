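#' Simulate regional genotype dosages under an AR(1) LD model
#'
#' Draws two haplotypes per person from a latent multivariate normal with
#' AR(1) correlation `exp(-ld_decay * distance)` (distance in inter-variant
#' spacing units; `ld_decay = 0` means independent variants), thresholded at
#' each variant's allele frequency so that per-variant sampling is
#' Hardy-Weinberg at its MAF. Variant metadata carries 1-based positions,
#' alleles and the realized allele frequency.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state
#'   (defaults to `config$seed`).
#' @param chrom Chromosome label for the region.
#' @param region_start 1-based position of the first variant.
#' @param spacing_bp Distance between adjacent variants in base pairs.
#' @param variants Optional variant metadata from a previous call; when
#'   given, its positions, alleles and MAFs are reused (fresh individuals at
#'   the same variants — e.g. a replication cohort).
#' @return A list with `dosages` (n x m numeric matrix, entries in \[0, 2\])
#'   and `variants` (tibble: variant_id, chrom, pos, effect_allele,
#'   other_allele, maf, eaf).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 100, seed = 7))
#' dim(g$dosages)
simulate_genotypes <- function(config, seed = config$seed, chrom = "1",
                               region_start = 1e6L, spacing_bp = NULL,
                               variants = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  m <- config$n_variants_region
  if (!is.null(variants)) {
    assert_that(nrow(variants) == m, "`variants` must match n_variants_region")
    pos <- variants$pos
    chrom <- variants$chrom[1]
    mafs <- variants$maf
  } else {
    spacing_bp <- spacing_bp %||% max(1L, floor(1e6 / m))
    pos <- as.integer(region_start + (seq_len(m) - 1L) * spacing_bp)
    mafs <- runif(m, config$maf_range[1], config$maf_range[2])
  }

  draw_haps <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (config$ld_decay > 0 && m > 1) {
      # AR(1) latent process: z_j = rho z_{j-1} + sqrt(1-rho^2) e_j
      rho <- exp(-config$ld_decay)
      for (j in 2:m) {
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
    }
    # allele carried iff latent value falls below the MAF quantile
    sweep(z, 2, qnorm(mafs), `<`) * 1
  }
  dosages <- draw_haps() + draw_haps()

  if (is.null(variants)) {
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
    variants <- tibble::tibble(
      variant_id = paste0(chrom, ":", pos),
      chrom = chrom,
      pos = as.integer(pos),
      effect_allele = ea,
      other_allele = unname(oa),
      maf = mafs,
      eaf = unname(colMeans(dosages)) / 2
    )
  } else {
    variants <- dplyr::mutate(variants, eaf = unname(colMeans(dosages)) / 2)
  }
  colnames(dosages) <- variants$variant_id
  list(dosages = dosages, variants = variants)
}

#' Simulate protein levels and outcomes with known causal structure
#'
#' The protein receives a per-allele effect from one causal variant plus a
#' standard-normal confounder and unit-variance noise. Under the shared-causal
#' architecture the quantitative outcome is
#' `protein_outcome_effect * protein + confounder_effect * confounder + noise`;
#' under the distinct-causal architecture the outcome instead receives a
#' direct per-allele effect from a different variant in the region (magnitude
#' `causal_protein_effect * protein_outcome_effect`) and nothing through the
#' protein. The binary outcome applies a logistic link to the same linear
#' predictor.
#'
#' @param dosages n x m dosage matrix from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param seed Integer seed or `NULL` (defaults to `config$seed + 1`).
#' @param causal_index Column index of the protein's causal variant
#'   (default: middle of the region).
#' @return A list: `protein`, `outcome_quant`, `outcome_binary` (0/1),
#'   `confounder`, `damage` (latent kidney-damage score, equal to the
#'   quantitative outcome), `causal_index`, `direct_index` (NA under the
#'   shared architecture).
#' @export
simulate_protein_and_outcome <- function(dosages, config,
                                         seed = config$seed + 1L,
                                         causal_index = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dosages)
  m <- ncol(dosages)
  causal_index <- causal_index %||% ((m + 1L) %/% 2L)
  confounder <- rnorm(n)
  protein <- config$causal_protein_effect * dosages[, causal_index] +
    confounder + rnorm(n)

  if (config$shared_causal) {
    direct_index <- NA_integer_
    lin <- config$protein_outcome_effect * protein +
      config$confounder_effect * confounder
  } else {
    # outcome driven by a different variant, far from the protein's causal one
    direct_index <- if (causal_index > m / 2) 1L else m
    direct_effect <- config$causal_protein_effect * config$protein_outcome_effect
    lin <- direct_effect * dosages[, direct_index] +
      config$confounder_effect * confounder
  }
  outcome_quant <- lin + rnorm(n)
  outcome_binary <- rbinom(n, 1, plogis(config$binary_intercept + lin))
  list(protein = protein, outcome_quant = outcome_quant,
       outcome_binary = outcome_binary, confounder = confounder,
       damage = outcome_quant, causal_index = causal_index,
       direct_index = direct_index)
}

#' Simulate regional GWAS summary statistics directly
#'
#' Generates z-scores for a region from the standard summary-statistic model:
#' with a single causal variant of non-centrality `z_causal`, the expected
#' z-score of variant j is `r_{j,causal} * z_causal` and the noise is
#' multivariate normal with the LD correlation matrix (AR(1),
#' `exp(-ld_decay * |i-j|)`). Used for colocalization scenario studies where
#' individual-level simulation would be wasteful.
#'
#' @param n_variants Number of variants.
#' @param causal_index Index of the causal variant.
#' @param z_causal Non-centrality (expected z) at the causal variant.
#' @param ld_decay AR(1) decay parameter (0 = independent).
#' @param n_samples GWAS sample size, used to scale betas (`se = 1/sqrt(n)`).
#' @param seed Integer seed or `NULL`.
#' @param chrom,region_start,spacing_bp Region coordinates as in
#'   [simulate_genotypes()].
#' @return A `sumstats` tibble (see [new_sumstats()]).
#' @export
simulate_region_sumstats <- function(n_variants, causal_index, z_causal,
                                     ld_decay = 0.25, n_samples = 50000,
                                     seed = NULL, chrom = "1",
                                     region_start = 1e6L, spacing_bp = 5000L) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_variants
  idx <- seq_len(m)
  if (ld_decay > 0) {
    corr <- exp(-ld_decay * abs(outer(idx, idx, `-`)))
  } else {
    corr <- diag(m)
  }
  mu <- corr[, causal_index] * z_causal
  z <- mu + drop(rnorm(m) %*% chol(corr))
  se <- rep(1 / sqrt(n_samples), m)
  pos <- region_start + (idx - 1L) * spacing_bp
  new_sumstats(
    tibble::tibble(
      variant_id = paste0(chrom, ":", pos),
      chrom = chrom, pos = as.integer(pos),
      effect_allele = "A", other_allele = "G",
      eaf = 0.5, beta = z * se, se = se, pvalue = wald_p(z * se, se)
    ),
    trait_name = "simulated_trait", trait_type = "quantitative",
    n = n_samples
  )
}
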