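test_that("ACAT passes identical p-values through and handles extremes", {
  expect_equal(acat(rep(0.05, 4)), 0.05, tolerance = 1e-12)
  expect_equal(acat(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  # clipping keeps extreme inputs finite
  expect_gt(acat(c(1e-300, 0.5)), 0)
  expect_lt(acat(c(1 - 1e-16, 1 - 1e-16)), 1)
  expect_error(acat(numeric()), "empty")
  expect_error(acat(c(0.5, 1.2)), "p-values")
})

test_that("ACAT is permutation-invariant and monotone", {
  set.seed(81)
  for (i in 1:25) {
    p <- runif(4)
    expect_equal(acat(p), acat(sample(p)), tolerance = 1e-12)
    j <- sample(4, 1)
    p2 <- p
    p2[j] <- p[j] * 0.5
    expect_lte(acat(p2), acat(p))
  }
})

test_that("Bonferroni helper reproduces the screen's printed cutoffs", {
  expect_equal(signif(bonferroni_threshold(0.05, 9), 2), 5.6e-3)
  expect_equal(signif(bonferroni_threshold(0.05, 1020), 2), 4.9e-5)
  expect_identical(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 50), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

make_endpoint_results <- function(betas, pvalues) {
  tibble::tibble(endpoint = c("egfr", "slope", "ckd", "eskd"),
                 beta = betas, pvalue = pvalues)
}

test_that("direction classification orients endpoints onto the benefit axis", {
  # higher eGFR, slower decline, lower CKD/ESKD risk: protective
  prot <- make_endpoint_results(c(0.3, 0.2, -0.4, -0.5), rep(0.001, 4))
  expect_identical(classify_direction(prot), "protective")
  det <- make_endpoint_results(c(-0.3, -0.2, 0.4, 0.5), rep(0.001, 4))
  expect_identical(classify_direction(det), "detrimental")
  # eGFR up but CKD risk also up: inconsistent
  mix <- make_endpoint_results(c(0.3, 0.1, 0.4, -0.1),
                               c(0.001, 0.5, 0.001, 0.5))
  expect_identical(classify_direction(mix), "inconsistent")
  # nothing below 0.0125
  none <- make_endpoint_results(c(0.3, 0.2, -0.4, -0.5), rep(0.02, 4))
  expect_identical(classify_direction(none), "indeterminate")
  # invariant to endpoint row order
  expect_identical(classify_direction(prot[c(3, 1, 4, 2), ]), "protective")
  # missing endpoint
  expect_identical(classify_direction(prot[1:3, ]), "indeterminate")
})

test_that("replication gate applies the attempted-protein Bonferroni", {
  rp <- replicate_protein(c(1e-6, 0.2, 0.3, 0.4), n_proteins_attempted = 50)
  expect_equal(rp$cutoff, 0.001)
  expect_true(rp$replicated)
  rp2 <- replicate_protein(c(0.2, 0.3), n_proteins_attempted = 50)
  expect_false(rp2$replicated)
  rp3 <- replicate_protein(numeric(), n_proteins_attempted = 10)
  expect_true(is.na(rp3$replicated))
})

test_that("family-wise false replication stays controlled under the null", {
  set.seed(82)
  n_prot <- 100
  flags <- replicate(n_prot, {
    replicate_protein(runif(4), n_proteins_attempted = n_prot)$replicated
  })
  # expected number of false replications is ~alpha under Bonferroni
  expect_lte(sum(flags), 2)
})

test_that("verdict assembly enforces the passes_all conjunction", {
  mr_table <- dplyr::bind_rows(
    dplyr::mutate(make_endpoint_results(c(0.3, 0.2, -0.4, -0.5),
                                        rep(1e-6, 4)),
                  protein_id = "good", se = 0.05, n_snp = 3L,
                  Q_pvalue = 0.5, egger_intercept_p = 0.6),
    dplyr::mutate(make_endpoint_results(c(0.1, -0.1, 0.1, -0.1),
                                        rep(0.4, 4)),
                  protein_id = "nullprot", se = 0.05, n_snp = 3L,
                  Q_pvalue = 0.5, egger_intercept_p = 0.6)
  )
  v <- protein_verdicts(
    mr_table, n_proteins_tested = 2,
    coloc_results = tibble::tibble(protein_id = c("good", "nullprot"),
                                   pp4 = c(0.95, 0.2)),
    replication = tibble::tibble(protein_id = c("good", "nullprot"),
                                 replication_acat_p = c(1e-5, 0.5),
                                 replicated = c(TRUE, FALSE)))
  good <- v[v$protein_id == "good", ]
  expect_true(good$significant)
  expect_identical(good$direction, "protective")
  expect_true(good$passes_all)
  bad <- v[v$protein_id == "nullprot", ]
  expect_false(bad$significant)
  expect_false(bad$passes_all)
  # acat_p in (0,1); passes_all implies every gate
  expect_true(all(v$acat_p > 0 & v$acat_p < 1))
  expect_true(all(!v$passes_all |
                    (v$significant &
                       v$direction %in% c("protective", "detrimental") &
                       v$pp4 > 0.8 & v$replicated)))
})
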