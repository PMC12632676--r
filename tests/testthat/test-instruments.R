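test_that("cis window is inclusive and the MAF filter is strict", {
  tss <- 2e6
  ss <- make_sumstats(beta = rep(0.1, 4), se = rep(0.02, 4),
                      pos = c(tss + 500000, tss + 500001, tss, tss - 200),
                      eaf = c(0.3, 0.3, 0.005, 0.995))
  gene <- list(gene = "GENE1", chrom = "1", tss = tss)
  kept <- select_cis_pqtls(ss, gene)
  # boundary variant retained; outside-window and rare variants removed
  expect_true(paste0("1:", tss + 500000) %in% kept$variant_id)
  expect_false(paste0("1:", tss + 500001) %in% kept$variant_id)
  expect_false(paste0("1:", tss) %in% kept$variant_id)        # eaf 0.005
  expect_false(paste0("1:", tss - 200) %in% kept$variant_id)  # eaf 0.995
})

test_that("empty candidate sets are returned with a warning", {
  ss <- make_sumstats(0.1, 0.02, pos = 1e6, eaf = 0.3)
  expect_warning(
    out <- select_cis_pqtls(ss, list(gene = "G", chrom = "2", tss = 1e6)),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("greedy clumping keeps p-ordered variants below the LD threshold", {
  ss <- make_sumstats(beta = c(0.5, 0.45, 0.2), se = c(0.02, 0.02, 0.02),
                      pos = c(1e6, 1e6 + 1000, 1e6 + 2000))
  ld <- diag(3)
  dimnames(ld) <- list(ss$variant_id, ss$variant_id)
  ld[1, 2] <- ld[2, 1] <- 0.8   # r; r^2 = 0.64 > 0.1
  ld[1, 3] <- ld[3, 1] <- 0.1
  ld[2, 3] <- ld[3, 2] <- 0.1
  kept <- clump_instruments(ss, ld, r2_max = 0.1, p_max = 1)
  expect_identical(kept$variant_id, ss$variant_id[c(1, 3)])
  # relevance threshold removes weak variants before clumping
  none <- clump_instruments(ss, ld, r2_max = 0.1, p_max = 1e-300)
  expect_equal(nrow(none), 0)
})

test_that("allele flips negate the outcome beta", {
  expo <- make_sumstats(0.30, 0.03, pos = 1e6, ea = "A", oa = "G")
  outc <- make_sumstats(-0.10, 0.02, pos = 1e6, ea = "G", oa = "A",
                        trait_name = "outcome")
  hm <- harmonize(expo, outc)
  expect_equal(hm$beta_exp, 0.30)
  expect_equal(hm$beta_out, 0.10)
  expect_identical(unname(attr(hm, "accounting")["flipped"]), 1L)
})

test_that("proxies substitute only above r2 0.9 with similar MAF", {
  expo <- make_sumstats(0.30, 0.03, pos = 1e6, ea = "A", oa = "G", eaf = 0.30)
  # outcome lacks the exposure variant but has two potential proxies
  outc <- make_sumstats(c(0.12, 0.08), c(0.02, 0.02),
                        pos = c(1e6 + 5000, 1e6 + 9000),
                        ea = c("A", "A"), oa = c("G", "G"),
                        eaf = c(0.31, 0.30), trait_name = "outcome")
  proxies_good <- tibble::tibble(variant_a = "1:1000000",
                                 variant_b = "1:1005000", r2 = 0.95)
  hm <- harmonize(expo, outc, ld_proxies = proxies_good)
  expect_equal(nrow(hm), 1)
  expect_true(hm$proxy_used)
  expect_equal(hm$beta_out, 0.12)
  expect_identical(unname(attr(hm, "accounting")["proxied"]), 1L)

  proxies_weak <- tibble::tibble(variant_a = "1:1000000",
                                 variant_b = "1:1005000", r2 = 0.85)
  hm2 <- harmonize(expo, outc, ld_proxies = proxies_weak)
  expect_equal(nrow(hm2), 0)
  expect_identical(unname(attr(hm2, "accounting")["dropped"]), 1L)

  # dissimilar MAF blocks the proxy
  outc_badmaf <- make_sumstats(0.12, 0.02, pos = 1e6 + 5000, ea = "A",
                               oa = "G", eaf = 0.40, trait_name = "outcome")
  hm3 <- harmonize(expo, outc_badmaf, ld_proxies = proxies_good)
  expect_equal(nrow(hm3), 0)
})

test_that("palindromic variants use frequency alignment with an ambiguity zone", {
  # clear frequencies, concordant: kept without flip
  expo <- make_sumstats(0.2, 0.02, pos = 1e6, ea = "A", oa = "T", eaf = 0.2)
  outc <- make_sumstats(0.1, 0.02, pos = 1e6, ea = "A", oa = "T", eaf = 0.25,
                        trait_name = "outcome")
  hm <- harmonize(expo, outc)
  expect_equal(hm$beta_out, 0.1)
  # clear frequencies, discordant: flipped
  outc2 <- make_sumstats(0.1, 0.02, pos = 1e6, ea = "A", oa = "T", eaf = 0.75,
                         trait_name = "outcome")
  hm2 <- harmonize(expo, outc2)
  expect_equal(hm2$beta_out, -0.1)
  # ambiguous near 0.5: dropped
  outc3 <- make_sumstats(0.1, 0.02, pos = 1e6, ea = "A", oa = "T", eaf = 0.52,
                         trait_name = "outcome")
  hm3 <- harmonize(expo, outc3)
  expect_equal(nrow(hm3), 0)
  expect_identical(unname(attr(hm3, "accounting")["dropped"]), 1L)
})

test_that("unexplainable allele mismatches are dropped with exact accounting", {
  expo <- make_sumstats(c(0.2, 0.3), c(0.02, 0.02), pos = c(1e6, 1e6 + 100),
                        ea = c("A", "A"), oa = c("G", "G"))
  outc <- make_sumstats(c(0.1, 0.1), c(0.02, 0.02), pos = c(1e6, 1e6 + 100),
                        ea = c("A", "C"), oa = c("G", "T"),
                        trait_name = "outcome")
  hm <- harmonize(expo, outc)
  acc <- attr(hm, "accounting")
  expect_identical(unname(acc["retained"]), 1L)
  expect_identical(unname(acc["dropped"]), 1L)
  expect_equal(sum(acc), nrow(expo))
})

test_that("harmonization is idempotent", {
  expo <- make_sumstats(c(0.2, 0.3, 0.25), c(0.02, 0.02, 0.03),
                        pos = c(1e6, 1e6 + 100, 1e6 + 200))
  outc <- make_sumstats(c(0.1, -0.05, 0.02), c(0.02, 0.02, 0.02),
                        pos = c(1e6, 1e6 + 100, 1e6 + 200),
                        trait_name = "outcome")
  hm1 <- harmonize(expo, outc)
  hm2 <- harmonize(expo, outc)
  expect_identical(as.data.frame(hm1), as.data.frame(hm2))
  # an already-aligned pair requires no flips
  expect_identical(unname(attr(hm1, "accounting")["flipped"]), 0L)
  expect_equal(hm1$beta_out, outc$beta)
})
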