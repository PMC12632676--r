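test_that("null causal effect leaves only the confounder path", {
  cfg <- sim_config(n_individuals = 20000, n_variants_region = 5,
                    protein_outcome_effect = 0, confounder_effect = 0.5,
                    seed = 31)
  g <- simulate_genotypes(cfg)
  po <- simulate_protein_and_outcome(g$dosages, cfg)
  # protein-outcome association disappears once the confounder is held fixed
  fit <- lm(po$outcome_quant ~ po$protein + po$confounder)
  est <- summary(fit)$coefficients["po$protein", ]
  expect_lt(abs(est["Estimate"]), 3 * est["Std. Error"])
  # but the marginal correlation is non-zero (confounder path)
  expect_gt(cor(po$protein, po$outcome_quant), 0.05)
})

test_that("per-allele protein effect is recovered by OLS", {
  cfg <- sim_config(n_individuals = 20000, n_variants_region = 3,
                    maf_range = c(0.3, 0.3), causal_protein_effect = 0.5,
                    ld_decay = 0, seed = 32)
  g <- simulate_genotypes(cfg)
  po <- simulate_protein_and_outcome(g$dosages, cfg)
  fit <- summary(lm(po$protein ~ g$dosages[, po$causal_index]))$coefficients
  expect_lt(abs(fit[2, "Estimate"] - 0.5), 3 * fit[2, "Std. Error"])
})

test_that("distinct-causal outcome is independent of the protein's variant", {
  cfg <- sim_config(n_individuals = 20000, n_variants_region = 9,
                    shared_causal = FALSE, ld_decay = 0, seed = 33)
  g <- simulate_genotypes(cfg)
  po <- simulate_protein_and_outcome(g$dosages, cfg)
  expect_false(is.na(po$direct_index))
  expect_true(po$direct_index != po$causal_index)
  # partial correlation of outcome with the protein's causal variant given
  # the direct-effect variant is ~0
  fit <- summary(lm(po$outcome_quant ~ g$dosages[, po$causal_index] +
                      g$dosages[, po$direct_index]))$coefficients
  expect_lt(abs(fit[2, "Estimate"]), 3 * fit[2, "Std. Error"])
  # while the direct variant has a real effect
  expect_lt(fit[3, "Pr(>|t|)"], 1e-4)
})

test_that("degenerate slope variance and zero noise give exact slopes", {
  cfg <- sim_config(n_individuals = 50, slope_mean = -3, slope_sd = 0,
                    scr_cv = 0, n_visits = 5, followup_years = 5,
                    damage_slope_effect = 0, damage_egfr_effect = 0,
                    seed = 34)
  set.seed(34)
  persons <- tibble::tibble(id = sprintf("p%02d", 1:50),
                            age = runif(50, 40, 70),
                            sex = rep(c("male", "female"), 25))
  lg <- simulate_longitudinal_egfr(cfg, persons, seed = NULL)
  labs <- dplyr::inner_join(lg$labs, persons, by = "id")
  labs$egfr <- ckdepi_egfr(labs$scr, labs$age + labs$day / 365.25, labs$sex)
  fit <- suppressWarnings(fit_egfr_slope(labs[, c("id", "day", "egfr")]))
  expect_equal(unname(fit$slopes$slope_pct_year),
               rep(-3, 50), tolerance = 1e-6)
})

test_that("single-visit persons are excluded from slope generation and flagged", {
  cfg <- sim_config(n_individuals = 10, seed = 35)
  persons <- tibble::tibble(id = sprintf("p%02d", 1:10),
                            age = rep(60, 10), sex = rep("male", 10),
                            n_visits = c(1L, rep(4L, 9)))
  lg <- simulate_longitudinal_egfr(cfg, persons)
  expect_identical(lg$excluded, "p01")
  expect_true(is.na(lg$truth$true_slope_pct_year[1]))
  expect_equal(sum(lg$labs$id == "p01"), 1)
})

test_that("a fixed seed reproduces the entire cohort", {
  cfg <- sim_config(n_individuals = 150, n_variants_region = 6, seed = 36)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$persons, c2$persons)
  expect_identical(c1$labs, c2$labs)
  expect_identical(c1$dosages, c2$dosages)
  expect_identical(c1$procedures, c2$procedures)
})

test_that("cohort tables satisfy their invariants and round-trip to text", {
  cfg <- sim_config(n_individuals = 80, n_variants_region = 4, seed = 37)
  ch <- simulate_cohort(cfg)
  expect_true(all(ch$labs$scr > 0))
  expect_true(all(ch$dosages >= 0 & ch$dosages <= 2))
  days_sorted <- tapply(ch$labs$day, ch$labs$id, function(d) all(diff(d) >= 0))
  expect_true(all(days_sorted))
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(
    dir, c("persons.tsv", "variants.tsv", "dosages.tsv", "labs.tsv")))))
  labs_back <- utils::read.table(file.path(dir, "labs.tsv"), header = TRUE,
                                 sep = "\t")
  expect_equal(nrow(labs_back), nrow(ch$labs))
  expect_equal(labs_back$scr, ch$labs$scr, tolerance = 1e-12)
})

test_that("summary statistics round-trip through the writer and reader", {
  cfg <- sim_config(n_individuals = 400, n_variants_region = 6, seed = 38)
  g <- simulate_genotypes(cfg)
  po <- simulate_protein_and_outcome(g$dosages, cfg)
  ss <- scan_quantitative(po$protein, g$dosages, NULL, g$variants,
                          trait_name = "protein")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path)
  expect_equal(back$beta, ss$beta, tolerance = 1e-12)
  expect_equal(back$se, ss$se, tolerance = 1e-12)
  expect_equal(back$eaf, ss$eaf, tolerance = 1e-12)
  expect_identical(attr(back, "trait_name"), "protein")
  expect_equal(attr(back, "n"), attr(ss, "n"))
})
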