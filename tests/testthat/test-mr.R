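test_that("Wald ratio follows the delta method", {
  r <- wald_ratio(0.5, 0.05, 0.1, 0.02)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.04)
  r0 <- wald_ratio(0.5, 0.05, 0, 0.02)
  expect_equal(r0$beta, 0)
  expect_equal(r0$pvalue, 1)
  # orientation invariance
  r1 <- wald_ratio(-0.5, 0.05, -0.1, 0.02)
  expect_equal(r1$beta, r$beta)
  expect_equal(r1$se, r$se)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.02), "skipped")
})

test_that("IVW equals the Wald ratio under perfect homogeneity", {
  instr <- make_instruments(c(0.4, 0.4), c(0.03, 0.03), c(0.1, 0.1),
                            c(0.02, 0.02))
  fit <- ivw_mre(instr)
  wald <- wald_ratio(0.4, 0.03, 0.1, 0.02)
  expect_equal(fit$beta, wald$beta, tolerance = 1e-12)
  expect_equal(fit$cochran_Q, 0, tolerance = 1e-12)
  # single instrument defers to the Wald ratio
  single <- ivw_mre(instr[1, ])
  expect_identical(single$method, "wald")
  expect_equal(single$beta, wald$beta)
  expect_equal(single$se, wald$se)
})

test_that("IVW matches a brute-force WLS oracle to 1e-10", {
  instr <- make_instruments(
    beta_exp = c(0.30, 0.20, 0.50),
    se_exp = c(0.03, 0.04, 0.05),
    beta_out = c(0.09, 0.05, 0.14),
    se_out = c(0.020, 0.030, 0.025)
  )
  fit <- ivw_mre(instr)
  # origin-constrained WLS via R's lm machinery as the oracle
  oracle <- lm(beta_out ~ beta_exp - 1, data = instr,
               weights = 1 / instr$se_out^2)
  expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-10)
  s <- summary(oracle)
  se_fixed <- s$coefficients[1, 2] / s$sigma  # strip residual scaling
  Q_oracle <- sum((instr$beta_out - fitted(oracle))^2 / instr$se_out^2)
  expect_equal(fit$cochran_Q, Q_oracle, tolerance = 1e-10)
  expect_equal(fit$se, se_fixed * sqrt(max(1, Q_oracle / 2)),
               tolerance = 1e-10)
})

test_that("IVW recovers a planted causal effect within 3 SE", {
  instr <- simulate_two_sample(n = 50000, k = 10, theta = 0.25, seed = 71)
  fit <- ivw_mre(instr)
  expect_lt(abs(fit$beta - 0.25), 3 * fit$se)
})

test_that("IVW is invariant to joint sign flips of an instrument", {
  instr <- make_instruments(c(0.3, -0.2, 0.5), c(0.03, 0.04, 0.05),
                            c(0.09, -0.05, 0.14), c(0.02, 0.03, 0.025))
  flipped <- instr
  flipped$beta_exp[2] <- -flipped$beta_exp[2]
  flipped$beta_out[2] <- -flipped$beta_out[2]
  expect_equal(ivw_mre(instr)$beta, ivw_mre(flipped)$beta, tolerance = 1e-12)
  expect_equal(ivw_mre(instr)$se, ivw_mre(flipped)$se, tolerance = 1e-12)
})

test_that("Egger intercept is calibrated and recovers a planted offset", {
  instr <- simulate_two_sample(n = 50000, k = 10, theta = 0.25, seed = 72)
  eg <- egger(instr)
  expect_true(eg$defined)
  expect_lt(abs(eg$intercept), 2 * eg$intercept_se)
  # constant pleiotropic offset on every outcome effect
  shifted <- instr
  shifted$beta_out <- shifted$beta_out + 0.05
  eg2 <- egger(shifted)
  expect_lt(abs(eg2$intercept - 0.05), 3 * eg2$intercept_se)
  # fewer than 3 instruments: flagged undefined
  expect_false(egger(instr[1:2, ])$defined)
})

test_that("Cochran's Q detects outliers and is calibrated under the null", {
  # identical ratios
  instr <- make_instruments(c(0.4, 0.2), c(0.03, 0.03), c(0.2, 0.1),
                            c(0.02, 0.02))
  q <- cochran_q(instr)
  expect_equal(q$Q, 0, tolerance = 1e-12)
  expect_equal(q$pvalue, 1)
  # one ratio displaced by 10 SE
  instr2 <- make_instruments(c(0.4, 0.4, 0.4), rep(0.03, 3),
                             c(0.1, 0.1, 0.1 + 10 * 0.02), rep(0.02, 3))
  expect_lt(cochran_q(instr2)$pvalue, 1e-6)
  # null-homogeneous simulation: Q p-values uniform
  set.seed(73)
  bx <- c(0.3, 0.4, 0.5, 0.25, 0.35)
  pv <- replicate(1000, {
    by <- 0.2 * bx + 0.02 * rnorm(5)
    cochran_q(make_instruments(bx, rep(0.03, 5), by, rep(0.02, 5)))$pvalue
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("subgroup heterogeneity z-test matches the normal oracle", {
  a <- list(beta = 0.3, se = 0.05)
  b <- list(beta = 0.0, se = 0.05)
  hz <- heterogeneity_z(a, b)
  expect_equal(hz$z, 0.3 / sqrt(2 * 0.05^2), tolerance = 1e-10)
  expect_equal(hz$pvalue, 2 * pnorm(-abs(hz$z)), tolerance = 1e-12)
  expect_equal(round(hz$z, 2), 4.24)
  expect_lt(abs(hz$pvalue - 2.2e-5), 1e-6)
  same <- heterogeneity_z(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$pvalue, 1)
  # the diabetes-heterogeneity screen threshold
  expect_false(6e-4 < bonferroni_threshold(0.05, 93))
})

test_that("genetic instruments bypass confounding that biases observation", {
  set.seed(74)
  n <- 30000
  g <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  u <- rnorm(n)
  x <- drop(g %*% rep(0.2, 5)) + 1.5 * u + rnorm(n)
  y <- 0.25 * x - 1.2 * u + rnorm(n)
  obs <- coef(lm(y ~ x))[2]
  expect_gt(abs(obs - 0.25), 0.1)  # naive estimate badly biased
  exp_ss <- scan_quantitative(x, g)
  out_ss <- scan_quantitative(y, g)
  fit <- ivw_mre(make_instruments(exp_ss$beta, exp_ss$se,
                                  out_ss$beta, out_ss$se))
  expect_lt(abs(fit$beta - 0.25), 3 * fit$se)
})

test_that("tidy and glance return well-formed tibbles", {
  fit <- run_mr(simulate_two_sample(n = 5000, k = 5, theta = 0.2, seed = 75))
  td <- tidy(fit)
  gl <- glance(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("protein_id", "outcome_name", "method", "estimate",
                     "std.error", "statistic", "p.value", "n_snp"))
  expect_equal(nrow(gl), 1)
  expect_false(is.na(gl$egger_intercept))
})
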