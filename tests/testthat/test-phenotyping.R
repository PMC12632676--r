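test_that("CKD-EPI eGFR matches the published equation on a 20-case grid", {
  for (case in ckdepi_grid) {
    expect_equal(ckdepi_egfr(case$scr, case$age, case$sex), case$egfr,
                 tolerance = 1e-8)
  }
})

test_that("CKD-EPI eGFR is monotone in creatinine and continuous at the knot", {
  expect_true(ckdepi_egfr(1.8, 50, "male") < ckdepi_egfr(0.9, 50, "male"))
  expect_true(ckdepi_egfr(1.4, 60, "female") < ckdepi_egfr(0.7, 60, "female"))
  for (sex in c("male", "female")) {
    kappa <- if (sex == "female") 0.7 else 0.9
    left <- ckdepi_egfr(kappa - 1e-9, 55, sex)
    right <- ckdepi_egfr(kappa + 1e-9, 55, sex)
    expect_equal(left, right, tolerance = 1e-6)
  }
  expect_error(ckdepi_egfr(-1, 50, "male"), "positive")
})

test_that("creatinine inversion is the exact inverse of the equation", {
  egfr <- c(20, 45, 60, 90, 120)
  scr <- nephromr:::invert_ckdepi(egfr, 60, "female")
  expect_equal(ckdepi_egfr(scr, 60, "female"), egfr, tolerance = 1e-10)
  scr_m <- nephromr:::invert_ckdepi(egfr, 45, "male")
  expect_equal(ckdepi_egfr(scr_m, 45, "male"), egfr, tolerance = 1e-10)
})

test_that("CKD persistence rule reproduces hand-enumerated records", {
  expect_identical(call_ckd(data.frame(day = c(0, 120), egfr = c(55, 52))),
                   "case")
  expect_identical(call_ckd(data.frame(day = c(0, 30, 60),
                                       egfr = c(55, 52, 58))), "control")
  expect_identical(call_ckd(data.frame(day = c(0, 120), egfr = c(55, 65))),
                   "control")
  expect_identical(call_ckd(data.frame(day = integer(), egfr = numeric())),
                   "indeterminate")
  # exactly 90 days qualifies (inclusive)
  expect_identical(call_ckd(data.frame(day = c(0, 90), egfr = c(59, 59))),
                   "case")
  # one encounter is not enough for control eligibility
  expect_identical(call_ckd(data.frame(day = 0, egfr = 70)), "indeterminate")
})

test_that("case calling is invariant to record permutation", {
  s <- data.frame(day = c(200, 0, 120), egfr = c(70, 55, 52))
  expect_identical(call_ckd(s), call_ckd(s[c(2, 3, 1), ]))
  expect_identical(call_ckd(s), "case")
})

test_that("ESKD combines procedure and laboratory branches", {
  expect_identical(call_eskd(data.frame(day = 0, egfr = 80),
                             procedure_events = "transplant"), "case")
  expect_identical(call_eskd(data.frame(day = c(0, 100), egfr = c(12, 13))),
                   "case")
  expect_identical(
    call_eskd(data.frame(day = c(0, 30), egfr = c(12, 13)), n_encounters = 1),
    "indeterminate")
  expect_identical(call_eskd(data.frame(day = c(0, 100), egfr = c(80, 85))),
                   "control")
})

test_that("mixed-model slope recovery hits the simulated truth", {
  cfg <- sim_config(n_individuals = 500, slope_mean = -3, slope_sd = 1,
                    n_visits = 6, followup_years = 5, scr_cv = 0.02,
                    damage_slope_effect = 0, damage_egfr_effect = 0,
                    seed = 41)
  set.seed(41)
  persons <- tibble::tibble(id = sprintf("p%03d", 1:500),
                            age = runif(500, 40, 75),
                            sex = ifelse(runif(500) < 0.5, "male", "female"))
  lg <- simulate_longitudinal_egfr(cfg, persons, seed = NULL)
  labs <- dplyr::inner_join(lg$labs, persons, by = "id")
  labs$egfr <- ckdepi_egfr(labs$scr, labs$age + labs$day / 365.25, labs$sex)
  fit <- fit_egfr_slope(labs[, c("id", "day", "egfr")])
  expect_identical(fit$method, "lmm")
  m <- merge(fit$slopes, lg$truth, by = "id")
  se_mean <- sd(m$true_slope_pct_year) / sqrt(nrow(m))
  expect_lt(abs(mean(m$slope_pct_year) - (-3)), 2 * se_mean + 0.15)
  expect_lt(abs(fit$slope_sd_pct_year - 1), 0.3)
  expect_gt(cor(m$slope_pct_year, m$true_slope_pct_year), 0.8)
  # single-visit persons never appear in the slope table
  persons1 <- dplyr::bind_rows(persons,
                               tibble::tibble(id = "lonely", age = 60,
                                              sex = "male"))
  labs1 <- dplyr::bind_rows(labs[, c("id", "day", "egfr")],
                            tibble::tibble(id = "lonely", day = 0, egfr = 80))
  fit1 <- fit_egfr_slope(labs1)
  expect_false("lonely" %in% fit1$slopes$id)
  expect_true("lonely" %in% fit1$excluded)
})

test_that("diabetes definition requires both code and prescription conjuncts", {
  codes <- tibble::tibble(
    id = c("a", "a", "b", "b", "c", "d"),
    day = c(1, 50, 1, 30, 10, 5),
    code = "E11",
    pcp_visit = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  rx <- tibble::tibble(id = c("a", "c", "d"),
                       drug_class = c("diabetes", "diabetes", "statin"))
  res <- define_diabetes(codes, rx, ids = c("a", "b", "c", "d", "e"))
  expect_identical(res$diabetes,
                   c(TRUE,   # two code days + drug
                     FALSE,  # two code days, no drug
                     TRUE,   # single PCP-visit code + drug
                     FALSE,  # single non-PCP code; drug is non-diabetes
                     FALSE)) # no events at all
})
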