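#' Estimated GFR from serum creatinine (race-free CKD-EPI 2021)
#'
#' Computes eGFR (mL/min/1.73 m^2) with the 2021 creatinine-only CKD-EPI
#' equation:
#' `142 * min(scr/k, 1)^a * max(scr/k, 1)^-1.200 * 0.9938^age * (1.012 if female)`
#' with `k = 0.7` (female) / `0.9` (male) and `a = -0.241` (female) /
#' `-0.302` (male). Vectorized over all arguments.
#'
#' @param scr Serum creatinine, mg/dL (> 0).
#' @param age Age in years (> 0).
#' @param sex `"male"` or `"female"` (recycled as needed).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' ckdepi_egfr(0.9, 50, "male")   # ~104
#' ckdepi_egfr(0.7, 60, "female") # ~99
ckdepi_egfr <- function(scr, age, sex) {
  assert_that(all(scr > 0) && all(age > 0),
              "`scr` and `age` must be positive")
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  r <- scr / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.200) * 0.9938^age *
    ifelse(female, 1.012, 1)
}

# invert the CKD-EPI equation: creatinine giving a target eGFR at age/sex.
# The equation is strictly decreasing in scr, piecewise around scr = kappa.
invert_ckdepi <- function(egfr, age, sex) {
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  g0 <- 142 * 0.9938^age * ifelse(female, 1.012, 1) # eGFR at scr = kappa
  r <- ifelse(egfr <= g0, (egfr / g0)^(-1 / 1.2), (egfr / g0)^(1 / alpha))
  kappa * r
}

#' Call chronic kidney disease from an eGFR series
#'
#' Case: two eGFR values below 60 mL/min/1.73 m^2 at least 90 days apart.
#' Control: no qualifying pair, event-free, and at least `min_encounters`
#' encounters. Anything else (including an empty series) is indeterminate and
#' excluded from the endpoint rather than forced to control.
#'
#' @param egfr_series Tibble/data frame with columns `day` and `egfr`
#'   (sorted internally, so input order is immaterial).
#' @param n_encounters Number of outpatient encounters for control
#'   eligibility (defaults to the number of eGFR measurements).
#' @param min_encounters Encounters required of controls (default 2).
#' @param threshold eGFR cutoff, default 60.
#' @param gap_days Minimum day gap between the qualifying pair, default 90.
#' @return `"case"`, `"control"` or `"indeterminate"`.
#' @export
#' @examples
#' call_ckd(data.frame(day = c(0, 120), egfr = c(55, 52)))  # case
call_ckd <- function(egfr_series, n_encounters = NULL, min_encounters = 2,
                     threshold = 60, gap_days = 90) {
  if (is.null(egfr_series) || nrow(egfr_series) == 0) return("indeterminate")
  s <- egfr_series[order(egfr_series$day), , drop = FALSE]
  low_days <- s$day[s$egfr < threshold]
  is_case <- length(low_days) >= 2 &&
    (max(low_days) - min(low_days)) >= gap_days
  if (is_case) return("case")
  n_encounters <- n_encounters %||% nrow(s)
  if (n_encounters >= min_encounters) "control" else "indeterminate"
}

#' Call end-stage kidney disease
#'
#' Case: any chronic-dialysis or kidney-transplant procedure event, or two
#' eGFR values below 15 at least 90 days apart. Control eligibility follows
#' [call_ckd()]: event-free with at least two encounters.
#'
#' @inheritParams call_ckd
#' @param procedure_events Character vector of procedure codes for the person
#'   (e.g. `"dialysis"`, `"transplant"`), or `NULL`.
#' @return `"case"`, `"control"` or `"indeterminate"`.
#' @export
call_eskd <- function(egfr_series, procedure_events = NULL,
                      n_encounters = NULL, min_encounters = 2) {
  if (length(procedure_events) > 0 &&
      any(procedure_events %in% c("dialysis", "transplant"))) {
    return("case")
  }
  call_ckd(egfr_series, n_encounters = n_encounters,
           min_encounters = min_encounters, threshold = 15, gap_days = 90)
}

#' Annualized relative eGFR slope from longitudinal creatinine
#'
#' Fits a linear mixed model of `log(eGFR)` on time in years with a random
#' intercept and random slope per person; the person-level slope is
#' `(fixed slope + BLUP) * 100`, i.e. percent change in eGFR per year.
#' Persons with fewer than two measurements are excluded and reported.
#' If the mixed fit is singular or fails, the function falls back to
#' per-person OLS slopes with a warning, flagged in the output.
#'
#' @param labs Tibble with columns `id`, `day`, and either `egfr` or `scr`.
#' @param demographics Tibble with `id`, `age`, `sex` — required when only
#'   `scr` is supplied so eGFR can be computed at each visit (age advances
#'   with `day`).
#' @return A list with `slopes` (tibble: id, slope_pct_year, n_obs),
#'   `fixed_slope_pct_year`, `slope_sd_pct_year`, `resid_sd`, `method`
#'   (`"lmm"` or `"ols"`), and `excluded` (ids with < 2 measurements).
#' @export
fit_egfr_slope <- function(labs, demographics = NULL) {
  labs <- tibble::as_tibble(labs)
  if (!"egfr" %in% names(labs)) {
    assert_that(!is.null(demographics),
                "demographics needed to derive eGFR from creatinine")
    labs <- dplyr::inner_join(labs, demographics[, c("id", "age", "sex")],
                              by = "id")
    labs$egfr <- ckdepi_egfr(labs$scr, labs$age + labs$day / 365.25, labs$sex)
  }
  counts <- dplyr::count(labs, .data$id)
  excluded <- counts$id[counts$n < 2]
  labs <- labs[!labs$id %in% excluded, , drop = FALSE]
  assert_that(nrow(labs) > 0, "no person has >= 2 measurements")
  labs$years <- labs$day / 365.25
  labs$log_egfr <- log(labs$egfr)

  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(log_egfr ~ years + (years | id), data = labs,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  use_lmm <- !is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)

  if (use_lmm) {
    fe <- unname(lme4::fixef(fit)["years"])
    re <- lme4::ranef(fit)$id
    slopes <- tibble::tibble(
      id = rownames(re),
      slope_pct_year = (fe + re$years) * 100
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    slope_sd <- sqrt(vc$vcov[vc$grp == "id" & vc$var1 == "years" &
                               is.na(vc$var2)]) * 100
    resid_sd <- stats::sigma(fit)
    method <- "lmm"
  } else {
    rlang::warn("mixed model singular or failed; falling back to per-person OLS slopes")
    per <- dplyr::group_by(labs, .data$id)
    per <- dplyr::summarise(
      per,
      slope_pct_year = unname(coef(lm(log_egfr ~ years))[2]) * 100,
      .groups = "drop"
    )
    slopes <- per
    fe <- mean(per$slope_pct_year) / 100
    slope_sd <- sd(per$slope_pct_year)
    resid_sd <- NA_real_
    method <- "ols"
  }
  obs <- dplyr::count(labs, .data$id, name = "n_obs")
  slopes$id <- as.character(slopes$id)
  obs$id <- as.character(obs$id)
  slopes <- dplyr::left_join(slopes, obs, by = "id")
  list(slopes = slopes, fixed_slope_pct_year = fe * 100,
       slope_sd_pct_year = slope_sd, resid_sd = resid_sd, method = method,
       excluded = as.character(excluded))
}

#' Diabetes case definition from codes and prescriptions
#'
#' A person is diabetic iff both conjuncts hold: (1) a single diabetes
#' diagnosis code at a face-to-face primary-care outpatient visit, OR
#' diabetes codes on two or more distinct days; and (2) at least one
#' outpatient prescription of a diabetes drug.
#'
#' @param code_events Tibble with columns `id`, `day`, `code`, and logical
#'   `pcp_visit` (face-to-face PCP outpatient visit flag); rows are diabetes
#'   diagnosis codes only.
#' @param prescriptions Tibble with columns `id`, `drug_class`; rows with
#'   `drug_class == "diabetes"` count.
#' @param ids Character vector of all person ids to report on.
#' @return Tibble `id`, `diabetes` (logical).
#' @export
define_diabetes <- function(code_events, prescriptions, ids) {
  code_events <- tibble::as_tibble(code_events)
  by_id <- dplyr::group_by(code_events, .data$id)
  crit1 <- dplyr::summarise(
    by_id,
    ok = any(.data$pcp_visit) || dplyr::n_distinct(.data$day) >= 2,
    .groups = "drop"
  )
  rx_ids <- unique(prescriptions$id[prescriptions$drug_class == "diabetes"])
  tibble::tibble(
    id = ids,
    diabetes = ids %in% crit1$id[crit1$ok] & ids %in% rx_ids
  )
}

#' Derive the four kidney endpoints for a cohort
#'
#' Applies [ckdepi_egfr()], [call_ckd()], [call_eskd()] and
#' [fit_egfr_slope()] to a cohort's longitudinal labs: baseline eGFR is the
#' first outpatient value after entry; CKD/ESKD use the persistence rules;
#' the slope comes from the mixed model.
#'
#' @param cohort A cohort list as produced by [simulate_cohort()] (fields
#'   `persons`, `labs`, `procedures`).
#' @return A tibble: id, baseline_egfr, egfr_slope, ckd_status, eskd_status.
#' @export
derive_endpoints <- function(cohort) {
  persons <- cohort$persons
  labs <- tibble::as_tibble(cohort$labs)
  labs <- dplyr::inner_join(labs, persons[, c("id", "age", "sex")], by = "id")
  labs$egfr <- ckdepi_egfr(labs$scr, labs$age + labs$day / 365.25, labs$sex)
  labs <- dplyr::arrange(labs, .data$id, .data$day)

  base <- dplyr::summarise(dplyr::group_by(labs, .data$id),
                           baseline_egfr = .data$egfr[1], .groups = "drop")
  procs <- cohort$procedures %||%
    tibble::tibble(id = character(), day = integer(), code = character())
  series_by_id <- split(labs[, c("day", "egfr")], labs$id)
  status <- purrr::map_dfr(persons$id, function(pid) {
    s <- series_by_id[[pid]]
    pe <- procs$code[procs$id == pid]
    tibble::tibble(
      id = pid,
      ckd_status = call_ckd(s),
      eskd_status = call_eskd(s, pe)
    )
  })
  sl <- fit_egfr_slope(labs[, c("id", "day", "egfr")])
  out <- dplyr::left_join(persons[, "id", drop = FALSE], base, by = "id")
  out <- dplyr::left_join(out, status, by = "id")
  out <- dplyr::left_join(out, sl$slopes[, c("id", "slope_pct_year")], by = "id")
  dplyr::rename(out, egfr_slope = "slope_pct_year")
}
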