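new_mr_result <- function(protein_id, outcome_name, method, beta, se, n_snp,
                          cochran_Q = NA_real_, Q_pvalue = NA_real_,
                          egger_intercept = NA_real_,
                          egger_intercept_p = NA_real_) {
  structure(list(
    protein_id = protein_id, outcome_name = outcome_name, method = method,
    beta = beta, se = se, pvalue = wald_p(beta, se), n_snp = as.integer(n_snp),
    cochran_Q = cochran_Q, Q_pvalue = Q_pvalue,
    egger_intercept = egger_intercept, egger_intercept_p = egger_intercept_p
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): %s -> %s\n  beta = %.4g, se = %.4g, p = %.3g, n_snp = %d\n",
              x$method, x$protein_id, x$outcome_name, x$beta, x$se, x$pvalue,
              x$n_snp))
  invisible(x)
}

#' Tidy / summarize an MR result
#'
#' `tidy()` returns the estimate rows; `glance()` returns one row with the
#' estimate plus instrument diagnostics (Cochran's Q, Egger intercept).
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(
    protein_id = x$protein_id, outcome_name = x$outcome_name,
    method = x$method, estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se, p.value = x$pvalue, n_snp = x$n_snp
  )
}

#' @rdname tidy.mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    protein_id = x$protein_id, outcome_name = x$outcome_name,
    method = x$method, estimate = x$beta, std.error = x$se,
    p.value = x$pvalue, n_snp = x$n_snp, cochran_Q = x$cochran_Q,
    Q_pvalue = x$Q_pvalue, egger_intercept = x$egger_intercept,
    egger_intercept_p = x$egger_intercept_p
  )
}

#' Wald-ratio MR estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`, with the first-order delta-method standard
#' error `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param beta_exp,se_exp Exposure effect and SE.
#' @param beta_out,se_out Outcome effect and SE.
#' @param protein_id,outcome_name Labels.
#' @return An `mr_result`.
#' @export
#' @examples
#' wald_ratio(0.5, 0.05, 0.1, 0.02)  # beta 0.2, se 0.04
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       protein_id = "protein", outcome_name = "outcome") {
  assert_that(beta_exp != 0, "Wald ratio undefined for beta_exp = 0; pair skipped")
  new_mr_result(protein_id, outcome_name, "wald",
                beta = beta_out / beta_exp, se = se_out / abs(beta_exp),
                n_snp = 1L)
}

# Cochran's Q with ratio weights w_j = beta_exp_j^2 / se_out_j^2, equal to
# the weighted RSS of the origin-constrained IVW fit
compute_q <- function(bx, by, so, beta_ivw) {
  w <- bx^2 / so^2
  sum(w * (by / bx - beta_ivw)^2)
}

#' Multiplicative random-effects IVW MR estimate
#'
#' Weighted least squares of outcome effects on exposure effects through the
#' origin with weights `1/se_out^2`; under heterogeneity the standard error
#' is inflated by `sqrt(max(1, Q/(k-1)))` (floored at the fixed-effect SE).
#' With fewer than two instruments the call defers to [wald_ratio()].
#'
#' @param instruments An `instrument_set` (or tibble with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`).
#' @param protein_id,outcome_name Labels (default from the instrument set's
#'   attributes when present).
#' @return An `mr_result` with `cochran_Q` and `Q_pvalue` filled in when
#'   `n_snp >= 2`.
#' @export
ivw_mre <- function(instruments,
                    protein_id = attr(instruments, "exposure_name") %||% "protein",
                    outcome_name = attr(instruments, "outcome_name") %||% "outcome") {
  k <- nrow(instruments)
  assert_that(k >= 1, "no instruments")
  if (k < 2) {
    return(wald_ratio(instruments$beta_exp, instruments$se_exp,
                      instruments$beta_out, instruments$se_out,
                      protein_id, outcome_name))
  }
  bx <- instruments$beta_exp; by <- instruments$beta_out
  so <- instruments$se_out
  w <- 1 / so^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- compute_q(bx, by, so, beta)
  phi <- max(1, Q / (k - 1))
  new_mr_result(protein_id, outcome_name, "ivw_mre",
                beta = beta, se = se_fixed * sqrt(phi), n_snp = k,
                cochran_Q = Q,
                Q_pvalue = pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' intercept (weights `1/se_out^2`), all exposure effects oriented positive
#' first. The intercept tests directional pleiotropy; its SE uses a residual
#' variance floored at 1 (the multiplicative random-effects convention).
#' Requires at least three instruments; otherwise the diagnostic is flagged
#' undefined.
#'
#' @inheritParams ivw_mre
#' @return A list: `intercept`, `intercept_se`, `intercept_p`, `slope`,
#'   `slope_se`, `slope_p`, `n_snp`, `defined`.
#' @export
egger <- function(instruments,
                  protein_id = attr(instruments, "exposure_name") %||% "protein",
                  outcome_name = attr(instruments, "outcome_name") %||% "outcome") {
  k <- nrow(instruments)
  if (k < 3) {
    return(list(intercept = NA_real_, intercept_se = NA_real_,
                intercept_p = NA_real_, slope = NA_real_, slope_se = NA_real_,
                slope_p = NA_real_, n_snp = k, defined = FALSE))
  }
  flip <- sign(instruments$beta_exp)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exp * flip
  by <- instruments$beta_out * flip
  w <- 1 / instruments$se_out^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * sqrt(w))
  coefs <- solve(XtWX, crossprod(X * w, by))
  resid <- by - X %*% coefs
  sigma2 <- max(1, sum(w * resid^2) / (k - 2))
  covb <- solve(XtWX) * sigma2
  se <- sqrt(diag(covb))
  list(intercept = coefs[1], intercept_se = se[1],
       intercept_p = wald_p(coefs[1], se[1]),
       slope = coefs[2], slope_se = se[2], slope_p = wald_p(coefs[2], se[2]),
       n_snp = k, defined = TRUE)
}

#' Cochran's Q heterogeneity test across instruments
#'
#' Q is the IVW weighted residual sum of squares of the per-SNP Wald ratios
#' about the IVW estimate; p from chi-square with k-1 degrees of freedom.
#' Instruments failing this test are flagged by callers, not removed.
#'
#' @inheritParams ivw_mre
#' @return A list: `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(instruments) {
  k <- nrow(instruments)
  assert_that(k >= 2, "Cochran's Q needs >= 2 instruments")
  fit <- ivw_mre(instruments)
  list(Q = fit$cochran_Q, df = k - 1L, pvalue = fit$Q_pvalue)
}

#' Heterogeneity z-test between two subgroup MR estimates
#'
#' `z = (beta1 - beta2) / sqrt(se1^2 + se2^2)` with a two-sided normal
#' p-value; used to compare diabetes vs non-diabetes subgroup estimates for
#' the same protein-outcome pair.
#'
#' @param result_a,result_b `mr_result`s for disjoint strata.
#' @return A list: `z`, `pvalue`.
#' @export
#' @examples
#' a <- wald_ratio(1, 0.1, 0.3, 0.05)
#' b <- wald_ratio(1, 0.1, 0.0, 0.05)
#' heterogeneity_z(a, b)$z  # ~4.24
heterogeneity_z <- function(result_a, result_b) {
  z <- (result_a$beta - result_b$beta) / sqrt(result_a$se^2 + result_b$se^2)
  list(z = z, pvalue = 2 * pnorm(-abs(z)))
}

#' Run the MR estimator the instrument count dictates
#'
#' IVW (multiplicative random effects) when two or more instruments are
#' available, otherwise the Wald ratio; attaches Egger diagnostics when
#' defined.
#'
#' @inheritParams ivw_mre
#' @return An `mr_result` (Egger fields filled when `n_snp >= 3`).
#' @export
run_mr <- function(instruments,
                   protein_id = attr(instruments, "exposure_name") %||% "protein",
                   outcome_name = attr(instruments, "outcome_name") %||% "outcome") {
  res <- ivw_mre(instruments, protein_id, outcome_name)
  if (nrow(instruments) >= 3) {
    eg <- egger(instruments, protein_id, outcome_name)
    res$egger_intercept <- eg$intercept
    res$egger_intercept_p <- eg$intercept_p
  }
  res
}
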