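#' Construct a summary-statistics table
#'
#' A `sumstats` object is a tibble with one row per variant (columns
#' `variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#' pvalue`) plus trait metadata held in attributes: `trait_name`,
#' `trait_type` (`"quantitative"` or `"binary"`), `n`, and for binary traits
#' `n_case`/`n_control`.
#'
#' @param records Tibble of per-variant records.
#' @param trait_name Trait label.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n Total sample size.
#' @param n_case,n_control Case/control counts (binary traits).
#' @return A tibble of class `sumstats`.
#' @export
new_sumstats <- function(records, trait_name, trait_type = c("quantitative", "binary"),
                         n, n_case = NA_integer_, n_control = NA_integer_) {
  trait_type <- match.arg(trait_type)
  needed <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pvalue")
  assert_that(all(needed %in% names(records)),
              paste("summary statistics need columns:", paste(needed, collapse = ", ")))
  assert_that(!anyDuplicated(records$variant_id),
              "one record per variant: duplicated variant_id")
  out <- tibble::as_tibble(records)
  attr(out, "trait_name") <- trait_name
  attr(out, "trait_type") <- trait_type
  attr(out, "n") <- n
  attr(out, "n_case") <- n_case
  attr(out, "n_control") <- n_control
  class(out) <- c("sumstats", class(out))
  out
}

sumstats_meta <- function(x) {
  list(trait_name = attr(x, "trait_name"), trait_type = attr(x, "trait_type"),
       n = attr(x, "n"), n_case = attr(x, "n_case"),
       n_control = attr(x, "n_control"))
}

# drop covariate columns that are collinear (rank-deficient design), with a
# warning naming them; returns the full-rank design matrix including intercept
full_rank_design <- function(covariates, n) {
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    rlang::warn(paste("dropping collinear covariates:",
                      paste(dropped, collapse = ", ")))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Per-variant linear-regression scan of a quantitative trait
#'
#' Fits, for every variant, an ordinary least-squares regression of the trait
#' on genotype dosage plus covariates, and reports the dosage term's
#' beta/SE/two-sided Wald p. Implemented by residualizing trait and dosages on
#' the covariates (Frisch-Waugh), which is exact OLS. Complete cases only;
#' collinear covariates are dropped with a warning. Variants whose residual
#' dosage variance is zero (monomorphic) or whose trait is degenerate get
#' beta 0, se NA, and a `degenerate` flag.
#'
#' @param trait Numeric response vector.
#' @param dosages n x m dosage matrix.
#' @param covariates Data frame / matrix of covariates (or `NULL`).
#' @param variants Variant metadata tibble as from [simulate_genotypes()];
#'   if `NULL`, minimal metadata is fabricated from column indices.
#' @param trait_name Label stored in the result.
#' @return A `sumstats` tibble with an extra logical `degenerate` column.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 300, n_variants_region = 5, seed = 2)
#' g <- simulate_genotypes(cfg)
#' y <- rnorm(300)
#' scan_quantitative(y, g$dosages, NULL, g$variants)
scan_quantitative <- function(trait, dosages, covariates = NULL,
                              variants = NULL, trait_name = "trait") {
  dosages <- as.matrix(dosages)
  cc <- complete.cases(trait, if (is.null(covariates)) rep(0, length(trait)) else covariates)
  trait <- trait[cc]
  dosages <- dosages[cc, , drop = FALSE]
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)[cc, , drop = FALSE]
  n <- length(trait)
  X <- full_rank_design(covariates, n)
  p <- ncol(X)
  # residualize trait and every dosage column on the covariate design
  qr_x <- qr(X)
  ry <- qr.resid(qr_x, trait)
  rg <- qr.resid(qr_x, dosages)

  gg <- unname(colSums(rg^2))
  gy <- unname(colSums(rg * ry))
  yy <- sum(ry^2)
  degenerate <- gg < 1e-12 | yy < 1e-12
  beta <- ifelse(degenerate, 0, gy / gg)
  df <- n - p - 1
  sigma2 <- pmax(0, (yy - beta^2 * gg) / df)
  se <- ifelse(degenerate, NA_real_, sqrt(sigma2 / gg))
  pv <- ifelse(degenerate, NA_real_, wald_p(beta, se))

  variants <- variants %||% tibble::tibble(
    variant_id = paste0("v", seq_len(ncol(dosages))), chrom = "1",
    pos = seq_len(ncol(dosages)), effect_allele = "A", other_allele = "G",
    maf = NA_real_, eaf = unname(colMeans(dosages)) / 2
  )
  new_sumstats(
    dplyr::mutate(
      dplyr::select(variants, "variant_id", "chrom", "pos", "effect_allele",
                    "other_allele"),
      eaf = unname(colMeans(dosages)) / 2, beta = beta, se = se, pvalue = pv,
      degenerate = degenerate
    ),
    trait_name = trait_name, trait_type = "quantitative", n = n
  )
}

#' Per-variant logistic-regression scan of a binary trait
#'
#' Fits an additive logistic regression of case status on dosage plus
#' covariates for each variant; beta is the log-odds per effect allele.
#' Variants with (quasi-)separation are flagged (`degenerate = TRUE`, missing
#' beta) and should be excluded downstream.
#'
#' @param case_status 0/1 (or logical) response; both classes must be present.
#' @inheritParams scan_quantitative
#' @return A `sumstats` tibble with a `degenerate` flag column.
#' @export
scan_binary <- function(case_status, dosages, covariates = NULL,
                        variants = NULL, trait_name = "trait") {
  y <- as.integer(case_status)
  assert_that(all(y %in% 0:1), "`case_status` must be 0/1")
  assert_that(length(unique(y)) == 2,
              "both cases and controls are required for a logistic scan")
  dosages <- as.matrix(dosages)
  cc <- complete.cases(y, if (is.null(covariates)) rep(0, length(y)) else covariates)
  y <- y[cc]
  dosages <- dosages[cc, , drop = FALSE]
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)[cc, , drop = FALSE]
  n <- length(y)
  X <- full_rank_design(covariates, n)

  fit_one <- function(g) {
    Xg <- cbind(X, dosage = g)
    fit <- suppressWarnings(stats::glm.fit(Xg, y, family = stats::binomial()))
    k <- ncol(Xg)
    est <- fit$coefficients[k]
    # Fisher information from the final IRLS weights
    w <- fit$weights
    cov_try <- tryCatch(solve(crossprod(Xg * sqrt(w))), error = function(e) NULL)
    se <- if (is.null(cov_try)) NA_real_ else sqrt(cov_try[k, k])
    sep <- !fit$converged || is.na(est) || abs(est) > 15 ||
      is.na(se) || se > 100
    c(beta = if (sep) NA_real_ else unname(est),
      se = if (sep) NA_real_ else se, sep = as.numeric(sep))
  }
  res <- vapply(seq_len(ncol(dosages)), function(j) fit_one(dosages[, j]),
                c(beta = 0, se = 0, sep = 0))
  beta <- unname(res["beta", ])
  se <- unname(res["se", ])
  degenerate <- unname(res["sep", ]) > 0

  variants <- variants %||% tibble::tibble(
    variant_id = paste0("v", seq_len(ncol(dosages))), chrom = "1",
    pos = seq_len(ncol(dosages)), effect_allele = "A", other_allele = "G",
    maf = NA_real_, eaf = unname(colMeans(dosages)) / 2
  )
  new_sumstats(
    dplyr::mutate(
      dplyr::select(variants, "variant_id", "chrom", "pos", "effect_allele",
                    "other_allele"),
      eaf = unname(colMeans(dosages)) / 2, beta = beta, se = se,
      pvalue = ifelse(degenerate, NA_real_, wald_p(beta, se)),
      degenerate = degenerate
    ),
    trait_name = trait_name, trait_type = "binary", n = n,
    n_case = sum(y), n_control = sum(1 - y)
  )
}

#' Stratified association scans
#'
#' Runs independent scans of the same trait restricted to each level of a
#' stratifying factor (e.g. diabetes status), as used for effect-modification
#' analysis. Refuses empty or undersized strata.
#'
#' @param trait Response vector (quantitative or 0/1 depending on `type`).
#' @param dosages Dosage matrix.
#' @param covariates Covariates or `NULL`.
#' @param stratum Factor/logical/char vector defining strata.
#' @param type `"quantitative"` or `"binary"`.
#' @param min_stratum_size Minimum persons per stratum (default 50).
#' @inheritParams scan_quantitative
#' @return Named list of `sumstats`, one per stratum level.
#' @export
stratified_scan <- function(trait, dosages, covariates = NULL, stratum,
                            type = c("quantitative", "binary"),
                            variants = NULL, trait_name = "trait",
                            min_stratum_size = 50) {
  type <- match.arg(type)
  stratum <- as.factor(stratum)
  assert_that(nlevels(droplevels(stratum)) >= 2, "need at least two non-empty strata")
  sizes <- table(stratum)
  if (any(sizes < min_stratum_size)) {
    rlang::abort(paste0("stratum below minimum size (", min_stratum_size, "): ",
                        paste(names(sizes)[sizes < min_stratum_size], collapse = ", ")))
  }
  scan_fun <- if (type == "quantitative") scan_quantitative else scan_binary
  lapply(stats::setNames(levels(stratum), levels(stratum)), function(lv) {
    idx <- stratum == lv
    scan_fun(trait[idx], dosages[idx, , drop = FALSE],
             if (!is.null(covariates)) as.data.frame(covariates)[idx, , drop = FALSE],
             variants, trait_name = paste0(trait_name, "[", lv, "]"))
  })
}

#' Write / read summary statistics as tab-delimited text
#'
#' Trait metadata travel in `#key=value` comment lines before the header; the
#' reader matches columns by name, so column order is immaterial.
#'
#' @param x A `sumstats` object.
#' @param path Output/input file path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats` returns
#'   a `sumstats` tibble.
#' @export
write_sumstats <- function(x, path) {
  meta <- sumstats_meta(x)
  hdr <- paste0("#", names(meta), "=", vapply(meta, as.character, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  lines <- readLines(path, n = 20)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$chrom <- as.character(tab$chrom)
  new_sumstats(
    tibble::as_tibble(tab),
    trait_name = meta$trait_name,
    trait_type = meta$trait_type,
    n = as.numeric(meta$n),
    n_case = suppressWarnings(as.integer(meta$n_case)),
    n_control = suppressWarnings(as.integer(meta$n_control))
  )
}
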