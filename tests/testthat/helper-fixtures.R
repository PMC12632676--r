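# shared builders for small deterministic fixtures

# expected eGFR values computed independently from the published 2021
# CKD-EPI creatinine equation
ckdepi_grid <- list(
  list(scr = 0.5, age = 30, sex = "male", egfr = 140.7182460142),
  list(scr = 0.7, age = 45, sex = "male", egfr = 115.7989529616),
  list(scr = 0.9, age = 50, sex = "male", egfr = 104.0490129932),
  list(scr = 1.0, age = 60, sex = "male", egfr = 86.1626207797),
  list(scr = 1.2, age = 65, sex = "male", egfr = 67.1114105720),
  list(scr = 1.5, age = 70, sex = "male", egfr = 49.7736298205),
  list(scr = 2.0, age = 75, sex = "male", egfr = 34.1639275045),
  list(scr = 3.0, age = 80, sex = "male", egfr = 20.3588500104),
  list(scr = 0.8, age = 40, sex = "male", egfr = 114.7350482313),
  list(scr = 1.1, age = 55, sex = "male", egfr = 79.2780055987),
  list(scr = 0.5, age = 30, sex = "female", egfr = 129.3169597507),
  list(scr = 0.7, age = 45, sex = "female", egfr = 108.6234307336),
  list(scr = 0.9, age = 50, sex = "female", egfr = 77.8834379584),
  list(scr = 1.0, age = 60, sex = "female", egfr = 64.4950003539),
  list(scr = 1.2, age = 65, sex = "female", egfr = 50.2346656756),
  list(scr = 1.5, age = 70, sex = "female", egfr = 37.2568782593),
  list(scr = 2.0, age = 75, sex = "female", egfr = 25.5726032537),
  list(scr = 3.0, age = 80, sex = "female", egfr = 15.2391376532),
  list(scr = 0.8, age = 40, sex = "female", egfr = 95.4636899041),
  list(scr = 1.1, age = 55, sex = "female", egfr = 59.3416838170)
)

make_sumstats <- function(beta, se, pos = seq_along(beta) * 1000 + 1e6,
                          ea = rep("A", length(beta)),
                          oa = rep("G", length(beta)),
                          eaf = rep(0.3, length(beta)),
                          chrom = "1", trait_name = "trait",
                          trait_type = "quantitative", n = 10000,
                          variant_id = paste0(chrom, ":", as.integer(pos))) {
  new_sumstats(
    tibble::tibble(variant_id = variant_id, chrom = chrom,
                   pos = as.integer(pos), effect_allele = ea,
                   other_allele = oa, eaf = eaf, beta = beta, se = se,
                   pvalue = 2 * pnorm(-abs(beta / se))),
    trait_name = trait_name, trait_type = trait_type, n = n
  )
}

make_instruments <- function(beta_exp, se_exp, beta_out, se_out) {
  structure(
    tibble::tibble(
      variant_id = paste0("v", seq_along(beta_exp)),
      beta_exp = beta_exp, se_exp = se_exp,
      beta_out = beta_out, se_out = se_out,
      eaf = 0.3, proxy_used = FALSE
    ),
    class = c("instrument_set", class(tibble::tibble()))
  )
}

# simulate a two-sample MR experiment: independent exposure and outcome
# cohorts genotyped at the same independent instruments, true causal effect
# `theta` of exposure on outcome
simulate_two_sample <- function(n = 50000, k = 10, theta = 0.25,
                                beta_g = 0.15, maf = 0.3, seed = 1) {
  set.seed(seed)
  draw <- function() matrix(rbinom(n * k, 2, maf), n, k)
  g1 <- draw()
  x1 <- drop(g1 %*% rep(beta_g, k)) + rnorm(n)
  exp_ss <- scan_quantitative(x1, g1)
  g2 <- draw()
  x2 <- drop(g2 %*% rep(beta_g, k)) + rnorm(n)
  y2 <- theta * x2 + rnorm(n)
  out_ss <- scan_quantitative(y2, g2)
  make_instruments(exp_ss$beta, exp_ss$se, out_ss$beta, out_ss$se)
}
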