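# nephromr

Proteome-to-phenome Mendelian randomization (MR) screening for kidney
disease, as a tested, reusable R pipeline.

## The problem

Circulating proteins are attractive drug targets for chronic kidney disease
(CKD), but observational protein–kidney associations are confounded.
`nephromr` implements a causal screen that treats cis protein quantitative
trait loci (cis-pQTLs — variants near a gene's transcription start site that
shift its circulating protein level) as genetic instruments, and asks, for
each protein, whether genetically proxied protein levels move a battery of
kidney endpoints:

- **baseline eGFR** — estimated glomerular filtration rate from serum
  creatinine via the race-free 2021 CKD-EPI equation,
- **annualized eGFR slope** — percent change per year from a linear mixed
  model of log(eGFR) with random intercepts and slopes,
- **incident CKD** — two eGFR values < 60 mL/min/1.73 m² at least 90 days
  apart,
- **ESKD** — dialysis, transplant, or two eGFR values < 15 at least 90 days
  apart.

For a protein with instruments `(β̂_xj, β̂_yj)` (per-allele effects on
protein and outcome), the single-instrument estimate is the Wald ratio
`β̂ = β̂_y/β̂_x` with SE `se_y/|β̂_x|`; with k ≥ 2 instruments the
multiplicative random-effects IVW estimate is the origin-constrained WLS

```
β̂_IVW = Σ w_j β̂_xj β̂_yj / Σ w_j β̂_xj²,   w_j = 1/se_yj²,
se inflated by √max(1, Q/(k−1)),  Q = Cochran's heterogeneity statistic
```

with the MR-Egger intercept as a directional-pleiotropy diagnostic. The four
correlated endpoint p-values are combined per protein with the Aggregated
Cauchy Association Test (ACAT), `T = Σ w_i tan((0.5−p_i)π)`,
`p = 0.5 − arctan(T)/π`, which is valid under dependence. Proteins passing a
per-dataset Bonferroni threshold are then gated by: directional consistency
across endpoints (at p < 0.0125 = 0.05/4), Bayesian colocalization of the
cis region with the kidney signal via Wakefield approximate Bayes factors
(pass: PP4 > 0.8, priors p1 = p2 = 1e-4, p12 = 1e-5), and replication by
ACAT in an independent cohort. Survivors are profiled phenome-wide
(phecode PheWAS, ≥2-code cases, <200-count exclusion) and classified from
kidney-specific to pleiotropic, then overlaid on protein–protein-interaction
and drug–target tables (first-shell interactors at confidence ≥ 0.9) to
build drug–protein–phenotype evidence networks.

Because the individual-level biobank data behind such screens are
access-restricted, `nephromr` ships a first-class synthetic-cohort module
with known causal architecture (cis effect → protein → latent kidney damage
→ endpoints, plus confounding and LD), so every stage is testable against
ground truth.

## Worked example

```r
library(nephromr)
res <- run_pipeline(run_config(scenario = "causal", seed = 1))
res$verdicts[, c("protein_id", "acat_p", "direction", "pp4", "replicated", "passes_all")]
#>   protein_id   acat_p   direction    pp4 replicated passes_all
#> 1      PROT1 1.59e-11 detrimental 0.9999       TRUE       TRUE
#> 2      PROT2 6.35e-01 indeterminate 0.0225       NA      FALSE
#> 3      PROT3 1.42e-02  protective 0.3719         NA      FALSE
res$report
#>                   gate n
#> 1    proteins_screened 3
#> 2          significant 2
#> 3 consistent_direction 2
#> 4          colocalized 1
#> 5           replicated 1
#> 6           passes_all 1
```

PROT1 carries the planted causal architecture: its ACAT p-value survives
the Bonferroni gate, all four endpoint effects point the same (detrimental)
way — lower eGFR, faster decline, higher CKD/ESKD risk —

```r
res$mr_table[res$mr_table$protein_id == "PROT1", c("endpoint", "beta", "se", "pvalue")]
#>   endpoint   beta     se   pvalue
#> 1     egfr -0.241 0.0433 2.62e-08
#> 2    slope -0.300 0.0432 3.98e-12
#> 3      ckd  0.531 0.0893 2.74e-09
#> 4     eskd  0.458 0.1730 8.07e-03
```

its cis region colocalizes with the eGFR signal (PP4 = 0.9999 > 0.8), and it
replicates in an independently simulated cohort — so it alone passes every
gate. The two null proteins are stopped at the colocalization/replication
gates even when one reaches nominal significance by chance. In this run the
PheWAS profile of PROT1 lands in the `no_hits` tier, which the screen keeps
distinct from kidney specificity: absent phenome-wide hits may simply
reflect small per-variant effects.

Scenario presets: `"null"`, `"causal"`, `"coloc-shared"`,
`"coloc-distinct"`. A shell entry point with the same surface lives at
`inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --scenario causal --seed 1 --out out_dir`).

Lower-level functions are exported individually —
`ckdepi_egfr()`, `call_ckd()`, `call_eskd()`, `fit_egfr_slope()`,
`scan_quantitative()`/`scan_binary()`, `select_cis_pqtls()`,
`clump_instruments()`, `harmonize()`, `wald_ratio()`, `ivw_mre()`,
`egger()`, `cochran_q()`, `heterogeneity_z()`, `acat()`, `colocalize()`,
`run_phewas()`, `classify_pleiotropy()`, `classify_druggability()`,
`build_network()` — and MR fits support `tidy()`/`glance()`; result types
have `autoplot()`/`plot_*()` methods.

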