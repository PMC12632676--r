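---
title: "Methods: proteome-to-phenome MR screening for kidney disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-to-phenome MR screening for kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nephromr` implements a sequential causal screen of circulating proteins
against kidney outcomes: synthetic cohort → endpoint phenotyping →
per-variant association scans → cis-instrument selection and harmonization →
two-sample MR → ACAT aggregation and sensitivity gates → colocalization →
replication → phenome-wide pleiotropy → druggability networks. This vignette
records the models, the assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

## The synthetic cohort: what it emulates and what it does not

No individual-level kidney-biobank data are distributable, so the generator
(`sim_config()`, `simulate_cohort()`) plants a known causal architecture:

- **Genotypes.** Two haplotypes per person are drawn from a latent
  multivariate normal with AR(1) correlation `exp(-ld_decay * d)` (`d` in
  inter-variant spacing units) and thresholded at each variant's MAF, giving
  Hardy-Weinberg sampling per variant and controllable, monotonically
  decaying LD. `ld_decay = 0` is the documented "LD disabled" setting
  (independent variants); for `ld_decay > 0` the latent correlation follows
  the AR(1) form, so the parameter is a decay rate with a deliberate
  discontinuity at zero. Thresholding attenuates dosage correlation below
  the latent correlation; tests therefore calibrate against realized dosage
  LD, not the latent matrix.
- **Protein and damage.** `protein = causal_protein_effect * G_causal +
  confounder + N(0,1)`. The latent kidney-damage score is
  `protein_outcome_effect * protein + confounder_effect * confounder +
  N(0,1)` under the shared-causal architecture; under the distinct-causal
  architecture the damage score instead takes a direct per-allele effect
  (magnitude `causal_protein_effect * protein_outcome_effect`, so the two
  architectures have comparable signal) from a variant at the far end of the
  region and nothing through the protein. A single standard-normal
  confounder is enough to bias naive observational estimates while leaving
  the genetic instruments valid.
- **Trajectories.** Each person's eGFR declines log-linearly at a true slope
  drawn from `N(slope_mean + damage_slope_effect * damage, slope_sd)` %/yr,
  from a baseline shifted by `damage_egfr_effect * damage` on the log scale.
  eGFR is inverted through the CKD-EPI equation to serum creatinine
  (the equation is strictly decreasing in creatinine, so the inverse is
  closed-form and exact), then multiplicative lognormal measurement noise
  with CV `scr_cv` is added. The creatinine noise magnitude is a free
  parameter with no published anchor; the default CV is 0.05.
- **ESKD events.** Laboratory-confirmed eGFR < 15 is vanishingly rare at
  desk-scale n, so dialysis/transplant procedure events are generated from a
  logistic link on the damage score (`plogis(-4 + 0.9 * damage)`), keeping
  both outcome classes populated for the logistic scans. This is a generator
  choice, not an epidemiological claim.
- **Scenario presets.** `"null"` keeps a real cis effect on the protein but
  no protein→outcome path; `"causal"`/`"coloc-shared"` use
  `causal_protein_effect = 0.6`, `protein_outcome_effect = 0.8`, chosen so
  the planted protein passes every gate with high power at the default
  n = 3,000 (the positive control is meant to be a power > 0.95 control, and
  the colocalization gate is the binding constraint); `"coloc-distinct"`
  moves the outcome signal to a different variant.

What the generator does **not** emulate: realistic human LD maps,
relatedness, imputation uncertainty, ancestry structure beyond pure-noise
PCs, platform/assay effects, informative visit schedules, or ICD coding
noise. Passing tests demonstrate internal correctness and calibration of
the statistical machinery under this architecture — not performance on real
biobank data.

## Phenotyping

`ckdepi_egfr()` is the race-free 2021 CKD-EPI creatinine equation; it is
continuous at the sex-specific knot `scr = kappa` and strictly decreasing in
creatinine (both test-pinned). `call_ckd()`/`call_eskd()` implement the
persistence rules — two values below threshold (60 / 15) at least 90 days
apart, or a dialysis/transplant event for ESKD — with the day gap inclusive
at exactly 90. Controls must be event-free with at least two encounters;
persons qualifying as neither case nor eligible control are *excluded* from
that endpoint, never forced to control. Records are sorted internally, so
case calling is permutation-invariant.

The annualized relative eGFR slope is the slope of `log(eGFR)` on time in
years, times 100 (%/year) — the standard relative-decline measure; the
per-person slope is the fixed slope plus the BLUP from
`lme4::lmer(log_egfr ~ years + (years | id))`. If the mixed fit is singular
or fails (e.g. the degenerate zero-variance case), the function falls back
to per-person OLS slopes with a warning and flags the method in its output;
in the noise-free common-decline case this reproduces the true slope
exactly. Baseline eGFR is the first outpatient value after entry. The
diabetes covariate requires both a qualifying code pattern (one PCP-visit
code, or codes on two distinct days) and a diabetes prescription;
"face-to-face PCP visit" is modeled as a per-event flag in synthetic data.

## Association scans

`scan_quantitative()` residualizes trait and dosages on the covariate design
(Frisch-Waugh), which is exact OLS for the dosage term; `scan_binary()` fits
per-variant additive logistic regressions with SEs from the final IRLS
Fisher information, flagging separation. p-values are two-sided normal on
`beta/se` throughout, so every stored p reproduces from its beta and SE.
Endpoint GWAS adjust for age, sex and 10 PCs; PheWAS uses 5 PCs by default
(`phewas_pc_count`) — both counts appear in the source methodology and both
are honored as configuration. Quantitative endpoint traits are standardized
before scanning so downstream effect-size priors (colocalization) are on
the trait-SD scale. Mixed-model GWAS machinery for relatedness is
deliberately replaced by plain covariate-adjusted regression: the synthetic
cohorts contain no relatedness.

## Instruments

Cis candidates lie within ±500 kb of the TSS (inclusive bounds, 1-based
coordinates) with MAF strictly greater than 1%. Instruments are then
selected by greedy p-value-ordered clumping at r² < `r2_clump` (default 0.1)
against the dosage LD reference, with genome-wide relevance
`p < 5e-8` (`p_instrument`) — the field-standard instrument threshold. The
LD reference must carry variant ids; unnamed matrices are refused rather
than silently treated as LD-free. Harmonization matches by variant id,
negates the outcome beta for swapped alleles, resolves palindromic (A/T,
C/G) variants by allele frequency only when both sides are away from 0.5
(margin 0.08), substitutes proxies at r² ≥ 0.9 with MAF difference ≤ 0.02,
and drops everything else; the retained/flipped/proxied/dropped accounting
is attached to the result and always sums to the input count.
Multi-assay proteins are analyzed per assay and reported per assay — there
is no silent merging rule.

## MR estimators

Wald ratio for one instrument (first-order delta SE `se_y/|beta_x|`); for
k ≥ 2, origin-constrained WLS with weights `1/se_y²` and multiplicative
random effects: the SE is inflated by `sqrt(max(1, Q/(k-1)))` and never
shrunk below the fixed-effect SE — the conservative convention, test-pinned.
Cochran's Q uses ratio weights `beta_x²/se_y²` (equal to the weighted RSS of
the IVW fit). MR-Egger orients all exposure effects positive, regresses with
an intercept under the same weights, and floors the residual variance at 1;
it needs ≥ 3 instruments and is otherwise flagged undefined. Instruments
failing Q or Egger are *flagged, never removed*. All estimator p-values are
normal, not t — at the instrument counts simulated the difference is
negligible, and the choice is pinned in tests. Subgroup effect modification
uses `z = (b1 - b2)/sqrt(se1² + se2²)`; the diabetes screen threshold is
0.05/93.

## Aggregation and gates

ACAT combines the four endpoint p-values with equal weights, clipping inputs
to `[1e-15, 1 - 1e-15]` to keep the tangent finite (oracle-checked against
linear-space enumeration). ACAT is exactly nominal for independent inputs;
under dependence it is only asymptotically exact as alpha → 0, and at
alpha = 0.05 with endpoint correlation 0.5 its true size is slightly above
nominal — the test suite therefore asserts the strict Monte-Carlo band for
the independent case and a 0.05 ± 0.015 dependence-robustness band for the
correlated case. Significance uses `0.05/n` with n the proteins tested in
the dataset. Direction classification orients each endpoint onto the
kidney-benefit axis (eGFR +, slope +, CKD −, ESKD −) and requires all
endpoint effects significant at 0.0125 to agree; the 0.0125 filter is
applied uniformly. Replication ACAT-combines the external-endpoint MR
p-values (cross-sectional eGFR, CKD, CKDi25 and Rapid3 analogs in the
replication cohort) at `0.05/n_attempted`. `passes_all` is the conjunction:
significant ∧ uniform direction ∧ PP4 > 0.8 ∧ replicated.

## Colocalization

Per-SNP Wakefield log-ABFs, `0.5 * (log(V/(V+W)) + z² W/(V+W))`, with prior
effect SD 0.15 for quantitative and 0.2 for binary traits (the canonical
defaults; configurable). Hypothesis sums use priors p1 = p2 = 1e-4,
p12 = 1e-5 (the duplicated "p1" in the printed priors is read as p2), with
all sums in log space (log-sum-exp); the H3 cross term is computed as
`S1*S2 - diag` via `log1p(-exp(.))`, which is exactly zero for a single-SNP
region. Posterior probabilities sum to one to 1e-9 and match a brute-force
linear-space oracle on small regions. Regions are sentinel ± 500 kb.

## PheWAS and pleiotropy

Cases need ≥ 2 phecode-mapped codes, controls none; single-code persons are
excluded, and phecodes with fewer than 200 cases or controls are dropped
with reason (`min_count`, configurable). The Bonferroni denominator is the
loaded catalog size — the synthetic catalog defaults to 1,020 phecodes over
11 domains plus a curated 12th kidney domain; 931 is an equally valid
catalog size and is reachable through configuration. A protein's profile is
the union of significant hits across its independent cis instruments; tiers
run `kidney_only` → `kidney_plus_k` → `extra_renal_only`, with `no_hits`
kept distinct from kidney specificity because absent hits may only reflect
small per-variant effects.

## Druggability and networks

`direct` if any drug targets the protein; `secondary` if any first-shell
interactor with confidence ≥ `score_min` (default 0.9; 0.80 is the
documented alternative and both are supported, the discrepancy is left
unresolved) is a drug target; monotone in the threshold by construction.
The evidence network is a typed igraph (drug / protein / kidney outcome /
phecode nodes; targets / interacts / mr_association / phewas_association
edges) exported as node/edge TSV plus GraphML, with unique drug, target and
pair counts as graph attributes. Drug-target and PPI inputs are synthetic
fixture tables shaped like ChEMBL/STRING extracts; there are no live
queries.

## Pipeline, sizes and determinism

`run_pipeline()` executes the stages in order and returns verdicts, MR and
coloc tables, replication, diabetes-heterogeneity z-tests, PheWAS profiles,
druggability, the network, a gate-accounting report and a manifest (seed,
config hash, package version). Every stage is a pure function of
(config, seed); identical configs give identical tables. Defaults are
n = 3,000 persons per cohort, 3 protein regions of 40 variants, 6 visits
over 8 years, and a 24-phecode catalog for the PheWAS stage — sizes at
which the full screen, including its replication cohort, runs in well under
a minute per protein and the property suites (20 seeded end-to-end runs,
100-region colocalization studies, 10,000-rep ACAT calibrations) complete
on one CPU; the PheWAS-stage catalog is intentionally small because
per-phecode logistic scans dominate runtime, while threshold arithmetic for
the 1,020-phecode catalog is exercised separately. Degenerate inputs
(monomorphic variants, separated logistic fits, singular mixed models,
empty instrument sets, zero-exposure-effect Wald ratios) are flagged or
skipped with explicit log/warning paths rather than silently propagated.

## Known limitations

- Single-causal-variant colocalization only; no conditional or SuSiE-style
  multi-signal analysis.
- No weighted-median/mode MR estimators; sensitivity analysis is Q + Egger.
- One-sample exposure/outcome scans in the synthetic pipeline (same cohort)
  — acceptable here because instruments require genome-wide relevance and
  the null calibration is verified empirically in the test suite, but real
  applications should use independent exposure and outcome GWAS.
- The synthetic LD model is AR(1); real regional LD is block-structured.
- PheWAS power at desk-scale n is limited; `no_hits` tiers are expected and
  are reported as such.
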