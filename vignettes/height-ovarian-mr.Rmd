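---
title: "Two-stage Mendelian randomisation of height and ovarian cancer risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Mendelian randomisation of height and ovarian cancer risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heightmr)
options(heightmr.verbose = FALSE)
```

## The question and the method

Observational studies consistently report that taller women have a modestly
higher risk of ovarian cancer, but case--control estimates of that
association are exposed to selection bias, reporting bias and confounding.
Mendelian randomisation (MR) side-steps those biases by using genetic
variants as instruments for height: alleles are assigned at conception,
before any confounder of adult behaviour can act, so a score built from
height-associated variants is (under stated assumptions) associated with
disease only through its effect on height.

`heightmr` implements the individual-level, multi-study version of this
design end to end:

1. **Instrument construction.** A weighted genetic risk score (GRS)
   $S_i = \sum_j w_j g_{ij}$ over height-associated SNPs, with external
   GWAS per-allele effects $w_j$ as weights and expected effect-allele
   dosages $g_{ij} \in [0,2]$. Weights are stored oriented to the
   height-increasing allele, so $S_i$ counts height-increasing alleles.
   Quality control retains genotyped SNPs unconditionally and imputed SNPs
   with imputation $r^2 \ge 0.6$; sensitivity subsets drop low-frequency
   SNPs (MAF < 5%), restrict to imputation $r^2 \ge 0.9$, to one SNP per
   locus, to genotyped SNPs only, or exclude annotation-tagged
   (potentially pleiotropic) SNPs.
2. **Two-stage predictor substitution.** Stage one regresses measured
   height on the score (plus age and five genetic principal components) in
   controls with height data, giving $\gamma$ cm per score unit and the
   instrument-strength diagnostics (semi-partial $R^2$ and the nested-model
   partial $F$). Predicted height is $\hat h_i = \gamma S_i$ — the score
   term only, since the covariates re-enter stage two and carrying their
   stage-one contribution forward would double-count the adjustment. Stage
   two fits, within each study, a logistic model of case status on
   $\hat h_i$ with age and the principal components; the coefficient is the
   causal log-odds per cm.
3. **Pooling.** Study estimates are combined by DerSimonian--Laird
   random-effects meta-analysis with Cochran's $Q$, $\tau^2$, $I^2$ and a
   heterogeneity p-value; effects are reported as odds ratios per 5 cm,
   $\mathrm{OR} = e^{5\beta}$ with Wald 95% intervals. Secondary
   (histotype) outcomes instead use a single logistic model stratified by
   study indicator terms, which preserves power when per-study case counts
   are small.
4. **Validity checks.** MR-Egger regression of per-SNP outcome effects on
   exposure effects (free intercept, weights $1/\mathrm{se}^2$) tests for
   directional pleiotropy; a confounder screen regresses each measured
   confounder on the score; a conventional (measured-height) analysis with
   confounder adjustment and study-by-5-year-age strata provides the
   observational comparator; and a closed-form noncentral chi-square power
   calculation characterises the design.

### Assumptions

The causal interpretation rests on the three instrumental-variable
assumptions: the score is associated with height (verifiable; the partial
$F$ diagnostic), the score is independent of confounders of the
height--disease association (partially verifiable; the confounder screen),
and the score affects disease only through height (not verifiable;
MR-Egger and annotation-exclusion subsets probe it). The second-stage
standard errors are the naive logistic-model errors — first-stage
estimation error in $\gamma$ is not propagated. With an instrument
$F \approx 2500$ at consortium scale this understatement is negligible; an
optional within-study bootstrap (`mr_bootstrap()`) quantifies it.

## Case definitions

Outcomes are defined by pure predicates over tumour behaviour and
histotype: all cases; invasive; borderline; high-grade serous (invasive
serous excluding low-grade G1, plus unknown-grade invasive serous, plus
peritoneal tumours of unknown behaviour — in both instances the majority
are high-grade serous); low-grade plus borderline serous; mucinous of any
behaviour; invasive endometrioid; invasive clear cell. For every outcome a
study enters the analysis only with strictly more than 5 qualifying cases.
Nine case-only studies are merged, before any fit, with the controls of a
case--control study from the same region (`ocac_grouping()`); the six UK
studies form a single group, so 39 studies yield 29 analysis groups.

## The synthetic cohort generator

Because the consortium's individual-level data are not publicly
deposited, the package ships a generator (`simulate_cohort()`) that
emulates the design with known ground truth, and the whole test suite
runs against it. Per SNP, genotypes are Hardy--Weinberg draws at an
effect-allele frequency from `maf_range`; per-allele height effects are
exponential draws rescaled so the *observed* score explains
`target_instrument_r2` of within-study height variance. Height is

$$h_{is} = \mu + a_s + \textstyle\sum_j b_j g_{ij} + \kappa U_i + \varepsilon_{is},$$

with study shifts $a_s \sim N(0, 2^2)$ cm, an optional latent confounder
$U_i$ shared with the disease model, and a Gaussian residual absorbing the
remaining variance so that the within-study SD equals `height_sd_cm`.
Disease follows
$\operatorname{logit} P = \alpha_s + \tfrac{\ln \mathrm{OR}_{5}}{5}(h - \mu)
 + \theta \sum_{j \in P}(g_{ij} - 2p_j) + \delta U_i + 0.01\,(\mathrm{age}-57)$,
and each study's case/control quota is met by rejection sampling from a
per-study random stream derived from the master seed (so edits to the
study list leave other studies' draws untouched).

Imputed SNPs report a posterior-mean-style dosage
$d = \lambda g + (1-\lambda)2p + e$ with $\lambda$ equal to the assigned
imputation $r^2$, clipped to $[0,2]$. Because boundary censoring raises
the observed-vs-true correlation, the jitter SD is calibrated against the
closed-form censored-normal moments so that the realised squared
correlation equals the assigned $r^2$; the same moments feed the
instrument-$R^2$ rescaling.

Default study conditions are the consortium design itself
(`ocac_design()`): the per-study invasive/borderline/unknown case and
control counts, the 22-study height subset, the 16-study confounder
subset, and the regional grouping, all encoded from the published study
table; histotype mixes are derived from the published subtype counts
(e.g., high-grade serous as ~41% of invasive cases). Values the source
does not state were fixed once as plausible epidemiological choices and
are free parameters of `sim_config()`: the per-study disease base rate
(0.25 — a rejection-sampling nuisance parameter that does not alter odds
ratios), height 163.5 (SD 6.5) cm with 2 cm between-study shifts, age
$N(57, 10)$ truncated to 18–94, parity 85%, oral-contraceptive use 50%,
education $N(12, 3)$ years, menarche $N(13, 1.5)$ years, and a weak
conditional age effect on disease (0.01 log-odds/year).

**What the generator does not emulate:** linkage disequilibrium between
instrument SNPs (loci are independent), population stratification beyond
supplied principal components, within-study height missingness (height is
all-or-none per study), genotyping batch effects, and real imputation
(dosage uncertainty is emulated parametrically). Passing tests therefore
demonstrate the statistical machinery under the stated structural model,
not robustness to these real-data features.

## Numerical choices

* Wald 95% intervals use $z = 1.959964$, pinned for bit-reproducibility.
* $\tau^2$ is the DerSimonian--Laird moment estimator truncated at zero;
  pooled intervals use normal quantiles (no Knapp--Hartung adjustment),
  matching conventional pooled-OR reporting; $I^2 = \max(0, (Q-df)/Q)$,
  defined as 0 when $Q = 0$.
* The first-stage partial $R^2$ is the increment in $R^2$ over the total
  sum of squares (semi-partial), the definition under which
  $F = \Delta R^2/(1-R^2_{\mathrm{full}}) \cdot df_{\mathrm{resid}}$ holds
  exactly.
* MR-Egger inference fixes the residual dispersion at 1 (covariance
  $(X'WX)^{-1}$) with t-based p-values on $n_{\mathrm{SNP}}-2$ df; a
  residual-based multiplicative variance inflation is available via
  `dispersion = "multiplicative"`. SNPs are auto-oriented so all exposure
  effects are positive, which leaves the fit invariant.
* Per-SNP outcome effects come from one pooled, study-indicator-adjusted
  logistic model per SNP (hundreds of per-study-per-SNP fits are unstable
  for rare subtypes); the SNP-wise IRLS sweep runs in compiled code and
  agrees with `stats::glm` to ~1e-10.
* Second-stage fits allow up to 100 IRLS iterations; a formally converged
  fit with boundary fitted probabilities or an absurd coefficient
  (|beta| or se > 10 per cm — odds ratios beyond $e^{50}$ per 5 cm) is
  treated as quasi-complete separation and excluded with a log notice,
  since such fits carry no odds-ratio information and would corrupt the
  heterogeneity statistics. True non-convergence remains a hard error.
* The power row evaluates the binary-outcome noncentral chi-square
  approximation at the covariate-adjusted instrument $R^2$ (0.17 at
  consortium scale): among the printed variance-explained figures this is
  the unique choice that reproduces the design's stated 97% power for an
  odds ratio of 1.10, and it is documented here as a reconstruction.

## Validation problem sizes

The statistical acceptance checks run the full pipeline on a
down-scaled consortium design — all 39 studies at one fifth of the
published counts (≈3,280 cases / 4,600 controls) with a 60-SNP instrument
rescaled to $R^2 = 0.13$: 200 replicates at a true OR of 1.06 per 5 cm
for bias and coverage, and 500 null replicates for type-I error. Egger
calibration uses 200 single-study replicates (2,000 cases / 2,000
controls, 60 SNPs); the pleiotropy-detection arm uses 100 replicates of a
larger design (20,000/20,000, 200 genotyped SNPs, direct effects of 0.02
log-odds per allele in 20% of SNPs) chosen by a pre-hoc power calculation
so the intercept test has ≈65% power — comfortably above the majority
threshold being tested — while each replicate stays inexpensive.

At the down-scaled study sizes several groups are very small (the
smallest has 13 cases and 13 controls against 7 model parameters), and
per-study logistic estimates carry a small finite-sample bias away from
the null; the pooled estimate consequently shows a relative upward bias
of roughly 5–10% of $\ln(1.06)$ in the recovery study. This is a property
of maximum-likelihood logistic regression at these group sizes, not of
the pipeline: it shrinks as the design approaches consortium scale.

## Known limitations

* Naive second-stage standard errors (no generated-regressor correction);
  the bootstrap is provided for comparison, not used by default.
* DerSimonian--Laird only; REML or Paule--Mandel estimators and
  Knapp--Hartung intervals are out of scope.
* Single-SNP (ratio) MR, weighted-median/mode estimators and outlier
  removal are out of scope; MR-Egger is the only pleiotropy-robust
  estimator included.
* The Egger slope's published scale in the motivating analysis is
  ambiguous (per score unit vs per cm vs per SD); this package reports it
  per cm and per 5 cm and makes no attempt to match a particular printed
  slope value.
* rsID-keyed throughout: no genome coordinates, no LD pruning, no
  imputation.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(sim = ocac_sim_config(scale = 5, n_snps = 60, seed = 1),
                  seed = 1)
report <- run_pipeline(cfg)
print(report)
```

The printed report shows, per score subset: first-stage diagnostics,
pooled odds ratios per 5 cm with heterogeneity statistics for the primary
outcomes, stratified estimates for histotype outcomes, the MR-Egger and
conventional comparators, and the design's power row.
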