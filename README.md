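# heightmr

Mendelian randomisation (MR) of adult height on ovarian cancer risk, as an
individual-level, multi-study pipeline with a fully synthetic validation
harness.

Observational studies report that taller women have a slightly higher risk
of ovarian cancer, but case–control estimates of that association are
vulnerable to selection bias, reporting bias and confounding. MR uses
genetic variants as instruments for height: because alleles are fixed at
conception, a height genetic risk score is unconfounded by adult exposures,
and its association with disease — under the instrumental-variable
assumptions — reflects a causal effect of height. `heightmr` is for
biostatisticians and genetic epidemiologists who want that full design as
tested, reusable code: consortium-style data with many case–control
studies, some contributing cases only, heterogeneous phenotype
availability, and histotype-specific outcomes.

## The model

* **Instrument.** A weighted genetic risk score
  `S_i = Σ_j w_j g_ij` over height-associated SNPs (external GWAS weights
  `w_j`, effect-allele dosages `g_ij ∈ [0,2]`), with QC (imputation
  r² ≥ 0.6) and sensitivity subsets (MAF ≥ 5%, r² ≥ 0.9, one SNP per
  locus, genotyped-only, annotation exclusions).
* **Two-stage predictor substitution.** Stage 1 (controls with height):
  `height ~ S + age + PC1..PC5`, giving γ cm per score unit, semi-partial
  R² and the partial-F instrument diagnostic. Stage 2 (per study):
  logistic `case ~ γS + age + PC1..PC5`; the coefficient is the causal
  log-odds per cm of genetically predicted height.
* **Pooling.** DerSimonian–Laird random effects over study estimates
  (Cochran's Q, τ², I²), reported as odds ratios per 5 cm,
  `OR = exp(5β)` with Wald 95% CIs; secondary histotype outcomes use one
  study-stratified logistic model instead.
* **Validity.** MR-Egger regression (weighted, free intercept) for
  directional pleiotropy; a score-vs-confounder screen; a conventional
  measured-height comparator (confounder-adjusted, study × 5-year-age
  strata); closed-form noncentral-χ² power for binary-outcome MR.
* **Synthetic cohorts.** `simulate_cohort()` generates the whole design —
  39 studies with the published case/control composition, Hardy–Weinberg
  genotypes, calibrated imputation noise, a score explaining 13% of height
  variance, and a logistic disease model with a known OR per 5 cm — so
  every stage is testable against ground truth.

## Worked example

A full run on a down-scaled consortium-shaped simulation (39 studies at
one fifth of the published sizes, 60-SNP instrument, true OR 1.06 per
5 cm):

```r
library(heightmr)
cfg <- run_config(sim = ocac_sim_config(scale = 5, n_snps = 60, seed = 1),
                  seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
run_report (config 48630b35, seed 1)
subset main [GRS-60]: first-stage 5.43 cm/unit, partial F 548.5
  all                          pooled OR/5cm 1.075 (0.969-1.194), k=29, I2=4%
  invasive                     pooled OR/5cm 1.064 (0.945-1.198), k=29, I2=12%
  borderline                   pooled OR/5cm 1.369 (1.049-1.786), k=11, I2=5%
  high_grade_serous            stratified OR/5cm 1.116 (0.987-1.262), k=29
  lowgrade_borderline_serous   stratified OR/5cm 1.310 (0.991-1.731), k=13
  mucinous                     stratified OR/5cm 1.153 (0.893-1.487), k=18
  endometrioid                 stratified OR/5cm 0.933 (0.747-1.165), k=21
  clear_cell                   stratified OR/5cm 1.012 (0.726-1.413), k=13
MR-Egger: OR/5cm 1.089 (0.944-1.257), intercept p = 0.930
conventional OR/5cm 1.085 (1.031-1.141) over 16 studies
power to detect OR 1.10: 33.4%
```

Reading this: the first stage is strong (partial F ≈ 549; 5.43 cm per
score unit against a generating value of 5.2). The 39 studies collapse to
29 analysis groups after merging the nine case-only studies with regional
controls. The all-case pooled OR of 1.075 per 5 cm brackets the generating
1.06; the borderline outcome runs only over the 11 groups with more than 5
borderline cases at this scale. The Egger intercept shows no directional
pleiotropy (none was simulated), and the design retains only 33% power at
one fifth of the consortium's sample size — at full scale the same
calculation gives 97% for an OR of 1.10 (`mr_power_binary(39398,
16395/39398, 0.17, 1.10)`).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/heightmr-cli.R` (verbs `simulate`, `run`, `power`, `meta`,
`egger`).

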