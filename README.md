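# grsburden

Blood-pressure genetic risk scores and the burden of coronary heart disease.

`grsburden` is an R package for epidemiologists and statistical geneticists
who want to test whether a genetically conferred tendency toward higher
blood pressure carries through to coronary heart disease (CHD) — not only
whether disease is present, but how many coronary vessels (0–3) are
significantly obstructed in a cohort referred for angiography. It implements
the full analysis pipeline: SNP panel handling with risk-allele orientation,
genotype quality control, score construction, quartile-based association
models, pleiotropy and effect-modification screens, sensitivity subsets, and
a seeded synthetic cohort generator with known ground truth.

## The scores

For individual *i* over a panel of *N* risk-oriented variants with dosages
*s<sub>ij</sub>* ∈ [0, 2] and positive effect sizes *β<sub>j</sub>* (mmHg
per allele):

- unweighted: uGRS<sub>i</sub> = Σ<sub>j</sub> s<sub>ij</sub>
  (one point per risk allele, additive model)
- weighted: wGRS<sub>i</sub> = (N / Σ<sub>j</sub>β<sub>j</sub>) ·
  Σ<sub>j</sub> β<sub>j</sub>s<sub>ij</sub>
  (effect-size weighted, normalized by the mean effect size)

Both are standardized to mean 0 / SD 1 and analysed as quartiles with the
lowest quartile as reference: logistic regression for hypertension and
prevalent CHD, and a baseline-category multinomial logit for vessel burden
(0 vessels as baseline), adjusted for age quartile, sex, smoking, BMI
category, diabetes, hyperlipidemia, stroke and peripheral artery disease.

QC filters use the chip-cohort conventions: variant missingness > 5%,
sample call rate < 95%, Hardy–Weinberg p < 1e-4 (chi-square on hard calls;
an exact test is available), minor allele count < 20, LD pruning at
r² ≥ 0.8, and r² > 0.8 proxy substitution for ungenotyped panel variants.

## Worked example

A fully simulated run at the default study conditions (4,809 individuals,
266 SNPs, hypertension prevalence calibrated to 56.3%, vessel distribution
to 46.1/26.6/13.9/13.4%, dose-response quartile effects on 2- and 3-vessel
disease):

```r
library(grsburden)

cfg <- grs_config(
  simulation = sim_config(n_individuals = 4809, n_snps = 266, seed = 42),
  seed = 42
)
res <- run_pipeline(cfg, out_dir = "grs_run")
```

`grs_run/summary.txt` from this exact run:

```
analysis n: 4809
panel variants used: 266
hypertension prevalence: 0.574
CHD prevalence: 0.536
vessel distribution (0/1/2/3): 0.464 / 0.271 / 0.133 / 0.132
uGRS quartile counts: 1226 / 1292 / 1258 / 1033
statistical tests performed (no multiplicity correction): 20
```

(Quartile counts are unequal because the unweighted score is integer-valued
and ties share a quartile.) The adjusted vessel-burden model,
`tidy(res$fits$vessels_u_adjusted)`:

```
  outcome level term    estimate     se    or ci_low ci_high  p_value model
1 vessels     1 grs_qQ2   0.0808 0.0947 1.08   0.901    1.31 0.393    adjusted
2 vessels     1 grs_qQ3  -0.0127 0.0971 0.987  0.816    1.19 0.896    adjusted
3 vessels     1 grs_qQ4  -0.0640 0.103  0.938  0.766    1.15 0.535    adjusted
4 vessels     2 grs_qQ2   0.0882 0.129  1.09   0.848    1.41 0.494    adjusted
5 vessels     2 grs_qQ3   0.312  0.125  1.37   1.07     1.75 0.0129   adjusted
6 vessels     2 grs_qQ4   0.262  0.132  1.30   1.00     1.68 0.0475   adjusted
7 vessels     3 grs_qQ2   0.258  0.131  1.29   1.00     1.67 0.0494   adjusted
8 vessels     3 grs_qQ3   0.388  0.130  1.47   1.14     1.90 0.00278  adjusted
9 vessels     3 grs_qQ4   0.456  0.134  1.58   1.21     2.05 0.000660 adjusted
```

Each row is one quartile contrast against the lowest quartile: no quartile
effect on 1-vessel disease, rising odds for 2- and 3-vessel disease — the
dose-response pattern the generator was configured with (true Q4 ORs 1.36
and 1.65 on levels 2 and 3; the fitted 1.30 and 1.58 sit well inside their
Wald intervals at this n). `anova_grs_vessels()` confirms the score differs
across vessel strata (F = 5.84, p = 5.6e-4 here) and the GRS×age
likelihood-ratio test finds no effect modification (p = 0.63), as simulated.

Real data enter the same way with file paths instead of a simulation config:
a panel TSV (`rsid chrom pos effect_allele other_allele beta_sbp beta_dbp
beta_pp traits [proxy_of proxy_r2]`), genotypes as a VCF (DS dosages
preferred, GT fallback) or a dosage TSV, and a phenotype CSV; see
`?grs_config` and `?run_pipeline`.

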