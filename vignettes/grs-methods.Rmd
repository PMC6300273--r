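---
title: "Blood-pressure genetic risk scores and coronary disease burden: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-pressure genetic risk scores and coronary disease burden: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsburden)
library(dplyr)
```

## The scientific problem

Genome-wide association studies have mapped several hundred common variants
that shift systolic blood pressure (SBP), diastolic blood pressure (DBP), or
pulse pressure (PP) by fractions of a mmHg per allele. A genetic risk score
(GRS) aggregates that signal per person so one can ask whether a lifelong,
genetically conferred tendency toward higher blood pressure translates into
coronary heart disease (CHD) — and, in cohorts referred for coronary
angiography, into a heavier *burden* of disease, measured as the number of
coronary vessels (0–3) with significant obstruction.

`grsburden` implements that analysis end to end: panel handling and allele
harmonization, genotype quality control, score construction, quartile-based
association models, screens for pleiotropy and effect modification,
sensitivity subsets, and a seeded synthetic cohort generator so every stage
is testable with known ground truth.

## Scores

Let $s_{ij} \in [0, 2]$ be the dosage of the risk allele of variant $j$
carried by individual $i$, and $\beta_j > 0$ its effect size (mmHg per
allele) after orientation. The package computes

$$\mathrm{uGRS}_i = \sum_{j=1}^{N} s_{ij}, \qquad
  \mathrm{wGRS}_i = \frac{N}{\sum_j \beta_j} \sum_{j=1}^{N} \beta_j\, s_{ij},$$

the unweighted count of risk alleles and the effect-size-weighted sum
normalized by the mean effect size so it stays on the allele-count scale.
Two identities anchor the implementation and its tests: with equal weights
the two scores coincide individual-by-individual, and a single-variant
weighted score is the dosage itself. Both scores are standardized to mean
zero and unit sample SD (the $n-1$ denominator; quartile-based analyses are
invariant to that choice), and analyses use quartiles of the score with the
lowest quartile as reference.

**Risk orientation.** Each variant's effect allele is oriented to be the
risk (effect-increasing) allele regardless of allele frequency: a variant
with $\beta < 0$ has its alleles swapped, all trait betas negated, and
dosages mirrored ($s \mapsto 2 - s$). The operation is idempotent, and
`orient_to_risk()` additionally harmonizes genotype allele codings that are
swapped relative to the panel. Variants whose alleles match neither
orientation, or with $\beta = 0$ (no risk direction; a zero-weight variant
would contribute nothing to the weighted score yet inflate the unweighted
one), are hard errors.

**Multi-trait variants.** A variant associated with two or three of
SBP/DBP/PP carries one beta per member trait. The combined panel uses, per
variant, the member beta of largest magnitude — a declared convention, since
the choice of a single combined weight for multi-trait variants is genuinely
open; trait-specific sub-scores (`subset_by_trait()`) use each trait's own
beta and sidestep the convention entirely.

**Missing dosages at scoring time.** Default is mean imputation (the
variant's mean observed dosage, i.e. twice its allele frequency), the
conventional choice in polygenic scoring because it keeps the analysis n
stable and is unbiased under missingness at random; `zero` and `drop`
policies are selectable.

**Quartiles.** Ranks are cut at the empirical 25/50/75 percentiles
(nearest-rank, `quantile(type = 1)`); all individuals tied at a cut value
fall in the lower interval, so integer-valued unweighted scores produce the
characteristic slightly-unequal quartile counts. Labels are invariant under
strictly monotone transforms, hence identical for raw and standardized
scores.

## Quality control

Thresholds follow the conventions of chip-based cohort studies, all strict
inequalities on the stated side:

| filter | default | removed when |
|---|---|---|
| variant missingness | 0.05 | missing fraction **>** 5% |
| sample call rate | 0.95 | call rate **<** 95% |
| Hardy–Weinberg equilibrium | 1e-4 | HWE p **<** 1e-4 |
| minor allele count (MAC) | 20 | MAC **<** 20 |
| LD pruning | r² = 0.8 | pairwise dosage r² **≥** 0.8 |

MAC is computed from dosage sums, `min(sum(s), 2·n_nonmissing − sum(s))` —
imputation-aware, with hard calls as the rounded special case. HWE is tested
on hard calls only (dosages within ±0.1 of an integer; equilibrium
proportions are not defined for continuous dosages), by a 1-df chi-square
goodness-of-fit test against $p^2, 2pq, q^2$ with no continuity correction;
a conditional exact test (full enumeration of heterozygote counts at fixed
allele counts, optionally mid-p) is available. For counts of a few hundred
with adequate expected classes the chi-square p tracks the exact mid-p
within about 0.05 absolute; monomorphic variants return p = 1 with a
warning, since no departure is observable. QC stages run in the order
variant missingness → sample call rate → HWE, and every exclusion is logged
with its rule and triggering value.

For pairs in LD the variant with the smaller |beta| is dropped (tie: later
panel order), a deterministic rule chosen because any rule reproduces a
panel that was already LD-pruned upstream. Index variants absent from the
genotype data are replaced by a genotyped proxy with r² > 0.8 when the proxy
map offers one (largest r² wins; the substituted row keeps the index
variant's effect sizes, assuming the proxy's dosages track the index risk
allele at that r²); otherwise the variant is dropped and logged.
Strand-ambiguous (A/T, C/G) variants are retained with a warning by default
— panel and genotypes are assumed harmonized to one genome build — and can
be dropped with `check_ambiguous(drop = TRUE)`.

## Association models

The covariate design follows the clinical-epidemiology convention: GRS
quartile (reference Q1), age quartile computed on the analysis sample
(reference youngest), sex, smoking, BMI category (underweight < 18.5, normal
18.5–25 as reference, overweight (25, 30], obese > 30 kg/m² — the boundary
values close the gap a printed "25–25.1" banding would leave), diabetes,
hyperlipidemia, stroke, and peripheral artery disease. Analyses are
complete-case (the dropped count is always reported); no multiple-testing
correction is applied, and the run summary states the number of tests
performed.

Binary outcomes (hypertension, prevalent CHD) are fitted by
maximum-likelihood logistic regression; coronary vessel burden (0/1/2/3) by
a baseline-category multinomial logit with 0 vessels as baseline, which
reduces exactly to the logistic model when only two levels are present.
Intervals are Wald 95% CIs, $\exp(b \pm 1.96\,\mathrm{SE})$. Saturated
single-predictor fits must reproduce the contingency-table cross-product
ratios exactly — the test suite holds both model families to that closed
form. Any fitted |log-odds| > 15 is treated as quasi-separation and raised
as an error rather than reported as an unstable OR; non-convergence within
the iteration caps (100 IRLS / 200 BFGS iterations, multinomial relative
tolerance 1e-12) is likewise an error.

Supporting analyses: a fixed-effects one-way ANOVA of the standardized score
across the four vessel strata (equal to the squared pooled-variance t with
two groups); a likelihood-ratio test for GRS×age effect modification (all
nine product terms, chi-square with 9 df); a pleiotropy screen regressing
each non-target risk factor on the quartiles (logistic for binary factors,
linear for BMI) — a blood-pressure score that associates with smoking or
diabetes would be acting through something other than blood pressure; and
sensitivity refits on the non-hypertensive or no-prior-AMI subsets with
quartiles recomputed within the subset.

## The synthetic cohort generator

The generator emulates the statistical structure of a genotyped angiography
cohort, with every default fixed once as the study condition it mirrors:

* 4,809 individuals, 266 independent biallelic SNPs; allele frequencies
  uniform on [0.05, 0.95]; dosages Binomial(2, p) per individual, so
  Hardy–Weinberg equilibrium holds by construction.
* Effect sizes exponential with mean 0.5 mmHg, already risk-oriented;
  about 24% of variants belong to two or three blood-pressure traits with
  sign-consistent member betas.
* Hypertension ~ Bernoulli(logit⁻¹(α + γ·GRS_std)) with γ = 0.25 per SD, a
  realistic magnitude for a polygenic blood-pressure score's dose-response;
  marginal prevalence calibrated to 56.3%.
* Vessel burden ~ baseline-category multinomial in GRS quartile indicators
  (matching the analysis model, so recovery tests are well-specified) with
  per-quartile log-odds ratios defaulting to the dose-response operating
  point: no quartile effect on 1-vessel disease, ORs (1, 1.33, 1.36) on
  2-vessel and (1.32, 1.77, 1.65) on 3-vessel disease for Q2–Q4; marginal
  distribution calibrated to 46.1/26.6/13.9/13.4%. Significant CHD is the
  indicator of ≥1 diseased vessel (prevalence 53.9% under the defaults).
* Covariate marginals: male 64.2%, smoking 24.0%, diabetes 17.5%,
  hyperlipidemia 57.8%, stroke 7.9%, PAD 6.3%, prior AMI 14.6% baseline
  with odds increasing 1.6-fold per diseased vessel; age ~ N(65.6, 11.9²)
  (median 66, IQR ≈ 58–74); BMI ~ N(26.9, 4.4²), an approximation that
  reproduces the normal/overweight/obese split only roughly. Covariates are
  drawn independently — no covariance structure is imposed — and with zero
  effect on the outcomes unless configured otherwise.
* Optional per-variant and per-sample missingness injection; a mandatory
  seed, so identical configurations reproduce bit-identical cohorts.

Intercepts are calibrated deterministically: the hypertension intercept by
monotone root-finding of the marginal prevalence integrated over the
standard-normal score (closed form logit(target) when γ = 0), multinomial
intercepts by iterative proportional adjustment over the uniform quartile
distribution (closed form log(p_k/p_0) under zero effects); achieved
marginals are verified to 0.5 percentage points.

**What passing tests do and do not show.** The generator draws variants
independently (no LD — the panel it emulates is already pruned), with no
population stratification, no relatedness, covariates independent of each
other and of genotype, and the vessel outcome generated from the same model
family the analysis fits. Calibration and recovery results therefore
demonstrate correctness of the machinery, not robustness to model
misspecification, confounding, or structured missingness in real cohorts.

## Numerical and design choices

* Score standardization is verified to 1e-10; equal-weight and single-SNP
  identities to machine precision.
* Quartile ties go to the lower interval; degenerate inputs (fewer than 4
  distinct score values, zero-variance scores, empty trait panels, empty
  vessel strata) raise errors rather than silently degrade.
* The exact HWE p-value sums all heterozygote configurations no more
  probable than the observed one, with a numerically safe log-gamma
  implementation and a (1 + 1e-12) tie guard.
* Aggregation to exposure-outcome cell counts with frequency weights is
  used in replicate-heavy calibration suites; for purely categorical
  designs the weighted fit maximizes the identical likelihood, so this is
  an implementation of the same estimator, not an approximation.
* Problem sizes in the packaged suites: oracle checks at 100×50; type-I
  error over 500 null cohorts of n = 4,000; ANOVA uniformity over 1,000
  replicates; interaction size over 250 replicates of n = 2,000; CI
  coverage over 200 cohorts of n = 5,000; recovery at n = 50,000 with the
  consistency scan at n ∈ {2,000, 8,000, 32,000}; marginal calibration at
  n = 100,000. Panel sizes in simulation-heavy checks are 10–40 variants,
  since score-quartile structure, not panel size, drives those quantities.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- grs_config(
  simulation = sim_config(n_individuals = 4809, n_snps = 266, seed = 42),
  seed = 42
)
res <- run_pipeline(cfg, out_dir = "grs_run")
res$summary$outcome_prevalence
tidy(res$fits$vessels_u_adjusted)
plot_forest(res$results)
```

The run directory holds the score set, QC report, exclusion log, tidy
association tables (TSV/JSON), a forest-table CSV, a human-readable summary,
and a provenance manifest (config, seed, versions) sufficient to reproduce
the run exactly.

## Known limitations

* No LD-aware scoring or reference-panel r² computation; LD pruning uses
  in-sample dosage correlation only, and proxies come from a precomputed map.
* No ancestry, relatedness, or sex-consistency checks; inputs are assumed
  to come from an already-curated, single-ancestry cohort on one genome
  build.
* The multinomial model treats vessel burden as nominal with a baseline
  category (the analysis convention it implements); an ordinal generator
  for misspecification probing is a possible extension, not included.
* Continuous-score effect estimates are exposed but the analysis surface is
  quartile contrasts.
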