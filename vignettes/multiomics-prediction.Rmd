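---
title: "Methylation and polygenic score prediction in twin cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation and polygenic score prediction in twin cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Complex traits and exposures carry signal in two omics layers of blood (or
buccal) samples: common genetic variation, summarised per individual by a
polygenic score (PGS), and DNA methylation, summarised by a methylation
score (MS). A PGS captures inherited predisposition; an MS — because
methylation responds to the environment — can also capture the molecular
footprint of exposures such as smoking. `omicscores` implements the full
comparison pipeline: score construction from discovery summary statistics,
nested prediction models robust to the family structure of twin cohorts,
and a decomposition of trait variance into MS and PGS contributions.

## Scores

**Methylation score.** For individual $j$,
$\mathrm{MS}_j = \sum_i \beta_i \, \mathrm{CpG}_{ij}$, where
$\mathrm{CpG}_{ij} \in [0,1]$ is the beta value at CpG $i$ and $\beta_i$
the effect size reported by an independent discovery EWAS. Subsets of CpGs
enter the score at p-value thresholds $10^{-1}, 10^{-5}, 10^{-7}$
(strict `<`), each optionally pruned. A fixed marker list (e.g. an
FDR-significant CpG set from an EWAS without genome-wide summary
statistics) can replace the threshold rule.

**Pruning.** `prune_markers()` performs greedy step-wise selection: take
the most significant remaining marker, discard every remaining marker
whose correlation with it — computed on the target cohort's own beta
values — is at or above the cut-off (default 0.1), repeat. Ties in p are
broken by marker id so runs are reproducible. We prune on $|r|$ by
default: a strongly negatively correlated probe is equally redundant for
a linear score; signed pruning is available via `use_abs = FALSE`.
Zero-variance markers are excluded up front because their correlation is
undefined. Whether the original procedure used signed or absolute
correlation, and whether beta values were covariate-adjusted first, is not
documented anywhere we know of; we use raw beta values, which is the only
matrix a target cohort is guaranteed to have.

**Polygenic score.** $\mathrm{PGS}_j = \sum_k w_k d_{kj}$ with $d_{kj}$
the aligned dosage of the effect allele. Alignment per variant: cohort
counts the effect allele — use $d$; cohort counts the other allele — use
$2-d$; otherwise the variant is dropped with a warning. GWAS input QC
removes strand-ambiguous (A/T, C/G) pairs, duplicate ids and MAF
$\le 0.01$. LD-aware reweighting of GWAS effect sizes (LDpred-style) is
out of scope: the reader accepts either raw or pre-adjusted weights and
the scores module does not care which.

Markers requested but absent from the cohort are counted and excluded
*without* renormalising the remaining weights: scores are z-scored before
modelling, so a missing-marker subset only changes the score's scale, and
the reported `coverage` lets users gate on completeness.

## Models

Traits (continuous), MS and PGS are z-scored (sample SD, $n-1$) within the
analysis sample after exclusions. The model grid is:

* Model 1: trait ~ MS + sex + age + EWAS covariates (cell proportions,
  technical batch);
* Model 2: trait ~ PGS + sex + age + GWAS covariates (genetic PCs,
  platform);
* Model 3: trait ~ MS + PGS + both covariate sets.

**Continuous traits** are fitted with generalized estimating equations
(exchangeable working correlation over families, identity link, at most
100 iterations) and robust sandwich standard errors. No GEE package is
assumed: `fit_gee()` implements the standard iteration — Fisher scoring on
the working model, a moment estimator of the exchangeable correlation from
Pearson residuals, and the closed-form inverse
$R^{-1} = \frac{1}{1-\alpha}\left(I - \frac{\alpha}{1+(n_i-1)\alpha}J\right)$
per cluster — and is validated against OLS under singleton clusters and
against Monte-Carlo sandwich consistency. Variance explained by a score is
its squared standardized coefficient times 100. This is the printed-rule
convention; when MS and PGS correlate it mis-states the joint $R^2$
slightly (observed MS–PGS correlations in this setting are $\le 0.15$),
which is why the decomposition also reports the components' sum rather
than a model-$R^2$ difference.

**Binary traits** use the liability-scale convention: each logistic
model's latent $R^2$ is $V/(V + \pi^2/3)$, with $V$ the variance of the
fitted linear predictor and $\pi^2/3$ the logit residual variance (the
probit variant, residual 1, is an option). A score's contribution is the
difference in latent $R^2$ between the full model and the model without
that score (3a−3b for MS, 3a−3c for PGS). Nested latent $R^2$ is not
monotone in finite samples, so negative differences are floored at zero
with a warning. p-values for binary traits come from binomial GEE refits
of the full design — except in one-twin-per-pair analyses, where plain
logistic fits are used, matching the convention for exposures shared by
co-twins. The total reported for the combined model is the *sum* of the
two nested differences (this matches how published totals of this design
add up); the full-model-minus-covariates-only difference is attached as an
attribute for transparency.

**Phenotype preparation.** Continuous traits are screened with a
single-pass 3-SD outlier rule. For exposures identical within a pair, one
twin per family is drawn reproducibly from a seed. A sensitivity filter
keeps samples whose trait measurement is within 3 years of DNA collection
(inclusive boundary: exactly 3.0 years is kept, since only gaps *more
than* 3 years away are excluded).

**Multiple testing.** `bonferroni_alpha()` divides the family-wise alpha
by the number of tests and carries an audit of how the executed plan
arrived at that count (grid cells + one test each for models 2 and 3 per
trait + sensitivity cells). The audit reports its own arithmetic rather
than forcing any externally printed total.

## The synthetic twin cohort

Real cohort data of this kind is access-restricted, so every stage is
validated against `simulate_cohort()`, which produces a cohort with known
ground truth:

* **Genotypes** follow a per-SNP parental-transmission model: two parents
  per family, one transmitted allele each per meiosis. MZ co-twins reuse
  one meiosis (identical dosages); DZ co-twins are independent meioses
  from the same parents (correlation 0.5 on average, with valid allele
  frequencies and integer dosages — a blanket 0.5 correlation would give
  neither).
* **Methylation** is generated on a latent Gaussian scale with
  within-block correlation `block_rho` (default 0.3, blocks of 10), a
  per-CpG cell-composition loading (N(0, 0.2)) shared with a measured
  cell-proportion covariate, then squashed to $[0,1]$ by
  $\mathrm{plogis}(b_i + 0.4 z)$ with baselines $b_i \sim U(-1.5, 1.5)$.
  The squash is deliberately gentle: beta values stay nearly affine in the
  latent scale (mid-range beta values, as at typical trait-associated
  CpGs), so a score computed on beta values recovers variance fractions
  configured on the latent scale. Rank structure, which pruning relies
  on, is preserved by monotonicity regardless.
* **Traits.** The continuous trait is the sum of a causal-SNP component, a
  causal-CpG (latent-scale) component, a covariate component and Gaussian
  noise, each component rescaled to its configured sample-variance
  fraction (`r2_pgs_true`, `r2_ms_true`, `r2_cov_true`); the binary trait
  thresholds an analogous liability at `qnorm(1 - prevalence)`. An
  optional `env_rho` shares part of the residual within pairs (default 0:
  no value for the intra-pair environmental correlation is documented, so
  it is exposed rather than fixed).
* **Discovery statistics.** Reported effect = true effect + N(0,
  $1/\sqrt{n_\mathrm{discovery}}$), SE equal to that SD, two-sided Wald p.
  Non-causal markers have true effect 0, so their p-values are uniform and
  threshold grids behave as in a real EWAS/GWAS.

All randomness flows from the config seed (the discovery-statistics
generator uses seed + 1), and equal seeds give bit-identical cohorts.

What the simulator does **not** emulate: realistic LD, imputation
uncertainty, array batch effects beyond one batch covariate, age-dependent
methylation drift, tissue differences between discovery and target. A
passing recovery test therefore shows the estimators are correct under the
assumed generative model, not that real-data performance will match.

## Numerical choices and problem sizes

* GEE convergence: max coefficient change $< 10^{-10}$, cap 100
  iterations; non-convergence is flagged but results are still returned.
* The working correlation is clamped to $(-0.99/(n_{max}-1),\ 0.99)$ to
  keep the exchangeable inverse defined.
* Logistic fits error on perfect separation (naming the separating
  column) and on quasi-separation (coefficients beyond ±25).
* Best-score ties (within $10^{-12}$ in $R^2$) break toward fewer markers
  — parsimony; realistic grids essentially never tie.
* Residual missing beta values after the 5% missingness rule are
  mean-imputed per marker: the minimal stand-in for the heavier matrix
  imputation used inside array QC pipelines, which is out of scope here;
  the count is logged.
* Test and validation problem sizes were chosen to keep Monte-Carlo error
  well inside the asserted tolerances at desk scale: recovery runs use
  1,500 pairs x 20 replicates over a 3x3 grid of variance fractions,
  null-calibration runs 100 replicates of 1,000 pairs, and the
  sandwich-consistency check 200 replicates of 500 clusters.

## Known limitations

* The squared-coefficient $R^2$ convention for continuous traits and the
  nested-difference convention for binary traits are not the same
  estimand when predictors correlate; both match the procedure this
  package sets out to implement, and the caveat is documented above.
* Mean imputation underestimates variance at imputed cells.
* The GEE implementation covers the exchangeable structure used here, not
  general working correlations; ACE-style variance-component twin models
  are out of scope.
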