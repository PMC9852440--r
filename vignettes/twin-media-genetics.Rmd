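---
title: "Genetically informed analysis of media use and mental health: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetically informed analysis of media use and mental health: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinconfound)
```

## The scientific problem

Associations between online media use (problematic internet use, online
victimisation, general social/phone/video use) and mental health are easy to
observe and hard to interpret: media use is itself partly heritable, so the
same genetic differences that shape how young adults use media can also
confer risk for anxiety, depression or behavioural problems. A correlation
between an "environmental" exposure and an outcome may then be genetically
confounded rather than causal. `twinconfound` implements the three
complementary designs used to probe this:

1. **Univariate twin models** — how heritable is each media-use measure?
2. **Bivariate twin models** — how much of a media-mental-health
   correlation is mediated by genetic versus environmental covariance?
3. **Polygenic-score analyses and a genetic-confounding sensitivity
   analysis (Gsens)** — how much of the association survives adjusting for
   measured genetic liability, and what would happen if the polygenic score
   were as predictive as SNP- or twin-based heritability implies?

Because the underlying cohort data (twin registry phenotypes and genotypes)
are access-restricted, the package pairs every analysis with a synthetic
data generator whose ground truth is known exactly. All estimators are
validated by parameter recovery against that truth, and the published
variance-component table is reproduced from its printed correlation
summaries.

## The ACE model

For a standardized phenotype, the classical twin decomposition writes the
variance as $a^2 + c^2 + e^2 = 1$: additive genetic (A), shared
environmental (C) and nonshared environmental (E, absorbing measurement
error). Monozygotic (MZ) co-twins share all segregating variants, dizygotic
(DZ) co-twins half on average, so the model-implied intraclass correlations
are

$$ r_{MZ} = a^2 + c^2, \qquad r_{DZ} = \tfrac{1}{2} a^2 + c^2. $$

`falconer_estimates()` inverts these by moments ($a^2 = 2(r_{MZ} -
r_{DZ})$), deliberately without constraints: a negative $c^2$ is a
diagnostic signal (it occurs whenever $r_{DZ} < r_{MZ}/2$) and is flagged
rather than clipped.

`fit_ace_ml_raw()` is the estimator of record: it maximizes the
bivariate-normal likelihood of co-twin pairs per zygosity group, with means
0 and unit variances fixed — phenotypes are assumed residualized and
normalized first (see below) — under $a^2, c^2 \ge 0$, $a^2 + c^2 \le 1$.
The components are parameterized directly as variance proportions on the
constrained simplex rather than as path coefficients; at an optimum the two
parameterizations coincide, and the direct one makes boundary solutions
($\hat c^2 = 0$ is ubiquitous in adult samples) explicit in the output
rather than hidden behind a squared path. DZ same-sex and opposite-sex
pairs are pooled into a single DZ group; no sex-limitation model is fitted,
matching the pooling decision justified by the sex/zygosity ANOVA below.

`fit_ace_ml_summary()` fits the same model when only printed group
correlations and pair counts are available, by maximizing the Fisher-z
likelihood $z(r_g) \sim N(z(\rho_g), 1/(n_g - 3))$. This is the standard
asymptotically equivalent summary-level fit; applied to the published
intraclass correlations it reproduces the printed boundary-constrained
A/C/E rows to two decimals for problematic media use (0.43/0.00/0.57) and
the E component of online victimisation (0.74). One published row is *not*
reproducible from its own printed correlations: the online-victimisation
A/C pair (printed 0.26/0.00) disagrees with the saturated solution of its
own correlations (0.22/0.04), presumably because the original raw-data fit
on transformed phenotypes is not exactly summarized by the rounded
intraclass correlations. We document this rather than forcing agreement,
and exclude that cell from reproduction checks.

### Intervals

`profile_ci()` computes likelihood-ratio profile intervals: the bound for a
component is where twice the log-likelihood drop reaches the $\chi^2_1$
quantile, profiling out the remaining free parameter, truncated to
$[0, 1]$. Components estimated on a boundary get a limit of exactly 0,
matching the "(0.00–0.00)" intervals typical of published tables. Coverage
for $a^2$ is verified by simulation at the published group sizes
(2,890 MZ / 4,879 DZ pairs, 500 replicates) and sits near 0.95.

### Optimization choices

Both fits use L-BFGS-B over the box $u = a^2+c^2 \in [0,1]$,
$v = c^2/u \in [0,1]$ from five deterministic starting points, followed by
a Nelder-Mead polish (relative tolerance $10^{-14}$). The polish matters
for a specific property: when the correlation pattern admits an interior
solution, the ML fit must equal the Falconer moment solution to $10^{-6}$,
which requires more absolute accuracy than L-BFGS-B's default stopping
rule delivers.

## Phenotype preparation

Co-twins share age exactly and MZ co-twins share sex, so any age or sex
effect inflates the apparent shared environment. `residualize()` removes
age and sex by least squares and re-standardizes; `vdw_transform()` then
corrects skewness by the van der Waerden rank-based inverse-normal map
$\Phi^{-1}(\mathrm{rank}/(n+1))$ with average ranks for ties.
Residualization precedes the rank transform, following the order in which
the two steps are described for the original analyses; the transform is
rank-preserving, so the composition is monotone in the residualized
phenotype. `variance_by_sex_zygosity()` implements the pooling check (a
two-way ANOVA on one randomly selected twin per pair); in the simulated
cohorts, as in the published sample, sex and zygosity jointly explain well
under 1% of variance.

Intraclass correlations are computed by double-entry Pearson correlation
(each pair contributes both orderings) rather than the ANOVA ICC(1): the
double-entry form is the twin-literature convention, is exactly invariant
to within-pair ordering, and is consistent with the likelihood used by the
model fits. Confidence intervals use the Fisher-z approximation with the
number of complete pairs as the effective sample size. Phenotypic
correlation families are adjusted by the Benjamini-Hochberg step-up rule;
the family is all media-by-mental-health cells of one analysis run, which
is the most conservative reading of "adjusted across the reported grid".

## The bivariate Cholesky decomposition

For two traits x and y the decomposition splits their phenotypic
correlation $r_{ph}$ into component covariances,

$$ r_{ph} = \underbrace{a_{11} a_{21}}_{cov_A} +
            \underbrace{c_{11} c_{21}}_{cov_C} +
            \underbrace{e_{11} e_{21}}_{cov_E}, $$

identified by cross-twin cross-trait correlations: the MZ cross-twin
cross-trait covariance is $cov_A + cov_C$, the DZ one is $cov_A/2 + cov_C$,
and the within-twin one adds $cov_E$. `fit_bivariate_cholesky()` maximizes
the 4-variate normal likelihood of $(x_1, y_1, x_2, y_2)$ per zygosity
group. Internally the model is parameterized by per-trait simplex
coordinates plus the three component correlations $(r_A, r_C, r_E)$, which
is equivalent to the lower-triangular Cholesky paths for two traits but
turns the positive-variance constraints into box constraints; the paths
$a_{11}, a_{21}, a_{22}, \dots$ are recovered afterwards and reported with
signs fixed by $a_{11}, a_{22}, c_{11}, \dots \ge 0$.

The primary output is the proportions `prop_a`/`prop_c`/`prop_e` of
$r_{ph}$ (the quantities usually plotted as "genetic and environmental
contributions to the association"), not the absolute covariances.
Proportions of a near-zero correlation are meaningless, so a guard warns
whenever $|r_{ph}| < 0.05$; in the source analyses the decomposition was
only applied to correlations of magnitude at least 0.20 (the published
phrase prints the inequality in the opposite direction, an apparent typo we
read as $|r| \ge 0.20$).

Numerical choices worth recording:

* the likelihood adds a fixed $10^{-8}$ ridge to the model covariance
  before Cholesky factorization. Without it the objective is discontinuous
  at the singular boundary reached by (near-)duplicate traits, and the
  optimizer chases rounding noise in the factorization pivots;
* exactly duplicated traits (sample cross-trait correlation above 0.999)
  are intercepted before optimization: the model covariance is singular
  there and the decomposition reduces *exactly* to the univariate ACE
  split of the shared trait, which is what `fit_bivariate_cholesky()`
  returns (with a warning) in that case;
* the first optimizer start is a Falconer-style moment estimate built from
  the double-entered cross-twin cross-trait correlations, which makes
  convergence robust across the admissible parameter space;
* confidence intervals on the proportions use a seeded nonparametric
  pair-resampling bootstrap (200 replicates by default). A profile
  likelihood on a ratio of seven parameters requires constrained
  optimization along a nonlinear manifold; the bootstrap is the more
  robust default for this derived quantity and is the package's CI method
  of record for proportions.

The `prop_a` estimator is a ratio and noticeably heavy-tailed when
$r_{ph}$ is moderate: at 20,000 + 20,000 pairs and $r_{ph} = 0.25$ its
spread across cohorts is roughly 0.03 with occasional multi-sigma
excursions. Recovery checks therefore average the estimate over replicate
cohorts (10 in the acceptance analyses), which estimates the same quantity
with Monte-Carlo error well inside the assessment band. A small downward
finite-sample bias (about 0.015) remains, caused by the $c^2 \ge 0$
boundary absorbing part of the genetic covariance; it vanishes as the
cohort grows.

## Polygenic scores

`gps_correlations()` and `multiple_gps_regression()` consume a ready matrix
of standardized polygenic scores — score construction from GWAS summary
statistics needs external genotype data and is deliberately out of scope —
and reproduce the two published operations: per-score Pearson correlations
with FDR control across the battery, and the joint least-squares fit whose
multiple correlation $R$ summarizes total measured-genetic prediction. The
synthetic battery generator draws mutually independent scores with
specified true correlations in the published sub-0.1 regime, so additivity
of $R^2$ is exact in the population and testable in samples. Ancestry
principal components are accepted as optional covariates but default off:
the synthetic cohort is homogeneous by construction, mirroring an analysis
restricted to a single genetic ancestry.

## The genetic-confounding sensitivity analysis

Gsens operates on the 3 x 3 correlation matrix of (polygenic score G,
exposure X, outcome Y). The unadjusted effect is $r_{xy}$; the adjusted
effect is the standardized partial regression coefficient

$$ B_{xy} = \frac{r_{xy} - r_{gx} r_{gy}}{1 - r_{gx}^2}, $$

and the attenuation is $100 (1 - B_{xy}/r_{xy})$ percent, reported signed
(suppression yields negative attenuation, never clipped). Observed
psychiatric polygenic scores capture far less variance than twin designs
attribute to genetics, so adjustment by the observed score understates
genetic confounding. The scenario machinery rescales the matrix as if the
score explained a target heritability $h^2$ of the *outcome*:

$$ r_{gy}' = \mathrm{sign}(r_{gy}) \sqrt{h^2}, \qquad
   r_{gx}' = r_{gx} \cdot \sqrt{h^2} / |r_{gy}|, $$

preserving the score's exposure/outcome association ratio, with $r_{xy}$
untouched and positive definiteness re-checked (a scaling that breaks it
means genetic confounding alone cannot account for the observed structure,
and the function says so). This outcome-anchored single-score variant is
the one implemented; the original sensitivity-analysis methodology offers
multi-score variants, which are out of scope here. `scenario_analysis()`
runs the observed, SNP-heritability and twin-heritability scenarios side
by side, the comparison usually shown as a red/blue/green forest plot
(`plot_gsens_scenarios()`).

Standard errors for $B_{xy}$ are the two-predictor regression standard
errors evaluated at the correlation matrix; optional bootstrap intervals
resample the sample correlation matrix through its exact Wishart
distribution (the sample covariance of $n$ centred trivariate-normal draws
is Wishart with $n-1$ degrees of freedom), which makes a
1,000-replicate parametric bootstrap essentially free and is verified to
give 93-97% coverage for $B_{xy}$ at $n = 6{,}000$.

One estimator property matters for interpreting scenario outputs: the
scaling factor $\sqrt{h^2}/|r_{gy}|$ multiplies the sampling noise of
$r_{gx}$ by the same large factor (about 7 when the observed score
explains 1% and the twin scenario 50%). A single cohort of 50,000
therefore yields twin-scenario attenuations of 100 +/- ~10 points under
pure confounding; scenario pattern checks consequently average over
replicate cohorts (40 in the acceptance analyses), giving Monte-Carlo
error of about 2 points.

## The synthetic cohorts

`simulate_univariate_twins()` and `simulate_bivariate_twins()` draw
pair-structured Gaussian phenotypes with exact ACE covariance algebra: A
factors correlate 1 (MZ) or 0.5 (DZ) across co-twins and $r_A$ across
traits, C is pair-shared, E individual. Default cohort dimensions follow
the published sample: roughly 2,900 MZ and 4,900 DZ pairs per measure,
ages drawn around 22.1 (SD 0.85), DZ sexes drawn independently with
same/opposite-sex labels assigned by outcome (no sex-limitation model —
justified by the <1% ANOVA shares). Skewness for testing the rank
transform is produced by a separate monotone exponential warp
(`warp_skew()`), so the latent ACE truth stays exact underneath.
`simulate_gps_cohort()` generates the Gsens ground truth: a latent genetic
factor with specified paths to exposure and outcome, and an observed score
calibrated to explain a chosen share of outcome variance. One global
integer seed drives everything; each generator derives its own stream from
it deterministically, so identical configurations are bit-identical.

What the generators deliberately do **not** emulate: genotype-level data
(no SNPs, no linkage disequilibrium), assortative mating,
gene-environment interaction, sex-limitation, item-level questionnaire
structure, non-Gaussian measurement scales, and missingness patterns.
Passing recovery tests therefore demonstrates that the estimators are
correct under the stated model, not that the model captures every feature
of real questionnaire data.

## Problem sizes used in the checks

Recovery and calibration analyses run at: 20,000 + 20,000 pairs for
univariate and bivariate recovery (5 and 10 replicate cohorts
respectively); 2,890 + 4,879 pairs and 500 replicates for profile-interval
coverage; 200 replicates of a 3 x 3 null design at n = 5,000 for FDR
calibration; 40 replicate cohorts of 50,000 for the confounded-scenario
pattern and one cohort of 200,000 for the causal pattern; 300 replicates
with 1,000 bootstrap draws at n = 6,000 for bootstrap coverage. These
sizes were chosen so that each check's Monte-Carlo error is several times
smaller than the property being asserted.

## Known limitations

* Complete-pair analysis only: partially observed pairs are dropped, not
  modelled (no FIML).
* No dominance (D) component, no sex-limitation or heterogeneity models,
  nothing beyond two traits in the Cholesky.
* The summary-level ACE fit treats printed intraclass correlations as
  sufficient statistics; as the online-victimisation row shows, rounded
  summaries need not encode the raw-data solution exactly.
* Gsens here is the single-score, outcome-anchored variant; exposures and
  outcomes enter through their correlation matrix only, so nonlinear or
  interactive confounding is outside the model.
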