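---
title: "Methods: bivariate twin modelling of synaesthesia-feature associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bivariate twin modelling of synaesthesia-feature associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlink)
```

## The scientific problem

Self-reported synaesthesia co-occurs with a range of neurodevelopmental and
psychiatric features (obsessive-compulsive, anxiety, depressive,
psychotic-like, ADHD, autistic, eating-disorder and (hypo-)mania-related
symptoms). The classical twin design separates the sources of such
associations: monozygotic (MZ) twins share essentially all segregating
genetic variants while dizygotic (DZ) twins share half on average, so the
pattern of cross-twin correlations identifies how much of a phenotypic
correlation is transmitted through additive genetic factors (A), environment
shared by co-twins (C), and environment unique to each twin (E).

`twinlink` implements the full analysis pipeline — from raw questionnaire
items to the bivariate decomposition — together with a synthetic cohort
generator, because registry twin data of this kind cannot be shared publicly.
Every stage is therefore testable end-to-end against known generating truth.

## The model

For a pair of traits measured on both members of a twin pair, the observation
vector is $(y_{11}, y_{21}, y_{12}, y_{22})$ (trait $i$, twin $j$). Each
trait decomposes as $y_i = a_i A_i + c_i C_i + e_i E_i$ with standardized
components $a_i^2 + c_i^2 + e_i^2 = 1$. The expected $4 \times 4$ covariance
is assembled from $2 \times 2$ blocks

$$\Sigma_z = \begin{pmatrix} W & B_z \\ B_z & W \end{pmatrix}, \qquad
W = \mathbf{A} + \mathbf{C} + \mathbf{E}, \qquad
B_{MZ} = \mathbf{A} + \mathbf{C}, \qquad
B_{DZ} = \tfrac12 \mathbf{A} + \mathbf{C},$$

where $\mathbf{A}$, $\mathbf{C}$, $\mathbf{E}$ are component covariance
matrices with factor correlations $r_A$, $r_C$, $r_E$ off the diagonal. The
additive-genetic cross-twin correlation is fixed at 1.0 (MZ) and 0.5 (DZ) —
the identifying assumption of the classical twin design; C is identical
within a pair and E independent. The model-implied phenotypic correlation
decomposes as

$$r_{Ph} = h_1 h_2 r_A + c_1 c_2 r_C + e_1 e_2 r_E,$$

and each term divided by $r_{Ph}$ is that component's *share* of the
association (the bivariate heritability decomposition, `decompose_rph()`).
Cross-twin cross-trait (CTCT) correlations obey the closed forms
$\mathrm{CTCT}_{MZ} = h_1 h_2 r_A + c_1 c_2 r_C$ and
$\mathrm{CTCT}_{DZ} = \tfrac12 h_1 h_2 r_A + c_1 c_2 r_C$, which the test
suite uses as oracles.

### Estimation

All models are fitted by full-information maximum likelihood (FIML): each
pair contributes the log multivariate-normal density of its *observed*
subvector, so item- or scale-level missingness needs no imputation. Internally
the pairs are grouped by missing-data pattern and reduced to per-pattern
sufficient statistics (count, mean, scatter), which makes the cost of a
likelihood evaluation independent of sample size — the engine fits cohorts of
8000 pairs in well under a second.

Three parameterizations of the same covariance family are provided:

* **Cholesky** (default): each component matrix is $LL^\top$ with $L$ lower
  triangular — positive semi-definiteness by construction, no constraint
  corners.
* **Correlated factors**: per-trait component variances plus factor
  correlations, the form in which results are reported. The two are
  mathematically equivalent and the test suite asserts identical $-2\ell$ to
  $10^{-6}$ on every dataset it touches.
* **Proportions/shares** (internal): total variance, standardized component
  proportions, and either factor correlations or ($r_{Ph}$, component
  shares) as explicit coordinates. Profile confidence intervals fix one
  coordinate exactly and re-minimize over the rest, avoiding penalty
  approximations.

Optimization uses bounded quasi-Newton (`nlminb` with an L-BFGS-B polish),
restarted from the incumbent until the objective is stable to $10^{-6}$, with
deterministic jittered restarts on failure. One numerical subtlety deserves
note: in explicit-correlation parameterizations, when a component variance
sits on its zero boundary the likelihood is flat in that component's factor
correlation, and a gradient method cannot discover that a small variance with
the *opposite* correlation sign fits better (the Cholesky form has no such
corner). The fitter therefore retries from bumped-variance starts with the
factor correlation at both signs before accepting a solution.

### Saturated models and assumption tests

`fit_saturated()` fits the per-zygosity multivariate normal at three
constraint levels: unconstrained; means/variances equated across twin order
(with the two CTCT covariances equated); and additionally equated across
zygosity. Likelihood-ratio tests between levels are the standard checks of
the twin-design assumptions. Twin and CTCT correlations are extracted from
the zygosity-constrained fit, with profile-likelihood CIs. With complete
data the unconstrained ML solution is closed-form (sample means, $n$-divisor
covariance) and is used directly.

A bivariate ACE model with free A, C and E cross-blocks has the same number
of free parameters (11) as the zygosity-constrained saturated model — it is a
reparameterization up to the component positive-semi-definiteness
constraints. The "ACE vs saturated" comparison is therefore made against the
fully unconstrained saturated model (28 parameters, $\Delta df = 17$); a
worse ACE fit can arise only from those boundary constraints, which is also
why such a model is reported rather than discarded.

### Model selection and inference

Nested AE/CE/E models are compared to ACE by likelihood-ratio tests with a
central $\chi^2$ reference ($\Delta df$ = difference in free parameter
counts). Variance components on the zero boundary make this reference
conservative for dropping C; a boundary-corrected mixture reference was
considered and not used, matching the dominant convention in twin modelling.
Among nested models not significantly worse than ACE (at $\alpha = 0.05$),
the pipeline selects the one with fewest parameters, breaking ties by AIC
($-2\ell + 2k$, reported with every fit).

Profile-likelihood 95% CIs place the bounds where the profiled $-2\ell$
exceeds its minimum by $\chi^2_1(0.95) = 3.841$; bound search walks outward
from the estimate and refines by root-finding, warm-starting each constrained
refit from the previous optimum. When the profile never crosses the
threshold before a parameter-space edge (components in $[0,1]$, correlations
in $[-1,1]$) the edge is returned and flagged open.

One statistical property worth knowing: when the true C is zero, a free-C
ACE fit estimates $\hat c^2$ on its boundary with positive truncation bias
(measured here: about $+0.02$ at 4000+4000 pairs) and correspondingly
shrinks $\hat a^2$. This is a property of boundary maximum likelihood, not
of the optimizer; the parameter-recovery acceptance check therefore fits the
generating (AE) model, for which bias is below 0.003, while separate tests
confirm the free ACE fit drives familial components to zero on E-only data.

## The synthetic cohort generator

`study_config()` encodes the study conditions the pipeline is designed for:
2572 twin pairs (814 MZ, 923 same-sex DZ, 835 opposite-sex DZ) assessed at
age 18 on an 8-item synaesthesia screen (responses no / to-some-extent / yes,
weighted 0 / 0.5 / 1) and eight symptom scales with the published item
counts (OC 12, anxiety 38, depression 11, PLE 6, ADHD 18, autism 12, eating
23, (hypo-)mania 13). Defaults were fixed once from the published
descriptive and twin-model tables:

* **Internal consistency**: per-scale Cronbach's alpha targets 0.65–0.93.
  Item noise is calibrated by inverting the Spearman–Brown/alpha relation
  through the *exact* ordinal inter-item correlation under the bivariate
  normal (a one-dimensional orthant-probability integral), so observed
  alphas land within about 0.01 of target.
* **Skew**: the synaesthesia, OC, PLE and autism scores are generated
  right-skewed (item thresholds equally spaced on an exponentiated latent
  scale), the rest approximately symmetric — so the skew-gated $\log(1+x)$
  rule fires exactly where it did in the study. Because the discretization
  is a monotone function of latent-plus-noise, thresholding on the
  transformed scale is equivalent to transforming after the fixed effects,
  and the preprocessing log approximately restores symmetry.
* **ACE structure**: heritability 0.45 for the screen score and 0.50 for the
  feature scales, $C = 0$ throughout (the study estimated shared environment
  as negligible); cross-trait genetic correlations graded 0.07–0.33 and
  non-shared-environment correlations 0.07–0.18 per the published bivariate
  estimates, wired through a single-factor ("hub") structure that guarantees
  a positive semi-definite latent covariance. Opposite-sex DZ pairs use the
  same genetic correlation as same-sex DZ pairs (no sex-limitation
  modelling, matching the study's pooling).
* **Missingness**: item-level missing/"don't know" rates chosen so that
  roughly 11% of individuals fail the screen's >1-missing-item rule and
  0.4–6% of scores fail the <80% completeness rule, bracketing the published
  per-scale inclusion percentages; a 0.8% fraction of same-sex pairs is
  relabelled "undetermined zygosity" for the exclusion filter to remove.
* **Fixed effects**: small sex effects (0–0.3 SD) and a 0.02 SD/year birth
  year trend, removed again by the residualization stage.

What the generator does *not* emulate: marginal item distributions beyond
the induced skew (the study publishes only item counts and alphas), scale
hierarchies/subscales, sex-limitation of genetic effects, dominance,
assortative mating, and any non-normality of the latent liabilities beyond
the monotone transform. Passing tests therefore demonstrate correctness of
the *methods* under a realistic data-generating process, not claims about
the registry data themselves. One consequence visible in the synthetic
results: item-level measurement error loads into E, attenuating *observed*
score correlations by roughly the geometric mean of the scale reliabilities
(about 0.65 here), while leaving $r_A$ and the A/E shares — which are
scale-free in the numerator and denominator alike — essentially unchanged.

## Preprocessing rules

* Scale scores: missing if less than 80% of items answered (strictly —
  exactly 80% is included); otherwise prorated, `n_items` times the mean of
  answered items. The study states only the exclusion rule; prorating was
  chosen over raw summation to avoid downward bias for near-complete
  responders and is flagged in the run provenance.
* Synaesthesia screen: summed with unanswered items contributing 0; an
  individual is excluded outright when more than one of the eight items is
  missing or answered "don't know".
* Exclusion cascade, in order: screen failures, then individuals whose
  co-twin is absent or excluded, then undetermined-zygosity pairs. The tally
  partitions the input individuals exactly (asserted in tests).
* Skewness uses the adjusted Fisher–Pearson $G_1$ estimator; alpha CIs use
  Feldt's F-distribution method — both the common package defaults, since
  the study names neither.
* Residualization regresses each (possibly log-transformed) score on sex and
  birth year jointly over all included individuals, then standardizes the
  residuals. The transform gate applies only to raw non-negative scores, so
  re-running preparation on prepared values never re-applies the log.

## Correlation analysis

Phenotypic correlations use one randomly selected twin per pair
(Bernoulli(0.5), seeded independently of the cohort) to respect
within-family dependence, with Fisher-z 95% CIs and pairwise-complete
deletion. The strongest correlation is compared to each other one with the
Pearson–Filon (1898) statistic for two overlapping dependent correlations;
$n$ is conservatively the minimum of the three pairwise sample sizes, and a
Bonferroni flag uses the family of eight primary correlations.

## Problem sizes used in validation

The test suite exercises the generator's moment structure at 5000 pairs per
zygosity group (tolerance ±0.04), parameter recovery over 20 replicate
cohorts of 4000+4000 pairs, profile-CI coverage over 500 replicates of
1000+1000 pairs, Pearson–Filon calibration over 5000 null replicates of
n = 1000 (plus a 10,000-replicate parametric bootstrap), and the structural
end-to-end pattern over ten full cohorts at the study's 2572-pair
composition — sizes chosen to keep Monte Carlo error comfortably inside each
assertion's tolerance.

## Known limitations

* Bivariate only (plus the univariate special case); no trivariate or higher
  Cholesky systems, no dominance (ADE), no sex-limitation or moderation
  models.
* LRT p-values for boundary components are conservative (no mixture
  correction), as discussed above.
* The E component absorbs measurement error by construction; nothing in the
  pipeline separates the two, exactly as in the underlying design.
* Ordinal items are scored as sums and modelled as Gaussian after
  transformation; no threshold (liability) model for the items themselves.
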