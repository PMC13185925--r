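---
title: "Models and methods in twinmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in twinmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

twinmediate asks a question that ordinary mediation analysis cannot answer:
when an exposure (here, childhood maltreatment), a set of intermediary
phenotypes (personality and mental-health composites), and an outcome
(intimate partner violence victimization) all run in families, how much of
the exposure-outcome association survives once their shared genetic and
environmental etiology is modelled — and how much of the surviving effect
travels through the intermediaries? This vignette documents the models, the
synthetic cohort they are validated on, and the numerical choices behind
them.

## The path-model engine

All models are expressed in RAM (reticular action model) form: a matrix of
directed paths $A$, a symmetric matrix $S$ of variances and covariances of
exogenous terms, a selection of observed variables $F$, and a mean vector.
The implied moments are

$$\Sigma = F\,(I-A)^{-1} S (I-A)^{-\top} F^\top, \qquad
  \mu = F\,(I-A)^{-1} m.$$

Entries of $A$, $S$ and $m$ are fixed values or labelled free parameters;
entries sharing a label share a parameter (equality constraints across
twins and groups), optionally scaled per group. That device carries the
whole twin algebra: the cross-twin additive-genetic covariance is the same
parameter scaled by 1 in MZ and 0.5 in DZ pairs.

Estimation is full-information maximum likelihood. Each row (a twin pair
for twin models, an individual for phenotypic models) contributes the
multivariate-normal density of its *observed* variables only, so item
nonresponse and structurally absent variables need no imputation. Rows are
pooled by missing-data pattern and each pattern's contribution is reduced
to sufficient statistics $(n_p, \bar x_p, S_p)$, which makes the cost of an
objective evaluation independent of sample size — the property that keeps
the seeded replication suites (hundreds of refits) tractable on one core.

Numerical choices:

* optimizer `nlminb` (quasi-Newton with box bounds), relative tolerance
  `1e-8`, up to 2000 iterations; on failure up to 5 jittered restarts, then
  an honest `converged = FALSE` with diagnostics, never a silent answer.
  `nlminb` occasionally reports "false convergence" at a genuine optimum;
  a solution is accepted when its numerical gradient is negligible
  relative to the objective scale.
* standard errors from the inverse numerical Hessian of $-2\ell$; Wald 95%
  intervals. Where rows are individuals nested in families, a CR1-adjusted
  sandwich over family-level score contributions replaces the Hessian
  covariance (the clustering correction used for the phenotypic SEMs).
  When a solution sits on a bound (a variance path at zero) the Hessian
  can be singular; effect extraction then degrades to point estimates with
  missing intervals and a warning rather than failing.
* non-positive-definite implied covariances are handled by a large
  penalized objective value, which steers the optimizer back into the
  admissible region.
* derived quantities (variance proportions, standardized paths, products
  $ab$, sums $\sum ab$) get first-order delta-method intervals computed on
  the standardized scale, so the standardized indirect effect is exactly
  the product of its standardized ingredients.

ACE components are parameterized through path coefficients whose squares
are the variance components, bounded below by zero. This avoids
negative-variance pathologies at the cost of a sign indeterminacy, which is
resolved by reporting squares and magnitudes.

## Twin models

The univariate ACE model decomposes a trait's variance using the MZ/DZ
covariance contrast (A covariance 1 vs 0.5, C 1 vs 1, E 0). The bivariate
model uses a *correlated-factors* parameterization rather than a Cholesky:
the genetic, shared- and nonshared-environmental correlations $r_g$, $r_c$,
$r_e$ appear directly as free parameters, matching the quantities one wants
to report. Falconer's moment estimator ($h^2 = 2(r_{MZ}-r_{DZ})$) is kept
in the package as an independent oracle; the likelihood fits must agree
with it on large balanced complete data, and the tests enforce that.

## MR-DoC models

The MR-DoC model treats a polygenic score (PGS) for the exposure as a
genetic instrument inside a direction-of-causation twin model. Per twin:
an instrumental path PGS $\to$ exposure, a causal path exposure $\to$
outcome, and a pleiotropic path PGS $\to$ outcome; exposure and outcome
carry A/C/E components whose A and C parts are correlated across traits
(the confounding the design exists to absorb). Identification follows the
standard convention: with the pleiotropic path free, the E-correlation
between exposure and outcome is fixed at zero; the builder refuses to free
both. The PGS is exogenous with cross-twin covariance fixed at 1 (MZ) and
0.5 (DZ, random mating; configurable) and is *not* decomposed into ACE.
Because MZ co-twins carry one and the same score, the pair-level MZ
likelihood would be singular with both copies present; the score enters the
MZ likelihood once per pair, which the pattern-wise FIML handles exactly.

Mediation variants insert observed composites or two latent factors between
exposure and outcome (`a`, `b`, and `c'` paths, plus PGS $\to$ mediator
pleiotropy). Cross-trait genetic confounding is carried by a triangular
Cholesky system ordered (exposure, mediators, outcome), which keeps the A
covariance positive semi-definite with any number of mediators; shared
environment gets the same treatment over the traits that retain it, and all
cross-trait E covariances are fixed at zero. Per-mediator C components are
dropped by default (`drop_c`), mirroring the practice of constraining
nonsignificant shared-environment terms to stabilise estimation; latent
factors are AE. Latent factors are scaled by a marker indicator, and
indicator uniquenesses carry their own AE split so that cross-twin residual
correlation in the indicators is not misattributed to the factors.

A note on one diagnostic: with the E-correlation fixed at zero, the causal
path remains identified through the twin-covariance (DoC) side even when
the instrument is useless, so removing the instrument does not blow up the
causal path's standard error. The weak-instrument condition is therefore
reported as a flag (instrument z below $\sqrt{10}$, the F ≈ 10 rule) rather
than diagnosed from the standard error.

Significance of the causal path is assessed by likelihood-ratio test
(`causal` free vs fixed at zero) rather than by its Wald z. In simulation
the Wald statistic for this parameter is under-dispersed — its standard
error co-varies with the estimate's magnitude along the likelihood ridge
shared with the genetic confounding correlation — and rejects at roughly
2-3% instead of the nominal 5%, while the LRT holds its size with uniform
null p-values. Wald/delta intervals are still reported for effect sizes;
the LRT is used wherever a decision is made about the causal path.

## Stratified equality tests

Whether mediation differs between higher- and lower-exposure groups is
tested by expanding a two-group spec into zygosity-by-stratum groups and
comparing, by likelihood-ratio test, a version with the mediation paths
(`a`, `b`, `c'`) free per stratum against one with them equated. Pairs are
stratified by their pair-mean exposure against the cohort median
(`pair_strata()`), which keeps families intact; the assignment rule for
discordant pairs is a design choice documented here, not a published one.

Stratifying on the exposure truncates its distribution within strata, so
the within-stratum normality assumption is an approximation exactly as it
is in the applied literature. The package's calibration suite therefore
validates the *test machinery* under exogenous (randomly assigned) strata,
where the null is clean: there the p-values must be uniform, and they are
(Kolmogorov–Smirnov check over 200 seeded replicates). Power is
demonstrated for an a-path contrast of 0.34 vs 0.23 at the cohort's
default per-stratum size.

## The synthetic cohort

The generator draws twin pairs from the exact multivariate-normal latent
model the estimators assume, built in layers: a standardized PGS (shared
exactly within MZ pairs, correlated 0.5 in DZ); a structural layer
(exposure, two mediator factors, outcome) whose residuals have
ACE-structured cross-twin and cross-trait covariance; mediator composites
loading on the two factors with AE-structured uniquenesses; and optionally
an ordinal measurement layer — items at reliability 0.8 cut into five
categories (right-skewed thresholds for exposure and outcome, symmetric for
mediators), thinned by missing-completely-at-random nonresponse (2% per
item) and averaged into composites requiring at least half the items.
Residual variances are solved numerically so every structural trait has
unit variance, which makes the configuration values *standardized* paths —
directly comparable to the recovered standardized estimates.

The defaults are the study conditions of the motivating cohort: 1988 MZ and
3683 DZ pairs; exposure ACE about a third each; outcome ACE
(0.17, 0.07, 0.76); instrumental path 0.09; pleiotropic path to the outcome
0.06 and to the factors (0.04, 0.03); factor-level mediation a = 0.29
(both factors), b = (0.17, 0.14), c' = 0.05 — a total causal effect of
0.14; 18 mediators in the published two-factor grouping. The published
factor loadings are not in the main text, so magnitudes (0.45–0.78, signs
following the reversed-keyed traits) are the implementer's choice, stated
in `default_factor_loadings()`. Residual A and C confounding correlations
default to 0.17, derived analytically (not by tuning against tests) so the
implied phenotypic exposure-outcome correlation equals the published 0.23
given the causal chain above. Item counts (8 exposure, 6 outcome, 5 per
mediator) follow the instruments' structure; thresholds approximate the
right-skewed score distributions whose exact tables are unavailable.

What the generator does *not* emulate: non-random missingness, sex
limitation (the five zygosity groups are collapsed to MZ/DZ), assortative
mating, SNP-level genotypes, and real measurement non-normality beyond
ordinal cutting. Passing tests therefore show that the estimators invert
the assumed data-generating process correctly — not that the assumptions
hold in any particular real cohort.

Recovery studies use the generator's continuous (`measurement = "latent"`)
scores: discretizing into ordinal items attenuates covariances, so
composite-based estimates recover the *composite-scale* parameters, not
the latent generating values. That attenuation is a property of the
measurement layer, quantified separately by the distribution checks on the
ordinal cohort, and is deliberately kept out of the structural recovery
suites.

## Effect decomposition conventions

For every mediation model the package reports standardized $a$, $b$, $c'$,
per-mediator $ab$, the total indirect effect $\sum ab$, the total effect
$c = c' + \sum ab$, and the percentage mediated

$$100 \cdot \frac{\sum ab}{\sum ab + c'},$$

i.e. the indirect share of the total effect *recomposed from its parts*.
Recomposition matters for reproducing printed tables: rounding the inputs
first gives slightly different percentages (e.g. 0.10 and 0.04 give 71.4%,
printed as 72% from unrounded internals), and the package reports the
unrounded value rather than forcing agreement. Significance flags use the
single Bonferroni threshold 0.05/18 ≈ 0.003 across all mediation analyses.

The association screen implements the "GEE" step as least squares on
z-scored variables with a family-clustered CR1 sandwich — identical point
estimates to a GEE with independence working correlation, and the
clustered type-I error is verified by simulation (within [3.5%, 6.5%] at
nominal 5%).

## Problem sizes and runtime

The validation suites are sized to run on one core in minutes: ACE
recovery uses 20 replicates of 5000+5000 pairs; the bivariate and MR-DoC
recovery fits use 4000–5000 pairs per zygosity; the causal type-I study
uses 200 replicates of 600+900 pairs; LRT calibration uses 200 replicates
of 1000+1800 pairs with an AE-only single-mediator model and fixed zero
means (the data are generated mean-centred); LRT power uses 25 replicates
at the default per-stratum size (994 MZ + 1841 DZ). Sufficient-statistic
FIML makes each fit's cost essentially independent of these sample sizes.

## Known limitations

* Confidence intervals are Wald/delta; profile-likelihood intervals are a
  natural extension for variance proportions near their bounds, where Wald
  intervals are clipped to [0, 1] and flagged unstable.
* The engine's gradients are numerical; models far larger than the ones
  here (hundreds of free parameters) would want analytic derivatives.
* Reverse-direction MR-DoC (outcome as exposure) is out of scope: there is
  no published instrument for the outcome.
* Multiple imputation is not implemented; FIML handles the MCAR
  missingness the generator produces, but informative missingness would
  require different machinery.
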