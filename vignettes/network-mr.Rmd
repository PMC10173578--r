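---
title: "Network Mendelian randomization with netMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network Mendelian randomization with netMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netMR)
```

## The problem netMR addresses

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone, using genetic
variants as instrumental variables: a SNP robustly associated with the
exposure is assumed to affect the outcome only through it. *Network* MR
extends this to a mediation diagram — one exposure, several candidate
mediators, one outcome — and asks how much of the exposure's total effect
flows through each mediator. The motivating application is the effect of
educational attainment on stroke risk, with hypertensive disease, body
mass index, smoking behaviour and television watching (a proxy for
physical inactivity) as modifiable mediators; the methods are generic.

All causal effects are computed and stored on the linear scale of the
outcome — the log-odds scale when the outcome is binary. Odds ratios are a
presentation transform only (`orScale()`), never an estimation scale.

## Estimation model

For SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association
with the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) with the
outcome, aligned to a common effect allele.

**IVW.** The inverse-variance-weighted estimate is the zero-intercept
weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights
$w_j=\sigma_{Yj}^{-2}$:
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
\hat\beta_{Xj}^2$. Under the default multiplicative random-effects model
the fixed-effect SE is inflated by $\max\{1, \sqrt{Q/(n-1)}\}$, where $Q$
is Cochran's statistic at the estimate; the floor means heterogeneity can
widen but never narrow the interval. With one SNP, IVW reduces to the
Wald ratio $\hat\beta_{Y}/\hat\beta_{X}$ with first-order SE
$\sigma_Y/|\hat\beta_X|$.

**MR-Egger.** The same regression with a free intercept, after orienting
every pair so $\hat\beta_{Xj}\ge 0$ (without this convention the
intercept is not interpretable as average directional pleiotropy). The
intercept estimates the mean direct (pleiotropic) effect; slope and
intercept use standard weighted-regression t inference on $n-2$ degrees
of freedom with the *estimated* residual scale. We deliberately do not
floor the Egger residual scale at 1: flooring makes the intercept test
conservative (empirical size about 0.015 at nominal 0.05 in our null
simulations), while the unfloored t test is exactly calibrated. The IVW
slope keeps its floor because there the random-effects model is a
variance inflation, not a test statistic.

**Maximum likelihood.** Each SNP's observed pair is modelled as
independent normals centred at $(\gamma_j, \theta\gamma_j)$ with known
SEs. Profiling out $\gamma_j$ gives
$-2\,\ell_p(\theta) = \sum_j (\hat\beta_{Yj}-\theta\hat\beta_{Xj})^2 /
(\sigma_{Yj}^2+\theta^2\sigma_{Xj}^2)$, maximized by golden-section
search on a bracket of $\pm 10$ IVW standard errors around the IVW
estimate; the SE comes from the numerical observed information.

**MR-RAPS.** The robust adjusted profile score solves
$\sum_j \psi(t_j(\theta))\,u_j(\theta)=0$ with standardized residuals
$t_j=(\hat\beta_{Yj}-\theta\hat\beta_{Xj})/\sqrt{\sigma_{Yj}^2+
\theta^2\sigma_{Xj}^2+\tau^2}$, $\psi$ the identity (`l2`) or a Huber
score (constant 1.345, configurable), and $u_j = \partial(-t_j)/
\partial\theta$. With `overdispersion = TRUE`, $\tau^2\ge 0$ is estimated
jointly so that the mean of $\psi(t_j)t_j$ matches its standard-normal
expectation (1 for `l2`, $2\Phi(k)-1$ for Huber). The root is bracketed
around the IVW estimate, the bracket widened once (by a factor 4) before
failing; the SE is the sandwich estimate.

## Instrument selection

Instruments are selected per contrast — for whichever trait plays the
exposure in that contrast — by (i) genome-wide significance
($P<5\times10^{-8}$ by default), (ii) greedy LD clumping at
$r^2<0.001$ within a 10 Mb window, and (iii) an optional file-based
exclusion list for SNPs associated with confounders (standing in for an
interactive database lookup). Clumping sorts by ascending p-value with
ties broken by position then SNP id, so the result is independent of
input row order; when no LD matrix is available the fall-back treats any
same-chromosome SNP within the window as correlated, which is
conservative in the right direction (it can only drop more SNPs). The
window is interpreted as $|pos_i-pos_j|\le 10^7$ on the same chromosome,
inclusive. Instrument strength is screened with the squared-t
approximation $F_j=(\hat\beta_{Xj}/\sigma_{Xj})^2$ (the variance-explained
form $F = r^2(n-2)/(1-r^2)$ is essentially equivalent for single SNPs at
GWAS scale); a set with mean $F\le 10$ is flagged weak.

## Harmonization

Outcome associations are aligned to the exposure's effect allele: swapped
alleles negate the outcome beta and reflect its frequency, complementary
strand encodings are translated first, and palindromic SNPs (A/T, C/G)
are dropped by default. Under `infer_by_eaf`, palindromic SNPs are
aligned by frequency agreement, but only when both frequencies are
present and further than `eaf_window = 0.08` from 0.5 — so palindromic
SNPs with minor-allele frequency above 0.42 are never inferable. Missing
frequency always drops a palindromic SNP. Positions are 1-based
throughout. Every drop is recorded with a reason and the counts are
carried in the harmonized set's provenance.

## Sensitivity analyses

* **Cochran's Q** in the IVW ($df=n-1$) and Egger ($df=n-2$) frameworks,
  computed by the same code path as the residual sums used for SE
  scaling. Heterogeneity is reported, never used to auto-drop SNPs.
* **Leave-one-out** IVW refits, flagging omissions whose interval
  excludes the pooled estimate or flips its sign.
* **PRESSO-style outlier analysis**: the observed statistic is the
  weighted leave-one-out residual sum of squares; its null distribution
  comes from `n_sim` parametric draws (default 1000) under the fitted
  model with a mandatory seed. Per-SNP empirical p-values are
  Bonferroni-adjusted and only acted on when the global test is
  significant; the distortion test compares the raw-vs-corrected shift
  against shifts from removing random subsets of the same size.
  Identical seeds give bit-identical results.
* **Steiger directionality**: per-SNP variance explained is
  $r^2_j = z_j^2/(z_j^2+n)$ with $z_j=\hat\beta_j/\sigma_j$; binary
  traits use the effective sample size $4/(1/n_{case}+1/n_{control})$
  (this matters here because the outcome is a disease trait, and tools
  differ on this point). The test compares Fisher-transformed $|r|$
  across the two independent samples.
* **Analytic power** for a binary outcome under the linearized logistic
  approximation: the IVW SE on the log-odds scale is
  $1/\sqrt{nK(1-K)R^2}$, so the two-sided power at level $\alpha$ has
  non-centrality $\ln(OR)\sqrt{nK(1-K)R^2}$. At $OR=1$ the power equals
  $\alpha$ exactly. Rather than asserting a closed form from elsewhere,
  the formula is validated in the test suite against a Monte-Carlo
  oracle that simulates summary statistics and runs the IVW test (5,000
  replicates at $n=50{,}000$, $K=0.1$, $R^2=0.02$, $OR=1.3$; agreement
  within $\pm 0.03$).

## Multivariable MR and mediation

The multivariable IVW model regresses outcome associations on the
SNP-by-exposure matrix (zero intercept, weights $\sigma_{Yj}^{-2}$); each
coefficient is the direct effect of that exposure conditional on the
others. SEs come from the weighted normal equations with the same
multiplicative inflation floored at 1, so the one-exposure case
reproduces univariable IVW exactly. The instrument pool is the union of
each exposure's selected instruments, re-clumped jointly using each SNP's
best exposure p-value, and all columns are re-aligned to the outcome's
effect alleles so the matrix shares one allele frame.

**Proportion mediated.** The default mediation method is the *difference*
method (two-step multivariable MR): indirect $=$ total $-$ direct, and
$PM = 100\,(\text{total}-\text{direct})/\text{total}$, reported in
percent with two decimals. This choice is not arbitrary: from the
published odds-ratio table of the motivating study (total 0.711;
adjusted 0.836, 0.774, 0.750, 0.716; jointly adjusted 0.901), the
difference method reproduces the published PM values (47.35%, 24.74%,
15.72%, 2.29%, 69.32%) to within 0.24 percentage points — the residual
being 3-decimal OR rounding, which `workedExampleReport()` verifies by
propagating $\pm 0.0005$ OR perturbations — whereas the product of
univariable coefficients does not (hypertension gives roughly 37% by
product). The product method is still provided (`mediationProduct()`)
for DAGs where it is the natural estimand.

PM uncertainty defaults to a delta-method SE treating total and direct
estimates as uncorrelated. That independence assumption is knowingly
wrong — the two share instruments — so a bootstrap-over-instruments
alternative (`pmBootstrap()`) is provided and both can be reported. PM
is deliberately left unbounded (it may be negative or exceed 100%) with
a quality flag, rather than clipped.

## The synthetic-data generator

`simulateStudy()` produces two-sample GWAS summary statistics under a
known DAG so the whole pipeline can be exercised, and its operating
characteristics measured, without any real GWAS download. Design
choices:

* Statistics are generated **directly on the summary scale**, not via
  individual-level genotypes: each trait's instruments receive true
  effects sized to the trait's variance explained, effects propagate
  through the DAG by path products, and each GWAS table adds independent
  noise at the theoretical SE ($1/\sqrt{2f(1-f)n}$ for continuous
  traits; the linearized logistic $1/\sqrt{2f(1-f)nK(1-K)}$ for the
  binary outcome). Exposure and outcome tables never share noise draws,
  enforcing two-sample independence. Individual-level simulation is out
  of scope.
* Allele frequencies are uniform on $[0.05, 0.5]$; palindromic SNPs are
  generated at a configurable rate to exercise the harmonizer.
* Pleiotropic offsets are applied **on the exposure-increasing allele
  direction**. With random-sign instruments, offsets applied on the
  arbitrary coded allele would cancel under the Egger orientation
  convention, making "directional" pleiotropy undetectable by
  construction; applying them on the exposure-increasing direction makes
  a nonzero mean offset genuinely directional.
* The default design mirrors the motivating study's shape: one
  continuous exposure, four mediators, a binary outcome with case
  fraction 0.1 (the study outcome has roughly 41k cases in 447k
  samples), 100,000 samples and 50 instruments per trait each explaining
  5% of trait variance, and edge coefficients
  $a=(-0.50,-0.40,-0.40,-0.25)$, $b=(0.20,0.15,0.12,0.08)$,
  $c=-0.1228$, giving a true combined PM of 65.0%. SNP positions are
  spaced more than two clump windows apart so distance-only clumping
  retains all designed instruments.

What the generator does **not** emulate: LD beyond block-diagonal toy
matrices, sample overlap between the two samples, allele-frequency
mismatch between studies, winner's-curse selection of instruments, and
non-collapsibility of the odds ratio (outcome effects are generated
linearly on the log-odds scale). Passing recovery tests therefore shows
the estimators are correct under the stated model, not that real-data
biases are absent.

## Numerical choices and degenerate inputs

* P-values are clamped to the smallest positive double so extreme z
  scores never produce an exact zero (the record invariant is
  $p\in(0,1]$).
* Ties in clumping break by position then SNP id; the kept list is
  returned in selection order.
* A perfect Egger fit (zero residual) yields a zero SE; the t statistic
  is then taken as $\pm\infty$ (p effectively 0) or 0 when the
  coefficient is also 0 (p = 1).
* `mediationDifference()` refuses a zero total effect (PM undefined);
  `trueEffects()` flags the same condition instead of dividing by zero.
* All stochastic routines (`mrPresso()`, `pmBootstrap()`,
  `simulateStudy()`, the pipeline) require an explicit seed, run under a
  temporary RNG state, and restore the caller's stream; the pipeline
  derives per-stage seeds from its master seed with a Lehmer step and
  logs each one.

## Validation design and problem sizes

The test suite checks every estimator against an independent oracle
(closed-form weighted least squares via explicit normal equations, dense
grid searches of the ML profile likelihood and the RAPS score root, an
exhaustive greedy re-implementation of clumping) and measures operating
characteristics by simulation: type-I error of Cochran's Q and the Egger
intercept over 2,000 null replicates (fixed exposure betas — the
no-measurement-error regime where the chi-square and t references are
exact); PRESSO detection of a 10-SE planted outlier and null calm over
200 seeded runs each; recovery of the designed proportions mediated over
200 generated studies at the default design; and the power formula
against its Monte-Carlo oracle over 5,000 replicates. These sizes keep
the full suite around a minute on a single core while leaving
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The delta-method PM interval ignores the total/direct correlation;
  the bootstrap alternative resamples the two instrument sets
  independently, which matches (rather than corrects) that assumption.
* No weighted-median or mode estimators, no correlated-instrument
  (generalized) IVW, no radial variants, no funnel asymmetry beyond the
  Egger intercept.
* No genome-build liftover, GWAS-VCF ingestion, or reference-panel LD
  computation: LD matrices and exclusion lists are inputs.
* Mediator-mediator interactions are not modelled; the combined-mediator
  decomposition assumes the joint multivariable model captures their
  overlap.
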