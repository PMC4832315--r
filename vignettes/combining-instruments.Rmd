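---
title: "Combining multiple genetic instruments from summarized data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining multiple genetic instruments from summarized data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcombine)
```

## The estimation problem

A valid genetic instrument is associated with the exposure of interest,
independent of confounders, and affects the outcome only through the
exposure. Under linear, homogeneous effects, each variant k identifies the
same causal slope through its ratio estimate
$\hat\beta_{Yk}/\hat\beta_{Xk}$, where $\hat\beta_{Xk}$ and
$\hat\beta_{Yk}$ are the per-allele associations with exposure and outcome
and $\sigma_{Xk}, \sigma_{Yk}$ their standard errors. `mrcombine` is about
combining K such instruments into one estimate when only these summarized
quantities (and possibly the correlation matrix between variants) are
available. Standard errors of the associations are treated as known
constants throughout — the usual convention for published summary
statistics, slightly anti-conservative in principle but with near-nominal
coverage in realistic settings.

Two families of combination exist, and they behave differently when
instruments are weak:

* the **allele score** family collapses the variants into a single
  composite instrument with *pre-specified* weights $w_k$. Because the
  weights carry no information from the analysis sample, a score built
  from equal or externally estimated weights behaves like one instrument,
  and its estimate is median-unbiased even when each variant is weak;
* the **summary statistic (IVW)** family weights each variant's ratio
  estimate by its precision, implicitly using $\hat\beta_{Xk}$ itself as a
  weight. When those weights come from the analysis sample ("crude"
  weights) the estimate inherits the weak-instrument bias of multivariable
  two-stage least squares, which points toward the confounded
  observational association. When they come from an independent sample,
  sampling noise in the weights acts like classical measurement error in a
  regressor and attenuates the estimate toward the null
  (regression dilution).

The package implements both families, their extensions to correlated
variants, a likelihood-based alternative, and the simulation machinery to
quantify these biases.

## Estimators

**Summarized allele score** (`allele_score_estimate()`):
$$\hat\beta_{score} = \frac{\sum_k w_k \hat\beta_{Yk}\sigma_{Yk}^{-2}}
{\sum_k w_k \hat\beta_{Xk}\sigma_{Yk}^{-2}}.$$
The derivation replaces each variant's dosage variance by a multiple of
$\sigma_{Yk}^{-2}$, valid when every variant explains little outcome
variance. Nothing in the formula involves between-variant correlations,
so the *point estimate* is unchanged under linkage disequilibrium; only
its standard error is affected.

Its delta-method variance (`allele_score_se()`) is, with
$A = \sum_k w_k\hat\beta_{Yk}\sigma_{Yk}^{-2}$,
$B = \sum_k w_k\hat\beta_{Xk}\sigma_{Yk}^{-2}$,
$C = \sum_k w_k^2\sigma_{Yk}^{-2}$:
$$\mathrm{var} = \frac{C}{B^2} + \frac{A^2C}{B^4}
  - 2\theta_S\frac{AC}{B^3},$$
where $\theta_S$ is the correlation between numerator and denominator
(zero in a two-sample analysis, which is the default; in one-sample use it
can be set to the observed exposure–outcome correlation, with
`theta_s_sweep()` for sensitivity). Three properties of this expression
are worth knowing and are exercised by the test suite:

* with $w_k = \hat\beta_{Xk}$ its leading term equals the IVW standard
  error exactly, so the two methods give identical tests in that case;
* it is an approximation that substitutes $C$ for the variance of the
  denominator sum. A side effect is that the second term carries
  $(A/B)^2$ — the squared causal estimate, a dimensioned quantity — so
  the full expression is not equivariant under rescaling of the outcome
  units (the leading term is). We keep the expression as published rather
  than substituting a $\sigma_{Xk}$-based variance, trading exactness of
  the expansion for comparability;
* because $\sigma_{Yk}$ is estimated from the *marginal* regression of
  outcome on variant, it embeds the marginal outcome residual variance,
  which exceeds the second-stage residual variance
  $\mathrm{var}(y-\hat\beta x)$ under positive confounding and falls
  below it under negative confounding. Summarized-data intervals are
  therefore systematically conservative (coverage around 97% at nominal
  95%) with positive confounding and slightly anti-conservative with
  negative confounding, even at $\theta_S = 0$ — behaviour the acceptance
  suite reproduces.

**IVW** (`ivw_estimate()`, `ivw_via_regression()`): the inverse-variance
weighted average of ratio estimates with first-order standard errors
$\sigma_{Yk}/\hat\beta_{Xk}$, equal to the slope of the
$\sigma_{Yk}^{-2}$-weighted regression of $\hat\beta_{Yk}$ on
$\hat\beta_{Xk}$ through the origin. The regression route requires the
textbook correction of forcing the residual standard error to one
(dividing the reported slope SE by the residual SE); both routes are kept
and asserted equal to ten significant figures.

**Correlated variants.** With signed correlations $\rho_{k_1k_2}$, the
allele-score standard error becomes
$$se = \frac{\sqrt{\sum_{k_1}\sum_{k_2}\rho_{k_1k_2} w_{k_1}w_{k_2}
\sigma_{Yk_1}^{-1}\sigma_{Yk_2}^{-1}}}{\left|\sum_k w_k
\hat\beta_{Xk}\sigma_{Yk}^{-2}\right|}$$
(leading delta term only), and the IVW *expression* remains usable only
as a test of the causal null with an analogous standard error
(`ivw_test_correlated()`); it no longer estimates the causal effect. The
estimator of choice is generalized least squares (`gls_estimate()`) with
weighting matrix $\Omega_{k_1k_2} = \sigma_{Yk_1}\sigma_{Yk_2}
\rho_{k_1k_2}$:
$$\hat\beta_{gls} = (\hat\beta_X^T\Omega^{-1}\hat\beta_X)^{-1}
\hat\beta_X^T\Omega^{-1}\hat\beta_Y, \qquad
se = (\hat\beta_X^T\Omega^{-1}\hat\beta_X)^{-1/2},$$
solved through a Cholesky factorization (never an explicit inverse; a
brute-force inverse serves as the test oracle at small K). All three
correlated-variant expressions reduce exactly to their uncorrelated
counterparts at identity correlation, which the suite asserts to ten
significant figures.

**Likelihood method** (`fit_ml()`). The association pairs are modelled
jointly as bivariate normal with means $(\xi_k, \beta_L\xi_k)$, known
standard deviations, and within-variant correlation $\theta_L$ (zero in
two-sample use). With correlated variants the model is a single
2K-variate normal whose blocks are
$\mathrm{cov}(\hat\beta_{Xk_1},\hat\beta_{Xk_2}) =
\rho_{k_1k_2}\sigma_{Xk_1}\sigma_{Xk_2}$, similarly for the outcome
block, and $\theta_L\rho_{k_1k_2}\sigma_{Xk_1}\sigma_{Yk_2}$ across — the
Kronecker-structured extension of the within-variant block, chosen
because it is the unique form that reduces to independent bivariate terms
at identity correlation and stays positive definite for any valid
$\rho$ and $|\theta_L| < 1$; both reductions are tested. Unlike the IVW
estimator, the likelihood treats the exposure associations as noisy
estimates of $\xi_k$, so it does not suffer regression-dilution
attenuation when external weights are imprecise.

## Diagnostics

`per_variant_ratios()` exposes the individual ratio estimates with
first-order standard errors (a second-order option adds the
exposure-uncertainty term). `cochran_q()` tests heterogeneity of the
ratios against $\chi^2_{K-1}$; algebraically Q equals the weighted
residual sum of squares of the no-intercept IVW regression, which the
suite uses as an oracle. `intercept_pleiotropy_test()` refits that
regression with an intercept: a non-zero intercept measures the average
direct (pleiotropic) effect of the variants on the outcome. Its p-values
use a t distribution with K − 2 degrees of freedom rather than a normal —
a deliberate small-K choice, since these regressions typically have
5–30 points. The intercept is not invariant to allele recoding, so the
test requires (and the reader should report) risk-increasing orientation.
`summarized_strength()` recovers R² and F from standardized effect sizes
and allele frequencies when individual-level data are absent.

## Data model and conventions

`summary_set()` validates dimensions, positive standard errors, and the
LD matrix (symmetric within 1e−8 after symmetrization — published LD
tables round asymmetrically — unit diagonal, entries in [−1, 1]).
`orient_to_risk_increasing()` flips every variant with a negative
exposure association, negating the outcome association and any weights,
complementing allele frequencies, and rescaling LD rows/columns by the
flip signs; every estimator is invariant to the original coding, which a
property test checks across random recodings. Variants with an exactly
zero exposure association have no defined direction: they are kept (they
receive zero weight in the inverse-variance sums, so dropping them would
silently change K) and flagged with a warning. Confidence intervals use
normal quantiles at 95% by default. Odds-ratio output is a presentation
transform applied only to estimates and interval limits.

Near-singular LD matrices are repaired by the smallest diagonal ridge
from {1e−8, 1e−6, 1e−4, 1e−2} that restores numerical positive
definiteness, with a warning and a flag; this preserves the published
off-diagonal correlations, unlike a nearest-correlation projection.
Exact duplicates (a correlation of magnitude one) are refused outright
with advice to prune — a ridge would make the algebra run but not mean
anything. `ld_prune()` implements the conventional greedy r² > 0.8 rule.

The likelihood optimizer is BFGS over $(\beta_L, \xi_1,\dots,\xi_K)$ with
an analytic gradient, initialized at the observed exposure associations
and the IVW (or GLS) estimate, plus one deterministic restart from
$\xi_k + 0.1\sigma_{Xk}$; if the restart improves the log-likelihood by
more than 1e−4 the fit is flagged non-converged. Standard errors come
from the inverse Hessian, with a profile-likelihood curvature fallback
when the Hessian is singular (the profile over $\xi$ is closed-form
generalized least squares for fixed $\beta$, which also provides the
grid-search oracle the tests compare against).

## What the simulator emulates

Two data-generating processes, both with
$x_i = \sum_k \alpha_k g_{ik} + u_i + \varepsilon_{Xi}$ and
$y_i = \beta_X x_i + \beta_U u_i + \varepsilon_{Yi}$, standard normal
confounder and noise, per-variant effects
$\alpha_k \sim U(0.5\alpha, 1.5\alpha)$ redrawn each replicate (so that
between-replicate variability in instrument strength is part of the
design):

* **independent variants**: $g_{ik} \sim \mathrm{Binomial}(2, \pi_k)$
  with $\pi_k \sim U(0.01, 0.5)$;
* **correlated variants**: a Wishart draw
  $\Lambda \sim W(K, \Lambda_0)$ with unit diagonal and constant
  off-diagonal 0.5 in $\Lambda_0$ is reduced to a correlation matrix by
  correlating its columns, $\Phi = \mathrm{cor}(\Lambda)$; two latent
  haplotype vectors per subject are drawn from $N_K(0, \Phi)$ (via an
  eigenvalue factorization — $\Phi$ is rank K − 1 by construction) and
  thresholded at $\pi'_k \sim U(0, 2)$, so allele frequencies range from
  0.5 down to 0.025. Correlating the columns, rather than normalizing the
  draw as a covariance matrix, is deliberate: it produces the intended
  regime of mostly-positive but variable genotype correlations
  (roughly 78% positive, quartiles near 0.03 and 0.26) and first-stage
  strength around F ≈ 86 at $\alpha = 0.2$; the covariance normalization
  instead yields almost uniformly strong positive correlations and
  F well above 120, a qualitatively different and less realistic regime.

External weights emulate a two-sample design: for independent variants a
direct draw from the sampling distribution
$N(\alpha_k, 1/(N\pi_k(1-\pi_k)))$; for correlated variants an entire
independent dataset of size N is generated *from the same realized
variant-level parameters* ($\Phi$, $\pi'_k$, $\alpha_k$ — two samples
from one population share these) and per-variant univariate regressions
are fitted. Oracle weights are the true $\alpha_k$. The binary-outcome
generator is this package's own documented choice: a logistic link with
the intercept solved numerically for 30% prevalence, and per-variant
outcome associations from univariate logistic regressions on the
log-odds scale.

`run_study()` runs replicates sequentially under one seed (fully
deterministic), records per-replicate estimates and standard errors,
excludes and counts estimator failures (the likelihood method
occasionally cannot produce a usable standard error with very weak
instruments), and aggregates medians — preferred over means because the
ratio estimator has no first moment — along with SDs, median SEs,
coverage and power of symmetric normal intervals, and Monte-Carlo
standard errors for each summary.

What passing these simulations does *not* show about real data: the
generator draws ideal instruments (no pleiotropy, no population
stratification, no strand ambiguity), linear homogeneous effects, and
perfectly known LD; conclusions about bias and coverage transfer to real
analyses only to the extent those assumptions hold.

## Problem sizes and tolerances

The acceptance checks and `scripts/acceptance.R` use 1000 replicates for
median targets and 2000 for coverage/size targets, at the study
conditions n = 5000, K = 15. At 1000 replicates the Monte-Carlo standard
error of a median is about 0.004–0.008 in the weak-instrument scenarios,
so reproduced medians are compared at three Monte-Carlo standard errors;
percentages are compared at three standard errors of a proportion.
Exact algebraic identities are asserted at 1e−10 relative tolerance,
oracle solves at 1e−8, and likelihood grid agreement at the grid step.

## Known limitations

* Allele-strand/palindromic-variant harmonization against reference
  panels is out of scope; inputs must already refer to a consistent
  effect allele, and correlations must be signed accordingly (published
  LD is often reported unsigned, which is not sufficient).
* Only fixed-effect combination is provided — no overdispersion,
  robust, median or mode estimators.
* The delta-method allele-score interval is approximate in the ways
  described above; with imprecise external weights the IVW and GLS point
  estimates attenuate toward the null by design of those estimators, and
  the likelihood method should be preferred when unbiased point estimates
  matter and convergence can be verified.
* Diagnostics assume approximately independent variants; the CLI warns
  when an LD matrix is supplied alongside them.
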