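---
title: "Causal inference with pleiotropic, correlated instruments: the pldmr model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal inference with pleiotropic, correlated instruments: the pldmr model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pldmr)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure $X$ on an outcome
$Y$ free of unmeasured confounding. Two realities of modern variant panels
violate the textbook instrumental-variable assumptions:

* **pleiotropy** — a variant may affect the outcome directly, not only
  through the exposure; and
* **linkage disequilibrium (LD)** — nearby variants are correlated, so
  per-variant summary statistics are not independent.

`pldmr` implements a family of estimators for *one-sample,
individual-level* data that model both at once.

## Model

For $n$ individuals, let $G$ be the column-centered $n \times m$ additive
dosage matrix, and $X$, $Y$ the centered exposure and outcome. The
structural model is

$$X = G\gamma + \varepsilon_X, \qquad
  Y = G\alpha + X\beta + \varepsilon_Y,$$

with $(\varepsilon_{Xi}, \varepsilon_{Yi})$ i.i.d. bivariate normal with
standard deviations $\sigma_X, \sigma_Y$ and correlation $\rho$ — the
influence of unknown confounders is carried entirely by $\rho$ — and the
pleiotropic effects random, $\alpha \sim N(\mu_\alpha 1,
\sigma_\alpha^2 I_m)$. $\beta$ is the causal effect of interest.

Writing $\hat\Gamma = (G^TG)^{-1}G^TY$ and $\hat\gamma =
(G^TG)^{-1}G^TX$ for the *joint* (multiple-regression) coefficient
vectors, the model implies the instrument-level regression

$$\hat\Gamma = \mu_\alpha 1 + \beta \hat\gamma + \epsilon, \qquad
  \epsilon \sim N(0, W^{-1}), \qquad
  W = \left[\sigma_\alpha^2 I_m + \sigma_Y^2 (G^TG)^{-1}\right]^{-1}.$$

$W$ is the precision of $\hat\Gamma$: the $\sigma_\alpha^2 I$ term is the
pleiotropy variance, the $\sigma_Y^2 (G^TG)^{-1}$ term the sampling noise
of the multiple regression, which carries all of the LD structure. With
the eigendecomposition $(G^TG)^{-1} = Q\Lambda Q^T$ (computed once per
dataset, cached in the `joint_coefs()` object, eigenvalues sorted
decreasingly with a deterministic sign convention) and $r^2 =
\sigma_\alpha^2/\sigma_Y^2$, everything reduces to diagonal arithmetic in
the rotated coordinates $Q^T\hat\Gamma$, $Q^T 1$, $Q^T\hat\gamma$.

## The estimator family

* **PLDMR** (`fit_pldmr()`, the default of `pldmr()`) — maximum
  likelihood in $(\mu_\alpha, \beta, r^2)$; see the next section for how
  $\sigma_Y^2$ is handled. Inference on $\beta$ uses a $t(m-2)$ reference.
* **PLDMR_t** (`fit_pldmr_t()`) — the same weighted regression with $W$
  built from externally supplied *true* variance components; a simulation
  oracle.
* **LDMR** (`fit_ldmr()`) — the closed-form limit $\sigma_\alpha^2 = 0$:
  regression of $\hat\Gamma$ on $\hat\gamma$ weighted by $G^TG$. Its
  variance is scaled by $\hat\sigma_Y^2 = \text{weighted RSS}/(m-2)$; a
  variance without this scale factor would not be dimensionally consistent
  with the general $W$-based expression, so the factor is included.
* **PLDMR_a** (`fit_pldmr_a()`) — the large-$n$ limit: $G^TG = O(n)$
  makes $W \approx \sigma_\alpha^{-2} I$, so ordinary least squares of
  $\hat\Gamma$ on $\hat\gamma$ with intercept suffices.
* **MR-Egger / IVW** (`fit_mr_egger()`, `fit_ivw()`) — the standard
  summary-statistic baselines, fit to per-variant *marginal* coefficients
  with $SE(\tilde\Gamma_j)^{-2}$ weights; Egger carries a multiplicative
  overdispersion floored at 1 (no under-dispersion), and the same
  convention is applied to IVW. Both ignore LD by construction — that is
  what the comparison is about.

The projection onto $W^{1/2}1$ that appears in the $\beta$ variance is the
standard orthogonal projection $W^{1/2}1 (1^TW1)^{-1} 1^T W^{1/2}$.

## Estimating the variance components

The pair $(r^2, \sigma_Y^2)$ enters the likelihood
$$-\log L = \frac{m}{2}\log(2\pi\sigma_Y^2)
 + \frac{1}{2}\sum_k \log(r^2+\lambda_k)
 + \frac{1}{2\sigma_Y^2}\sum_k \frac{u_k^2}{r^2+\lambda_k},
 \qquad u = Q^T(\hat\Gamma - \mu_\alpha 1 - \beta\hat\gamma),$$
only through $m$ residual coordinates. Maximizing over *both* from these
$m$ numbers is badly conditioned: for $r^2$ much larger than the
$\lambda_k$ only the product $r^2\sigma_Y^2 = \sigma_\alpha^2$ is
identified, the profile likelihood is a near-flat ridge, and the estimate
of $r^2$ collapses to a boundary in a substantial fraction of replicates —
with an anti-conservative plug-in variance as the consequence (we measured
type-I error up to twice the nominal level at $m = 25$ under strong LD
when both components are taken from the instrument-level likelihood).

Individual-level data offers a better route, and `fit_pldmr()` takes it:

1. $\sigma_Y^2$ **first, at $n$-level precision.** With $e_X$, $e_Y$ the
   residuals of the multiple regressions of $X$ and $Y$ on $G$ and
   $\beta_0$ a preliminary (LDMR) estimate, $e_Y - \beta_0 e_X$ estimates
   $\varepsilon_Y$ residualized on $G$, so
   $\hat\sigma_Y^2 = \lVert e_Y - \beta_0 e_X\rVert^2 / (n - m)$.
2. **Profile likelihood in $r^2$.** With $\hat\sigma_Y^2$ fixed,
   $(\mu_\alpha, \beta)$ are profiled in closed form (two-parameter
   generalized least squares in the eigenbasis) and the remaining
   one-dimensional function of $r^2$ is minimized on $[0, r^2_{max}]$
   (default $r^2_{max} = 10^4$) by a coarse log-spaced bracket followed by
   golden-section refinement; $\hat r^2 = 0$ is reported as a legitimate
   boundary estimate. Fixing $\sigma_Y^2$ removes the ridge: the profiled
   objective now grows like $\tfrac m2\log r^2$ for large $r^2$ and the
   minimizer concentrates near the true variance ratio. The search is
   deterministic, so there is no starting-point sensitivity; a multi-start
   full-dimensional optimizer over $(\mu_\alpha, \beta, r^2)$ is retained
   in the test suite as an independent oracle and agrees with the profile
   to $10^{-5}$ on seeded instances.
3. **Dispersion-scaled plug-in variance.**
   $\widehat{Var}(\hat\beta) = \hat\phi \, \big[\hat\gamma^T W^{1/2}
   (I-P_{W^{1/2}1}) W^{1/2}\hat\gamma\big]^{-1}$ with $W$ at the
   estimates and $\hat\phi = \sum_k u_k^2/(r^2+\lambda_k) \big/
   \{(m-2)\hat\sigma_Y^2\}$ the weighted residual mean square. $\hat\phi$
   absorbs residual misweighting when $\hat r^2$ errs, the same device
   MR-Egger uses for overdispersion (here it is not floored; its null
   expectation is close to 1 by construction).

In our null calibration runs ($n = 5000$, $m = 25$, $\sigma_\alpha = 0.1$,
2000 replicates per cell) this estimator holds the 0.05 level across all
combinations of pleiotropy direction and LD strength, while the
both-components-from-the-likelihood variant does not. The degrees of
freedom remain $m - 2$ (intercept and slope estimated at the instrument
level).

## Simulator

`mr_scenario()` + `simulate_mr_data()` generate datasets with exactly the
structure above. Genotypes come from a Gaussian copula: draw $z_i \sim
MVN(0, \Sigma_g)$ with Toeplitz correlation $(\Sigma_g)_{j_1 j_2} =
\rho_g^{|j_1-j_2|}$, and set $G_{ij}$ to the $\Phi(z_{ij})$ quantile of
Binomial(2, MAF$_j$) — implemented as two per-column normal thresholds,
which is algebraically identical to the inverse-CDF definition (smallest
dosage whose binomial CDF reaches $\Phi(z)$) and avoids $2nm$
distribution-function calls; a test asserts equivalence to the literal
`qbinom(pnorm(z))` route.

Scenario defaults are the study's base conditions: MAF$_j \sim
U[0.2, 0.4]$, $\gamma_j \sim U[0.5, 4]$, $\sigma_X = \sigma_Y = 2$,
$\rho = 0.5$, nominal level 0.05. MAFs and instrument strengths are
redrawn each replicate — the marginal distributions above then hold
per replicate and results average over instrument-strength
configurations; `redraw_effects = FALSE` fixes them instead, since
either reading of the design is defensible. Each replicate runs on one
seeded generator with fixed stream order (MAFs, copula normals, $\gamma$,
$\alpha$, errors), so datasets are bit-reproducible. A draw that produces
a monomorphic column (possible at small $n\cdot$MAF) is redrawn wholesale
so the LD structure is preserved, and the attempt count is recorded.

What the simulator does *not* emulate: real LD block structure (the
Toeplitz decay is a stylized stand-in), MAF-dependent effect sizes,
non-normal phenotypes, case-control outcomes, and population
stratification. Passing the simulation suite therefore shows correctness
*under the model*, not robustness to these real-data features.

## Monte-Carlo harness

`run_scenario()` aggregates `run_replicate()` into per-method rejection
rates (with binomial Monte-Carlo standard errors), mean estimates,
empirical and mean model-based standard errors, and a count of failed
replicates — failures are tallied, never silently dropped. The
summary-statistic baselines are fed two-sample-style inputs by splitting
each simulated cohort in half after a seeded permutation: exposure
regressions from one half, outcome regressions from the other.
`run_grid()` crosses scenario parameters, writes one tidy TSV row per
scenario and method, and resumes by a stable digest of the canonicalized
configuration. Default replicate counts (2000 per scenario; 500 for bias
summaries; 1000 for the instrument-count sweep) keep a full calibration
study at desk scale with ~0.005 Monte-Carlo standard error at the null.

## Preprocessing for real cohorts

`mr_preprocess()` fixes the order: (1) drop variants with more than 20%
missing dosages, mean-imputing the remainder; (2) exclude
Hardy–Weinberg-violating variants by a 1-df chi-square test (default
threshold $10^{-6}$; the test and threshold are exposed because
conventions differ); (3) residualize phenotypes on covariates (e.g. sex,
age, age$^2$), with optional log transform applied before
residualization; (4) select instruments by one joint multiple regression
of the exposure on all candidates, keeping positively associated variants
at $p < 5\times10^{-8}$ by default ($10^{-4}$ as a common lenient
alternative); (5) center. Every input variant appears exactly once in the
QC report with its per-stage decision.

## Numerical choices and edge cases

* Gram matrices with condition number above $10^{12}$ are rejected with
  the near-collinear variants named — pruning is the analyst's decision,
  not something to paper over with ridge terms.
* Regressions on centered data carry no intercept; adding constants to
  raw phenotypes provably leaves all estimates unchanged.
* A constant $\hat\gamma$ makes intercept and slope non-identifiable and
  raises an error rather than returning NaN.
* Exact-fit (noiseless) data collapses $\hat\sigma_Y^2$ to the boundary;
  the fit reports $\hat r^2 = 0$ and near-zero standard errors instead of
  dividing by zero.
* Marginal-regression standard errors use an $n-1$ denominator (one
  slope, no intercept on centered data); any consistent choice only
  rescales the Egger weights.
* With a single instrument, IVW degenerates to the Wald ratio with
  first-order (normal) inference.

## Known limitations

The $t(m-2)$ reference is exact only when $W$ is known ($\texttt{PLDMR}_t$);
with estimated components a slight type-I elevation remains under strong
LD at small $m$. The model conditions on $\hat\gamma$ and ignores the
correlation between $\hat\gamma$ and the sampling noise of $\hat\Gamma$
induced by confounding ($\rho \ne 0$) — the same approximation the
summary-statistic methods make. Only quantitative traits are supported,
$m$ must be well below $n$ (no GWAS-scale panels, no sparse Gram
computation), and summary-level input with a reference LD panel is out of
scope.
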