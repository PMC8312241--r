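# pldmr

Mendelian randomization (MR) from one-sample, individual-level data when
the genetic instruments are both **pleiotropic** and in **linkage
disequilibrium (LD)** — the two standard violations of the textbook
instrumental-variable assumptions in modern variant panels.

The package is for biostatisticians and genetic epidemiologists who have
an additive genotype matrix (PLINK `.raw` or plain TSV), a quantitative
exposure and a quantitative outcome, and want a causal-effect estimate
that does not require pruning correlated variants or assuming the
pleiotropic effects away.

## Model and estimators

For centered genotypes *G* (n × m), exposure *X* and outcome *Y*:

    X = Gγ + ε_X,    Y = Gα + Xβ + ε_Y,    α ~ N(μ_α 1, σ_α² I_m),

with (ε_X, ε_Y) bivariate normal (correlation ρ carries all confounding).
The joint regression coefficients Γ̂ = (GᵀG)⁻¹GᵀY and γ̂ = (GᵀG)⁻¹GᵀX
then satisfy

    Γ̂ = μ_α 1 + β γ̂ + ε,    ε ~ N(0, W⁻¹),
    W  = [σ_α² I_m + σ_Y² (GᵀG)⁻¹]⁻¹,

so the pleiotropy mean is an intercept, the pleiotropy variance and the
LD-aware sampling noise form the weight matrix, and β is the slope.
`pldmr()` fits this model by profile maximum likelihood over
(μ_α, β, r² = σ_α²/σ_Y²) after an eigendecomposition of GᵀG, with σ_Y²
estimated at n-level precision from the individual-level regression
residuals; inference uses t(m−2). Also provided: the closed-form
approximations **LDMR** (σ_α² ≈ 0) and **PLDMR_a** (large n), the oracle
**PLDMR_t** (true variance components), and the summary-statistic
baselines **MR-Egger** and **IVW** — plus a genotype/phenotype simulator
(Gaussian-copula genotypes with Toeplitz LD) and a Monte-Carlo harness
for type-I error, power and bias studies.

See `vignettes/pldmr-methods.Rmd` for the full account.

## Worked example

Simulate one cohort under directional pleiotropy (μ_α = 0.1) with
moderate LD (ρ_g = 0.3) and a true causal effect β = 0.05, then fit:

```r
library(pldmr)
sc  <- mr_scenario(n = 5000, m = 25, rho_g = 0.3, mu_alpha = 0.1,
                   sigma_alpha = 0.1, beta = 0.05, seed = 7)
dat <- simulate_mr_data(sc, 1)
fit <- pldmr(dat$genotypes, dat$exposure, dat$outcome)
summary(fit)
#> PLDMR causal-effect estimate
#>   beta_hat = 0.05537  (SE 0.0228, 95% CI [0.008201, 0.1025])
#>   t = 2.428 on 23 df, p = 0.0234  (H0: beta = 0)
#>   auxiliary estimates:
#>     mu_alpha_hat    0.1065
#>     r2_hat          0.002546
#>     sigma_y2_hat    3.957
#>     overdispersion  1.069
#>     nll_at_optimum  -19.86
```

PLDMR recovers the causal effect (0.055 vs the true 0.05), the
pleiotropy mean (0.107 vs 0.1) and the variance ratio (r̂² = 0.0025 vs
the true 0.1²/2² = 0.0025), and rejects the causal null. The baselines on
the same data show why the corrections matter:

```r
pldmr(dat$genotypes, dat$exposure, dat$outcome, method = "ldmr")$beta_hat
#> [1] 0.05052
pldmr(dat$genotypes, dat$exposure, dat$outcome, method = "ivw")$beta_hat
#> [1] 0.09549   # IVW cannot absorb directional pleiotropy: ~2x the truth
```

A calibration experiment is one call:

```r
res <- run_scenario(mr_scenario(n = 5000, m = 25, beta = 0, n_reps = 2000,
                                seed = 1), c("pldmr", "ldmr"))
res$per_method   # rejection rate ~0.05 for calibrated methods
```

`mr_preprocess()` runs the real-cohort QC pipeline (missingness filter,
Hardy–Weinberg test, covariate residualization, instrument selection),
and `inst/cli/pldmr-cli.R` exposes `simulate`, `fit`, `qc` and
`experiment` subcommands for shell use.

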