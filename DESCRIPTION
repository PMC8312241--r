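Package: pldmr
Title: Mendelian Randomization with Pleiotropy and Linkage Disequilibrium
    from Individual-Level Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal-effect estimation from one-sample individual-level data
    using genetic variants as instrumental variables, allowing both
    directional pleiotropy and linkage disequilibrium among the instruments.
    Implements a mixed-effects regression model in which the pleiotropic
    effects of the variants on the outcome are normally distributed random
    effects; the causal effect is estimated by maximum likelihood after an
    eigendecomposition of the genotype Gram matrix (PLDMR), together with
    its closed-form approximations for negligible pleiotropy variance (LDMR)
    and large sample size (PLDMR_a), the oracle-weighted variant (PLDMR_t),
    and the summary-statistic baselines MR-Egger and inverse-variance
    weighting. Also provides a genotype/phenotype simulator (Gaussian-copula
    genotypes with Toeplitz linkage-disequilibrium structure), a Monte-Carlo
    harness for type-I-error, power and bias studies, genotype file input
    and output (PLINK .raw dialect and plain TSV), and the usual
    quality-control steps (missingness filter, Hardy-Weinberg test,
    covariate residualization, instrument selection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
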