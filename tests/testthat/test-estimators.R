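# Estimator family: closed-form identities, brute-force GLS oracles,
# profile-vs-full optimization, inference helpers.

test_that("noiseless data is recovered to near machine precision", {
  sc <- mr_scenario(n = 500, m = 8, sigma_alpha = 0, sigma_x = 1e-12,
                    sigma_y = 1e-12, mu_alpha = 0.1, beta = 0.3, seed = 71)
  dat <- simulate_mr_data(sc, 1)
  fit <- pldmr(dat$genotypes, dat$exposure, dat$outcome)
  expect_equal(fit$beta_hat, 0.3, tolerance = 1e-6)
  expect_equal(fit$mu_alpha_hat, 0.1, tolerance = 1e-6)
  expect_equal(fit$r2_hat, 0)
  ld <- pldmr(dat$genotypes, dat$exposure, dat$outcome, method = "ldmr")
  expect_equal(ld$beta_hat, 0.3, tolerance = 1e-6)
})

test_that("PLDMR_t at sigma_alpha2 = 0 coincides with LDMR", {
  dat <- quick_dataset(n = 400, m = 10, seed = 72, rho_g = 0.3, mu_alpha = 0.1)
  jc <- jc_of(dat)
  ft <- fit_pldmr_t(NULL, NULL, variance_components(0, 0, 4), jc = jc)
  fl <- fit_ldmr(NULL, NULL, jc = jc)
  expect_equal(ft$beta_hat, fl$beta_hat, tolerance = 1e-12)
  expect_equal(ft$mu_alpha_hat, fl$mu_alpha_hat, tolerance = 1e-12)
})

test_that("PLDMR_t with W proportional to I equals the OLS fit (PLDMR_a)", {
  n <- 60
  Gc <- orthogonal_centered_design(n, 5, scale = 3)  # Gram = 9 I
  set.seed(73)
  x <- rnorm(n); y <- rnorm(n)
  jc <- jc_from_design(Gc, x - mean(x), y - mean(y))
  ft <- fit_pldmr_t(NULL, NULL, variance_components(0, 0.2, 1.8), jc = jc)
  fa <- fit_pldmr_a(jc)
  expect_equal(ft$beta_hat, fa$beta_hat, tolerance = 1e-10)
  expect_equal(ft$mu_alpha_hat, fa$mu_alpha_hat, tolerance = 1e-10)
})

test_that("weighted estimators match a brute-force GLS oracle", {
  dat <- quick_dataset(n = 500, m = 9, seed = 74, rho_g = 0.5, mu_alpha = -0.1)
  jc <- jc_of(dat)
  X <- cbind(1, jc$gamma_hat)
  # PLDMR_t with arbitrary variance components
  vc <- variance_components(0, 0.03, 5)
  W <- weight_matrix(vc, jc)
  gls <- oracle_gls(jc$Gamma_hat, X, W)
  ft <- fit_pldmr_t(NULL, NULL, vc, jc = jc)
  expect_equal(ft$beta_hat, gls$coef[2], tolerance = 1e-8)
  expect_equal(ft$mu_alpha_hat, gls$coef[1], tolerance = 1e-8)
  expect_equal(ft$se_beta, sqrt(gls$cov[2, 2]), tolerance = 1e-8)
  # LDMR: the printed closed form with J = all-ones, and GLS weighting by G'G
  gram <- unname(jc$gram)
  J <- matrix(1, jc$m, jc$m)
  A <- gram - gram %*% J %*% gram / sum(gram)
  beta_disp <- drop(t(jc$gamma_hat) %*% A %*% jc$Gamma_hat /
                      (t(jc$gamma_hat) %*% A %*% jc$gamma_hat))
  fl <- fit_ldmr(NULL, NULL, jc = jc)
  expect_equal(fl$beta_hat, beta_disp, tolerance = 1e-10)
  gls2 <- oracle_gls(jc$Gamma_hat, X, gram)
  expect_equal(fl$beta_hat, gls2$coef[2], tolerance = 1e-10)
  # PLDMR point estimate is the GLS at the fitted W; its SE is the GLS
  # covariance scaled by the multiplicative dispersion
  fp <- fit_pldmr(NULL, NULL, jc = jc)
  Wp <- weight_matrix(variance_components(0, fp$r2_hat * fp$sigma_y2_hat,
                                          fp$sigma_y2_hat), jc)
  glsp <- oracle_gls(jc$Gamma_hat, X, Wp)
  expect_equal(fp$beta_hat, glsp$coef[2], tolerance = 1e-8)
  expect_equal(fp$se_beta, sqrt(fp$overdispersion * glsp$cov[2, 2]),
               tolerance = 1e-8)
})

test_that("PLDMR_a matches textbook simple regression", {
  # 5-point dataset, checked against lm()
  x <- c(0.8, 1.4, 2.1, 2.9, 3.6)
  y <- c(0.12, 0.17, 0.20, 0.26, 0.33)
  jc <- structure(list(gamma_hat = x, Gamma_hat = y, gram = diag(5),
                       eig_Q = diag(5), eig_lambda = rep(1, 5), n = 50, m = 5,
                       variant_ids = paste0("V", 1:5)),
                  class = "mr_joint_coefs")
  fa <- fit_pldmr_a(jc)
  lf <- summary(lm(y ~ x))
  expect_equal(fa$beta_hat, unname(coef(lf)[2, 1]), tolerance = 1e-10)
  expect_equal(fa$se_beta, unname(coef(lf)[2, 2]), tolerance = 1e-10)
  expect_equal(fa$mu_alpha_hat, unname(coef(lf)[1, 1]), tolerance = 1e-10)
  expect_equal(fa$p_value, unname(coef(lf)[2, 4]), tolerance = 1e-10)
  # exact line
  jc$Gamma_hat <- 0.1 + 0.05 * jc$gamma_hat
  fa2 <- fit_pldmr_a(jc)
  expect_equal(fa2$beta_hat, 0.05, tolerance = 1e-12)
  expect_equal(fa2$mu_alpha_hat, 0.1, tolerance = 1e-12)
})

test_that("PLDMR_a approaches PLDMR at large n", {
  sc <- mr_scenario(n = 20000, m = 25, sigma_alpha = 0.1, mu_alpha = 0.1,
                    rho_g = 0.3, beta = 0.05, seed = 75)
  dat <- simulate_mr_data(sc, 1)
  jc <- jc_of(dat)
  fp <- fit_pldmr(NULL, NULL, jc = jc)
  fa <- fit_pldmr_a(jc)
  expect_lt(abs(fa$beta_hat - fp$beta_hat), 0.1 * fp$se_beta)
})

test_that("MR-Egger matches weighted normal equations and floors dispersion", {
  dat <- quick_dataset(n = 600, m = 12, seed = 76, mu_alpha = 0.1)
  mc <- marginal_coefs(dat$genotypes, phenotype_pair(dat$exposure, dat$outcome))
  fe <- fit_mr_egger(mc)
  w <- 1 / mc$se_Gamma_tilde^2
  gls <- oracle_gls(mc$Gamma_tilde, cbind(1, mc$gamma_tilde), diag(w))
  expect_equal(fe$beta_hat, gls$coef[2], tolerance = 1e-10)
  expect_gte(fe$overdispersion, 1)
  # equal weights: same point estimate as unweighted regression
  mc2 <- mc
  mc2$se_Gamma_tilde <- rep(0.02, mc$m)
  fe2 <- fit_mr_egger(mc2)
  ols <- lm(mc$Gamma_tilde ~ mc$gamma_tilde)
  expect_equal(fe2$beta_hat, unname(coef(ols)[2]), tolerance = 1e-10)
  # exact line with equal SEs: dispersion floored to 1, slope = OLS slope
  mc3 <- mc2
  mc3$Gamma_tilde <- 0.02 + 0.4 * mc3$gamma_tilde
  fe3 <- fit_mr_egger(mc3)
  expect_equal(fe3$beta_hat, 0.4, tolerance = 1e-10)
  expect_equal(fe3$overdispersion, 1)
})

test_that("IVW reduces to the direct weighted formula and the Wald ratio", {
  dat <- quick_dataset(n = 600, m = 12, seed = 77)
  mc <- marginal_coefs(dat$genotypes, phenotype_pair(dat$exposure, dat$outcome))
  fi <- fit_ivw(mc)
  w <- 1 / mc$se_Gamma_tilde^2
  expect_equal(fi$beta_hat,
               sum(w * mc$gamma_tilde * mc$Gamma_tilde) / sum(w * mc$gamma_tilde^2),
               tolerance = 1e-12)
  expect_equal(fi$df, 11)
  # equal weights and exact proportionality
  mc2 <- mc
  mc2$Gamma_tilde <- 2 * mc2$gamma_tilde
  mc2$se_Gamma_tilde <- rep(0.1, mc$m)
  expect_equal(fit_ivw(mc2)$beta_hat, 2, tolerance = 1e-12)
  # single instrument: Wald ratio
  mc1 <- structure(list(gamma_tilde = 0.5, Gamma_tilde = 0.2,
                        se_Gamma_tilde = 0.05, se_gamma_tilde = 0.04,
                        n = 100, m = 1L, variant_ids = "V1"),
                   class = "mr_marginal_coefs")
  expect_equal(fit_ivw(mc1)$beta_hat, 0.4, tolerance = 1e-12)
})

test_that("t inference: null, normal limit, and t(23) quantile", {
  ti <- t_inference(0.2, 0.1, df = 10, beta0 = 0.2)
  expect_equal(ti$t_stat, 0)
  expect_equal(ti$p_value, 1)
  expect_equal(t_inference(1.96, 1, df = 1e6)$p_value, 0.05, tolerance = 1e-3)
  expect_equal(t_inference(2.069, 1, df = 23)$p_value, 0.05, tolerance = 1e-3)
  expect_error(t_inference(1, 1, df = 0), "degrees of freedom")
  expect_error(t_inference(1, 0, df = 5), "positive")
  # CI is equal-tailed around the estimate
  ti2 <- t_inference(0.3, 0.05, df = 20, level = 0.9)
  expect_equal(ti2$ci_high - 0.3, 0.3 - ti2$ci_low, tolerance = 1e-12)
})

test_that("all estimators are scale-equivariant in the outcome", {
  dat <- quick_dataset(n = 500, m = 8, seed = 78, mu_alpha = 0.1, beta = 0.1)
  cc <- 3.7
  for (meth in c("pldmr", "pldmr_a", "ldmr", "egger", "ivw")) {
    f1 <- pldmr(dat$genotypes, dat$exposure, dat$outcome, method = meth)
    f2 <- pldmr(dat$genotypes, dat$exposure, cc * dat$outcome, method = meth)
    expect_equal(f2$beta_hat, cc * f1$beta_hat, tolerance = 1e-6,
                 label = paste(meth, "beta scaling"))
    expect_equal(f2$se_beta, cc * f1$se_beta, tolerance = 1e-6,
                 label = paste(meth, "SE scaling"))
  }
  ft1 <- pldmr(dat$genotypes, dat$exposure, dat$outcome, method = "pldmr_t",
               vc_true = variance_components(0.1, 0.01, 4))
  ft2 <- pldmr(dat$genotypes, dat$exposure, cc * dat$outcome, method = "pldmr_t",
               vc_true = variance_components(0.1, 0.01 * cc^2, 4 * cc^2))
  expect_equal(ft2$beta_hat, cc * ft1$beta_hat, tolerance = 1e-8)
})

test_that("profile optimization agrees with multi-start full optimization", {
  for (seed in 81:85) {
    dat <- quick_dataset(n = 500, m = 10, seed = seed, rho_g = 0.3,
                         mu_alpha = 0.1, sigma_alpha = 0.15)
    jc <- jc_of(dat)
    fp <- fit_pldmr(NULL, NULL, jc = jc)
    full <- oracle_multistart_pldmr(jc, fp$sigma_y2_hat, n_starts = 6,
                                    seed = seed)
    expect_equal(fp$beta_hat, full$beta, tolerance = 1e-5,
                 label = sprintf("seed %d beta", seed))
    expect_lte(fp$nll_at_optimum, full$nll + 1e-6)
    # optimizer dominance: fitted NLL not worse than at the true
    # (mu_alpha, beta, r2), same error-variance plug-in
    truth_nll <- pldmr_nll(0.1, 0, 0.15^2 / 4, fp$sigma_y2_hat, jc)
    expect_lte(fp$nll_at_optimum, truth_nll + 1e-9)
  }
})

test_that("weighted residuals are W-orthogonal to intercept and slope", {
  dat <- quick_dataset(n = 400, m = 8, seed = 86, rho_g = 0.4)
  jc <- jc_of(dat)
  fp <- fit_pldmr(NULL, NULL, jc = jc)
  W <- weight_matrix(variance_components(0, fp$r2_hat * fp$sigma_y2_hat,
                                         fp$sigma_y2_hat), jc)
  res <- jc$Gamma_hat - fp$mu_alpha_hat - fp$beta_hat * jc$gamma_hat
  scale <- sqrt(sum(diag(W))) * sqrt(sum(res^2)) + 1e-12
  expect_lt(abs(sum(W %*% res)) / scale, 1e-8)
  expect_lt(abs(drop(t(jc$gamma_hat) %*% W %*% res)) /
              (scale * sqrt(sum(jc$gamma_hat^2))), 1e-8)
})

test_that("degenerate inputs raise errors rather than NaN", {
  dat <- quick_dataset(n = 100, m = 4, seed = 87)
  jc <- jc_of(dat)
  jc$gamma_hat <- rep(1.5, 4)  # constant instrument effects
  expect_error(fit_pldmr_a(jc), "collinear|identifiable")
  expect_error(fit_pldmr(NULL, NULL, jc = jc), "collinear|identifiable")
  small <- quick_dataset(n = 50, m = 3, seed = 88)
  jc2 <- jc_of(small)
  jc2$m <- 2; jc2$gamma_hat <- jc2$gamma_hat[1:2]
  jc2$Gamma_hat <- jc2$Gamma_hat[1:2]
  jc2$eig_Q <- diag(2); jc2$eig_lambda <- rep(1, 2)
  expect_error(fit_pldmr(NULL, NULL, jc = jc2), "at least 3")
})
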