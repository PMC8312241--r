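# Causal-effect estimators: PLDMR (profile MLE), PLDMR_t (true variance
# components), PLDMR_a (large-n OLS approximation), LDMR (sigma_alpha^2 = 0
# approximation), MR-Egger and IVW summary baselines.

mr_fit_methods <- c("pldmr", "pldmr_t", "pldmr_a", "ldmr", "egger", "ivw")
mr_fit_labels <- c(pldmr = "PLDMR", pldmr_t = "PLDMR_t", pldmr_a = "PLDMR_a",
                   ldmr = "LDMR", egger = "MR-Egger", ivw = "IVW")

#' Two-sided t inference for a causal-effect estimate
#'
#' @param beta_hat point estimate.
#' @param se positive standard error.
#' @param df degrees of freedom (\eqn{\ge 1}; \code{Inf} gives the normal
#'   limit).
#' @param beta0 null value tested (default 0).
#' @param level confidence level in (0, 1).
#' @return List with \code{t_stat}, \code{p_value}, \code{ci_low},
#'   \code{ci_high}.
#' @examples
#' t_inference(0.1, 0.05, df = 23)
#' @export
t_inference <- function(beta_hat, se, df, beta0 = 0, level = 0.95) {
  if (!is.finite(se) || se <= 0) stop("'se' must be positive")
  if (df < 1) stop("degrees of freedom must be at least 1")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  t_stat <- (beta_hat - beta0) / se
  p_value <- 2 * stats::pt(-abs(t_stat), df = df)
  q <- stats::qt(1 - (1 - level) / 2, df = df)
  list(t_stat = t_stat, p_value = p_value,
       ci_low = beta_hat - q * se, ci_high = beta_hat + q * se)
}

# Assemble an mr_fit object; inference fields from t_inference.
new_mr_fit <- function(method, beta_hat, se_beta, df,
                       mu_alpha_hat = NA_real_, r2_hat = NA_real_,
                       sigma_y2_hat = NA_real_, overdispersion = NA_real_,
                       converged = TRUE, nll_at_optimum = NA_real_,
                       beta0 = 0, level = 0.95, jc = NULL, mc = NULL,
                       diagnostics = NULL) {
  se_beta <- max(se_beta, .Machine$double.xmin)  # exact fits give se -> 0
  inf <- t_inference(beta_hat, se_beta, df, beta0 = beta0, level = level)
  structure(list(method = method, label = unname(mr_fit_labels[method]),
                 beta_hat = beta_hat, se_beta = se_beta,
                 mu_alpha_hat = mu_alpha_hat, r2_hat = r2_hat,
                 sigma_y2_hat = sigma_y2_hat, overdispersion = overdispersion,
                 df = df, t_stat = inf$t_stat, p_value = inf$p_value,
                 ci_low = inf$ci_low, ci_high = inf$ci_high,
                 beta0 = beta0, level = level,
                 converged = converged, nll_at_optimum = nll_at_optimum,
                 jc = jc, mc = mc, diagnostics = diagnostics),
            class = "mr_fit")
}

eig_vectors <- function(jc) {
  list(a = drop(colSums(jc$eig_Q)),
       g = drop(crossprod(jc$eig_Q, jc$gamma_hat)),
       z = drop(crossprod(jc$eig_Q, jc$Gamma_hat)))
}

# outcome error variance at individual-level precision: residuals of the
# multiple regressions of X and Y on G, with the causal contribution
# removed using a preliminary beta estimate;
# e_Y - beta0 e_X estimates eps_Y, so ||e_Y - beta0 e_X||^2/(n - m) is an
# n-level estimate of sigma_Y^2 (the fraction explained by the m fitted
# coefficients is the only loss)
sigma_y2_individual <- function(jc, beta_prelim) {
  s <- (jc$rss_yy - 2 * beta_prelim * jc$rss_xy +
          beta_prelim^2 * jc$rss_xx) / (jc$n - jc$m)
  max(s, 1e-300)  # exact-fit data collapses the estimate to the boundary
}

#' Fit PLDMR by profile maximum likelihood
#'
#' Estimates the causal effect under the mixed-effects model
#' \eqn{\hat\Gamma = \mu_\alpha 1 + \beta\hat\gamma + \epsilon},
#' \eqn{\epsilon \sim N(0, W^{-1})},
#' \eqn{W = [\sigma_\alpha^2 I + \sigma_Y^2 (G^TG)^{-1}]^{-1}}.
#'
#' Because PLDMR operates on individual-level data, the outcome error
#' variance \eqn{\sigma_Y^2} does not need to be recovered from the m
#' instrument-level residuals: it is estimated first, at \eqn{n}-level
#' precision, from the residuals of the multiple regressions of the
#' exposure and the outcome on the genotypes (with the causal contribution
#' removed via a preliminary LDMR estimate). The likelihood is then
#' maximized over \eqn{(\mu_\alpha, \beta, r^2)} with
#' \eqn{(\mu_\alpha, \beta)} profiled in closed form (generalized least
#' squares in the eigenbasis) and the remaining one-dimensional function of
#' \eqn{r^2 = \sigma_\alpha^2/\sigma_Y^2} minimized on
#' \eqn{[0, r^2_{max}]}; \eqn{\hat r^2 = 0} is a legitimate boundary MLE
#' (the fit then degenerates toward LDMR). The standard error is the
#' plug-in
#' \eqn{\widehat{Var}(\hat\beta) = \hat\phi\,[\hat\gamma^T W^{1/2}
#' (I - P_{W^{1/2}1}) W^{1/2} \hat\gamma]^{-1}}
#' with \eqn{W} evaluated at the estimates and \eqn{\hat\phi} the weighted
#' residual mean square (a multiplicative dispersion that absorbs residual
#' misweighting when \eqn{\hat r^2} errs); inference uses \eqn{t(m-2)}.
#'
#' @param G centered [genotype_matrix()] (or raw; centered internally).
#' @param P a [phenotype_pair()].
#' @param beta0 null value for the test (default 0).
#' @param level confidence level (default 0.95).
#' @param r2_max upper bound of the profiled search (default \code{1e4}).
#' @param jc optionally, a precomputed [joint_coefs()] (then \code{G},
#'   \code{P} may be \code{NULL}).
#' @return An object of class \code{"mr_fit"}.
#' @export
fit_pldmr <- function(G, P, beta0 = 0, level = 0.95, r2_max = 1e4, jc = NULL) {
  if (is.null(jc)) jc <- joint_coefs(G, P)
  if (jc$m < 3) stop("PLDMR needs at least 3 instruments (df = m - 2)")
  ev <- eig_vectors(jc)
  b_prelim <- wls_intercept_eig(ev$a, ev$g, ev$z, 1 / jc$eig_lambda)$beta
  sy2 <- sigma_y2_individual(jc, b_prelim)
  prof <- function(r2) {
    d <- 1 / (r2 + jc$eig_lambda)
    ls <- wls_intercept_eig(ev$a, ev$g, ev$z, d)
    u <- ev$z - ls$mu * ev$a - ls$beta * ev$g
    (jc$m / 2) * log(2 * pi * sy2) + 0.5 * sum(log(r2 + jc$eig_lambda)) +
      sum(d * u^2) / (2 * sy2)
  }
  if (sy2 <= 1e-300) {
    # exact-fit data: no residual variance, r2 unidentified; report the
    # sigma_alpha^2 = 0 boundary
    opt <- list(r2 = 0, value = -Inf)
  } else {
    opt <- minimize_over_r2(prof, r2_max = r2_max)
  }
  d <- 1 / (opt$r2 + jc$eig_lambda)
  ls <- wls_intercept_eig(ev$a, ev$g, ev$z, d)
  u <- ev$z - ls$mu * ev$a - ls$beta * ev$g
  rss_w <- sum(d * u^2)
  phi <- rss_w / ((jc$m - 2) * sy2)
  var_beta <- rss_w / ((jc$m - 2) * ls$prec_beta)  # = phi * sy2 / prec_beta
  new_mr_fit("pldmr", beta_hat = ls$beta, se_beta = sqrt(var_beta),
             df = jc$m - 2, mu_alpha_hat = ls$mu, r2_hat = opt$r2,
             sigma_y2_hat = sy2, overdispersion = phi, converged = TRUE,
             nll_at_optimum = opt$value, beta0 = beta0, level = level,
             jc = jc,
             diagnostics = list(se_mu_alpha = sqrt(phi * sy2 / ls$prec_mu),
                                beta_prelim = b_prelim))
}

#' Fit PLDMR with known (true) variance components
#'
#' The weighted-least-squares display evaluated at externally supplied
#' \eqn{\sigma_\alpha^2} and \eqn{\sigma_Y^2} rather than their MLEs; used
#' as an oracle benchmark in simulation studies.
#'
#' @inheritParams fit_pldmr
#' @param vc_true a [variance_components()] holding the true
#'   \eqn{\sigma_\alpha^2} and \eqn{\sigma_Y^2}.
#' @return An object of class \code{"mr_fit"}.
#' @export
fit_pldmr_t <- function(G, P, vc_true, beta0 = 0, level = 0.95, jc = NULL) {
  if (is.null(jc)) jc <- joint_coefs(G, P)
  if (jc$m < 3) stop("PLDMR_t needs at least 3 instruments (df = m - 2)")
  stopifnot(inherits(vc_true, "variance_components"))
  ev <- eig_vectors(jc)
  d <- 1 / (vc_true$r2 + jc$eig_lambda)
  ls <- wls_intercept_eig(ev$a, ev$g, ev$z, d)
  var_beta <- vc_true$sigma_y2 / ls$prec_beta
  new_mr_fit("pldmr_t", beta_hat = ls$beta, se_beta = sqrt(var_beta),
             df = jc$m - 2, mu_alpha_hat = ls$mu, r2_hat = vc_true$r2,
             sigma_y2_hat = vc_true$sigma_y2, beta0 = beta0, level = level,
             jc = jc)
}

#' Fit LDMR (negligible pleiotropy variance)
#'
#' Closed-form weighted regression of \eqn{\hat\Gamma} on \eqn{\hat\gamma}
#' with intercept, weighting by \eqn{G^TG}; the limiting case
#' \eqn{\sigma_\alpha^2 = 0} of the mixed-effects model. The variance scale
#' \eqn{\hat\sigma_Y^2} is the weighted residual sum of squares divided by
#' \eqn{m - 2}.
#'
#' @inheritParams fit_pldmr
#' @return An object of class \code{"mr_fit"}.
#' @export
fit_ldmr <- function(G, P, beta0 = 0, level = 0.95, jc = NULL) {
  if (is.null(jc)) jc <- joint_coefs(G, P)
  if (jc$m < 3) stop("LDMR needs at least 3 instruments (df = m - 2)")
  ev <- eig_vectors(jc)
  d <- 1 / jc$eig_lambda          # weights = eigenvalues of G'G
  ls <- wls_intercept_eig(ev$a, ev$g, ev$z, d)
  u <- ev$z - ls$mu * ev$a - ls$beta * ev$g
  sigma_y2 <- sum(d * u^2) / (jc$m - 2)
  var_beta <- sigma_y2 / ls$prec_beta
  new_mr_fit("ldmr", beta_hat = ls$beta, se_beta = sqrt(var_beta),
             df = jc$m - 2, mu_alpha_hat = ls$mu, r2_hat = 0,
             sigma_y2_hat = sigma_y2, beta0 = beta0, level = level, jc = jc)
}

#' Fit the large-sample approximation PLDMR_a
#'
#' When \eqn{n} is large, \eqn{G^TG = O(n)} makes
#' \eqn{W \approx \sigma_\alpha^{-2} I}, so ordinary least squares of
#' \eqn{\hat\Gamma} on \eqn{\hat\gamma} with intercept estimates the causal
#' effect; slope \eqn{= \hat\beta}, intercept \eqn{= \hat\mu_\alpha},
#' residual mean square with \eqn{m-2} df gives the standard error.
#'
#' @param jc an [joint_coefs()] result (or pass \code{G}, \code{P}).
#' @inheritParams fit_pldmr
#' @return An object of class \code{"mr_fit"}.
#' @export
fit_pldmr_a <- function(jc, beta0 = 0, level = 0.95) {
  if (!inherits(jc, "mr_joint_coefs")) stop("'jc' must come from joint_coefs()")
  if (jc$m < 3) stop("PLDMR_a needs at least 3 instruments (df = m - 2)")
  ev <- eig_vectors(jc)
  ls <- wls_intercept_eig(ev$a, ev$g, ev$z, rep(1, jc$m))
  u <- ev$z - ls$mu * ev$a - ls$beta * ev$g
  s2 <- sum(u^2) / (jc$m - 2)
  new_mr_fit("pldmr_a", beta_hat = ls$beta, se_beta = sqrt(s2 / ls$prec_beta),
             df = jc$m - 2, mu_alpha_hat = ls$mu, sigma_y2_hat = NA_real_,
             overdispersion = s2, beta0 = beta0, level = level, jc = jc)
}

#' Fit MR-Egger from marginal summary statistics
#'
#' Weighted least squares of the marginal outcome coefficients
#' \eqn{\tilde\Gamma} on the marginal exposure coefficients
#' \eqn{\tilde\gamma} with intercept, weights \eqn{SE(\tilde\Gamma)^{-2}}.
#' A multiplicative overdispersion \eqn{\hat\sigma^2} is estimated from the
#' weighted residual mean square and floored at 1 (no under-dispersion);
#' slope inference uses \eqn{t(m-2)}.
#'
#' @param mc an [marginal_coefs()] result.
#' @inheritParams fit_pldmr
#' @return An object of class \code{"mr_fit"}.
#' @export
fit_mr_egger <- function(mc, beta0 = 0, level = 0.95) {
  stopifnot(inherits(mc, "mr_marginal_coefs"))
  m <- mc$m
  if (m < 3) stop("MR-Egger needs at least 3 instruments (df = m - 2)")
  w <- 1 / mc$se_Gamma_tilde^2
  ls <- wls_intercept_eig(rep(1, m), mc$gamma_tilde, mc$Gamma_tilde, w)
  u <- mc$Gamma_tilde - ls$mu - ls$beta * mc$gamma_tilde
  disp <- max(1, sum(w * u^2) / (m - 2))
  new_mr_fit("egger", beta_hat = ls$beta, se_beta = sqrt(disp / ls$prec_beta),
             df = m - 2, mu_alpha_hat = ls$mu, overdispersion = disp,
             beta0 = beta0, level = level, mc = mc)
}

#' Fit the inverse-variance weighted (IVW) estimator
#'
#' The MR-Egger regression with the intercept constrained to zero:
#' no-intercept weighted regression of \eqn{\tilde\Gamma} on
#' \eqn{\tilde\gamma}, weights \eqn{SE(\tilde\Gamma)^{-2}}, with the same
#' floored multiplicative overdispersion and \eqn{t(m-1)} inference. With a
#' single instrument this reduces to the Wald ratio with normal inference.
#'
#' @inheritParams fit_mr_egger
#' @return An object of class \code{"mr_fit"}.
#' @export
fit_ivw <- function(mc, beta0 = 0, level = 0.95) {
  stopifnot(inherits(mc, "mr_marginal_coefs"))
  m <- mc$m
  w <- 1 / mc$se_Gamma_tilde^2
  Sgg <- sum(w * mc$gamma_tilde^2)
  if (Sgg == 0) stop("all marginal exposure coefficients are zero; IVW undefined")
  beta_hat <- sum(w * mc$gamma_tilde * mc$Gamma_tilde) / Sgg
  if (m == 1) {
    return(new_mr_fit("ivw", beta_hat = beta_hat,
                      se_beta = mc$se_Gamma_tilde / abs(mc$gamma_tilde),
                      df = Inf, beta0 = beta0, level = level, mc = mc))
  }
  u <- mc$Gamma_tilde - beta_hat * mc$gamma_tilde
  disp <- max(1, sum(w * u^2) / (m - 1))
  new_mr_fit("ivw", beta_hat = beta_hat, se_beta = sqrt(disp / Sgg),
             df = m - 1, overdispersion = disp, beta0 = beta0, level = level,
             mc = mc)
}

#' Mendelian-randomization causal-effect estimation
#'
#' The front-end fitting function. Given individual-level data — an
#' additive genotype dosage matrix, an exposure vector and an outcome
#' vector — estimates the causal effect of the exposure on the outcome,
#' correcting for linkage disequilibrium among the instruments and for the
#' mean and variance of their pleiotropic effects.
#'
#' Methods: \code{"pldmr"} (profile maximum likelihood under the
#' mixed-effects model), \code{"pldmr_t"} (weights from user-supplied true
#' variance components), \code{"pldmr_a"} (large-n OLS approximation),
#' \code{"ldmr"} (zero pleiotropy-variance approximation), \code{"egger"}
#' and \code{"ivw"} (summary-statistic baselines computed from per-variant
#' marginal regressions). Genotypes and phenotypes are centered internally,
#' so all regressions are intercept-free apart from the pleiotropy
#' intercept \eqn{\mu_\alpha}.
#'
#' @param genotypes \code{n x m} dosage matrix or [genotype_matrix()].
#' @param exposure length-\code{n} exposure vector.
#' @param outcome length-\code{n} outcome vector.
#' @param method one of \code{"pldmr"}, \code{"pldmr_t"}, \code{"pldmr_a"},
#'   \code{"ldmr"}, \code{"egger"}, \code{"ivw"}.
#' @param beta0 null value of the causal effect for the test (default 0).
#' @param level confidence level (default 0.95).
#' @param vc_true [variance_components()], required for
#'   \code{method = "pldmr_t"}.
#' @param ... passed on to the method-specific fitter (e.g. \code{r2_max}).
#' @return An object of class \code{"mr_fit"} with \code{print},
#'   \code{summary}, \code{coef}, \code{confint}, \code{residuals} and
#'   \code{plot} methods.
#' @examples
#' sc <- mr_scenario(n = 800, m = 10, beta = 0.05, seed = 7)
#' dat <- simulate_mr_data(sc)
#' fit <- pldmr(dat$genotypes, dat$exposure, dat$outcome)
#' summary(fit)
#' @export
pldmr <- function(genotypes, exposure, outcome,
                  method = c("pldmr", "pldmr_t", "pldmr_a", "ldmr", "egger", "ivw"),
                  beta0 = 0, level = 0.95, vc_true = NULL, ...) {
  method <- match.arg(method)
  G <- center_genotypes(as_genotype_matrix(genotypes))
  P <- phenotype_pair(exposure, outcome)
  P <- check_pair(G, P)
  if (method %in% c("egger", "ivw")) {
    mc <- marginal_coefs(G, P)
    return(switch(method,
                  egger = fit_mr_egger(mc, beta0 = beta0, level = level),
                  ivw = fit_ivw(mc, beta0 = beta0, level = level)))
  }
  jc <- joint_coefs(G, P)
  switch(method,
         pldmr = fit_pldmr(NULL, NULL, beta0 = beta0, level = level, jc = jc, ...),
         pldmr_a = fit_pldmr_a(jc, beta0 = beta0, level = level),
         ldmr = fit_ldmr(NULL, NULL, beta0 = beta0, level = level, jc = jc),
         pldmr_t = {
           if (is.null(vc_true)) stop("method 'pldmr_t' requires 'vc_true'")
           fit_pldmr_t(NULL, NULL, vc_true, beta0 = beta0, level = level, jc = jc)
         })
}
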