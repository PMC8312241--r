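# Shared linear-algebra layer: joint and marginal regression coefficients,
# Gram-matrix eigendecomposition, weight-matrix construction.

# Deterministic sign convention: first entry of each eigenvector with
# |entry| > tol is made positive, so the decomposition is reproducible
# across LAPACK builds.
fix_eigen_signs <- function(Q, tol = 1e-12) {
  for (k in seq_len(ncol(Q))) {
    idx <- which(abs(Q[, k]) > tol)
    if (length(idx) && Q[idx[1L], k] < 0) Q[, k] <- -Q[, k]
  }
  Q
}

#' Joint (multiple-regression) instrument-effect coefficients
#'
#' Regresses the outcome and the exposure on all variants jointly:
#' \eqn{\hat\Gamma = (G^T G)^{-1} G^T Y} and
#' \eqn{\hat\gamma = (G^T G)^{-1} G^T X}. The Gram matrix \eqn{G^T G} and the
#' eigendecomposition \eqn{(G^T G)^{-1} = Q \Lambda Q^T} are computed once
#' and cached, since every likelihood evaluation reuses them. Eigenvalues
#' are sorted in decreasing order with a deterministic eigenvector sign
#' convention.
#'
#' @param G a centered [genotype_matrix()] (or plain matrix, centered here).
#' @param P a [phenotype_pair()].
#' @param cond_max reject Gram matrices whose condition number exceeds this
#'   threshold (default \code{1e12}) instead of silently regularizing;
#'   pruning collinear variants is the caller's modelling decision.
#' @return An object of class \code{"mr_joint_coefs"}: list with
#'   \code{gamma_hat}, \code{Gamma_hat}, \code{gram}, \code{eig_Q},
#'   \code{eig_lambda} (eigenvalues of \eqn{(G^TG)^{-1}}, decreasing),
#'   \code{n}, \code{m}, \code{variant_ids}.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(200 * 4, 2, 0.3), 200, 4)
#' X <- rnorm(200); Y <- rnorm(200)
#' jc <- joint_coefs(G, phenotype_pair(X, Y))
#' jc$gamma_hat
#' @export
joint_coefs <- function(G, P, cond_max = 1e12) {
  G <- as_genotype_matrix(G)
  n <- nrow(G$values)
  m <- ncol(G$values)
  if (n <= m) stop("need more samples than variants (n > m) to invert the Gram matrix")
  G <- center_genotypes(G)
  P <- check_pair(G, P)
  gram <- crossprod(G$values)
  e <- eigen(gram, symmetric = TRUE)  # values decreasing
  if (min(e$values) <= 0 || max(e$values) / min(e$values) > cond_max) {
    load <- abs(e$vectors[, m])
    worst <- G$variant_ids[order(load, decreasing = TRUE)[seq_len(min(3L, m))]]
    stop("Gram matrix is rank deficient or ill-conditioned (condition number > ",
         format(cond_max), "); near-collinear variants include: ",
         paste(worst, collapse = ", "))
  }
  # eigenvalues of the inverse, sorted decreasing
  lambda <- rev(1 / e$values)
  Q <- fix_eigen_signs(e$vectors[, rev(seq_len(m)), drop = FALSE])
  GtY <- crossprod(G$values, P$outcome)
  GtX <- crossprod(G$values, P$exposure)
  Gamma_hat <- drop(Q %*% (lambda * crossprod(Q, GtY)))
  gamma_hat <- drop(Q %*% (lambda * crossprod(Q, GtX)))
  # residual cross-moments of the two multiple regressions (e_X = X - G
  # gamma_hat, e_Y = Y - G Gamma_hat), used to estimate sigma_Y^2 at
  # individual-level precision; computed via normal-equation identities
  rss_xx <- sum(P$exposure^2) - sum(GtX * gamma_hat)
  rss_yy <- sum(P$outcome^2) - sum(GtY * Gamma_hat)
  rss_xy <- sum(P$exposure * P$outcome) - sum(GtY * gamma_hat)
  structure(list(gamma_hat = gamma_hat, Gamma_hat = Gamma_hat, gram = gram,
                 eig_Q = Q, eig_lambda = lambda, n = n, m = m,
                 variant_ids = G$variant_ids,
                 rss_xx = rss_xx, rss_yy = rss_yy, rss_xy = rss_xy),
            class = "mr_joint_coefs")
}

#' @export
print.mr_joint_coefs <- function(x, ...) {
  cat(sprintf("mr_joint_coefs: m = %d variants, n = %d samples\n", x$m, x$n))
  cat(sprintf("  eigenvalues of (G'G)^-1 in [%.3g, %.3g]\n",
              min(x$eig_lambda), max(x$eig_lambda)))
  invisible(x)
}

#' Marginal (per-variant) instrument-effect coefficients
#'
#' Per-variant simple-regression slopes of the outcome and the exposure on
#' each centered genotype column, without intercept, plus the standard error
#' of the outcome slope. The residual variance uses an \eqn{n - 1}
#' denominator (one slope, no intercept on centered data).
#'
#' @inheritParams joint_coefs
#' @return An object of class \code{"mr_marginal_coefs"}: list with
#'   \code{gamma_tilde}, \code{Gamma_tilde}, \code{se_Gamma_tilde},
#'   \code{se_gamma_tilde}, \code{n}, \code{m}, \code{variant_ids}.
#' @export
marginal_coefs <- function(G, P) {
  G <- center_genotypes(as_genotype_matrix(G))
  P <- check_pair(G, P)
  ex <- marginal_single(G$values, P$exposure)
  out <- marginal_single(G$values, P$outcome)
  structure(list(gamma_tilde = ex$slope, Gamma_tilde = out$slope,
                 se_Gamma_tilde = out$se, se_gamma_tilde = ex$se,
                 n = nrow(G$values), m = ncol(G$values),
                 variant_ids = G$variant_ids),
            class = "mr_marginal_coefs")
}

# slopes/SEs of y on each centered column of V, no intercept, df = n - 1
marginal_single <- function(V, y) {
  n <- nrow(V)
  ss <- colSums(V^2)
  if (any(ss == 0)) stop("zero-variance genotype column in marginal regression")
  slope <- drop(crossprod(V, y)) / ss
  rss <- sum(y^2) - 2 * slope * drop(crossprod(V, y)) + slope^2 * ss
  # numerical floor: rss can go slightly negative for an exact fit
  rss <- pmax(rss, 0)
  se <- sqrt(rss / (n - 1) / ss)
  list(slope = slope, se = se)
}

#' Variance components of the pleiotropy model
#'
#' Bundles the mean pleiotropic effect \eqn{\mu_\alpha}, the pleiotropy
#' variance \eqn{\sigma_\alpha^2}, the outcome error variance
#' \eqn{\sigma_Y^2}, and their ratio \eqn{r^2 = \sigma_\alpha^2/\sigma_Y^2}.
#'
#' @param mu_alpha mean pleiotropic effect.
#' @param sigma_alpha2 pleiotropy variance (non-negative).
#' @param sigma_y2 outcome error variance (positive).
#' @return An object of class \code{"variance_components"}.
#' @export
variance_components <- function(mu_alpha = 0, sigma_alpha2 = 0, sigma_y2 = 1) {
  if (sigma_y2 <= 0) stop("'sigma_y2' must be positive")
  if (sigma_alpha2 < 0) stop("'sigma_alpha2' must be non-negative")
  structure(list(mu_alpha = mu_alpha, sigma_alpha2 = sigma_alpha2,
                 sigma_y2 = sigma_y2, r2 = sigma_alpha2 / sigma_y2),
            class = "variance_components")
}

#' Precision (weight) matrix of the joint outcome coefficients
#'
#' Under the mixed-effects model the joint outcome coefficients satisfy
#' \eqn{\hat\Gamma = \mu_\alpha 1 + \beta\hat\gamma + \epsilon} with
#' \eqn{\epsilon \sim N(0, W^{-1})} and
#' \eqn{W = [\sigma_\alpha^2 I_m + \sigma_Y^2 (G^TG)^{-1}]^{-1}}.
#' Computed in the cached eigenbasis as
#' \eqn{W = \sigma_Y^{-2} Q (r^2 I + \Lambda)^{-1} Q^T}.
#'
#' @param vc a [variance_components()].
#' @param jc an [joint_coefs()] result.
#' @return A symmetric positive-definite \code{m x m} matrix.
#' @export
weight_matrix <- function(vc, jc) {
  stopifnot(inherits(jc, "mr_joint_coefs"))
  if (vc$sigma_y2 <= 0) stop("'sigma_y2' must be positive")
  d <- 1 / (vc$r2 + jc$eig_lambda) / vc$sigma_y2
  W <- jc$eig_Q %*% (d * t(jc$eig_Q))
  (W + t(W)) / 2
}

# quadratic forms of the W-weighted regression with intercept, in the
# eigenbasis: given d_k = 1/(r2 + lambda_k) (W = Q diag(d) Q' / sigma_y2),
# returns the GLS solution of z on [a, g] plus the beta precision
# gamma' W^{1/2}(I - P_{W^{1/2}1}) W^{1/2} gamma (without the 1/sigma_y2).
wls_intercept_eig <- function(a, g, z, d) {
  Saa <- sum(d * a * a); Sag <- sum(d * a * g); Sgg <- sum(d * g * g)
  Saz <- sum(d * a * z); Sgz <- sum(d * g * z)
  det <- Saa * Sgg - Sag^2
  if (!is.finite(det) || det <= .Machine$double.eps * Saa * Sgg * 1e4) {
    stop("instrument effects are collinear with the intercept; ",
         "mean pleiotropy and causal effect are not jointly identifiable")
  }
  mu <- (Sgg * Saz - Sag * Sgz) / det
  beta <- (Saa * Sgz - Sag * Saz) / det
  # precision of beta after projecting out the weighted intercept
  prec_beta <- Sgg - Sag^2 / Saa
  list(mu = mu, beta = beta, prec_beta = prec_beta, prec_mu = Saa - Sag^2 / Sgg)
}
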