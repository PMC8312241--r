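# PLDMR likelihood in the eigenbasis of (G'G)^{-1} and its r^2 profile.

#' Negative log-likelihood of the pleiotropy/LD mixed-effects model
#'
#' Evaluates \eqn{-\log L(\mu_\alpha, \beta, r^2, \sigma_Y^2; \hat\Gamma,
#' \hat\gamma)} in the eigenbasis: with
#' \eqn{u = Q^T(\hat\Gamma - \mu_\alpha 1 - \beta\hat\gamma)},
#' \deqn{\mathrm{NLL} = \frac{m}{2}\log(2\pi\sigma_Y^2)
#'   + \frac12\sum_k \log(r^2 + \lambda_k)
#'   + \frac{1}{2\sigma_Y^2}\sum_k \frac{u_k^2}{r^2 + \lambda_k}.}
#' This equals the dense-matrix form with weight
#' \eqn{W = [\sigma_\alpha^2 I + \sigma_Y^2 (G^TG)^{-1}]^{-1}} evaluated at
#' \eqn{\sigma_\alpha^2 = r^2 \sigma_Y^2}.
#'
#' @param mu_alpha mean pleiotropic effect.
#' @param beta causal effect.
#' @param r2 variance ratio \eqn{\sigma_\alpha^2/\sigma_Y^2}, non-negative.
#' @param sigma_y2 outcome error variance, positive.
#' @param jc an [joint_coefs()] result.
#' @return The negative log-likelihood (a scalar).
#' @export
pldmr_nll <- function(mu_alpha, beta, r2, sigma_y2, jc) {
  stopifnot(inherits(jc, "mr_joint_coefs"))
  if (!all(is.finite(c(mu_alpha, beta, r2, sigma_y2)))) {
    stop("non-finite parameter value")
  }
  if (r2 < 0) stop("'r2' must be non-negative")
  if (sigma_y2 <= 0) stop("'sigma_y2' must be positive")
  u <- drop(crossprod(jc$eig_Q, jc$Gamma_hat - mu_alpha - beta * jc$gamma_hat))
  dk <- r2 + jc$eig_lambda
  (jc$m / 2) * log(2 * pi * sigma_y2) + 0.5 * sum(log(dk)) +
    sum(u^2 / dk) / (2 * sigma_y2)
}

#' Profile the likelihood at a fixed variance ratio
#'
#' For fixed \eqn{r^2}, the remaining parameters maximize the likelihood in
#' closed form: \eqn{(\mu_\alpha, \beta)} solve the two-parameter
#' generalized least squares of \eqn{Q^T\hat\Gamma} on \eqn{[Q^T 1,
#' Q^T\hat\gamma]} with diagonal weights \eqn{1/(r^2+\lambda_k)}, and
#' \eqn{\sigma_Y^2 = m^{-1}\sum_k u_k^2/(r^2+\lambda_k)} at those values.
#'
#' @param r2 non-negative variance ratio.
#' @param jc an [joint_coefs()] result.
#' @return List with \code{mu_alpha}, \code{beta}, \code{sigma_y2} and
#'   \code{nll} (the negative log-likelihood at the returned quadruple;
#'   \code{-Inf} with \code{sigma_y2 = 0} flags an exact-fit boundary).
#' @export
profile_given_r2 <- function(r2, jc) {
  stopifnot(inherits(jc, "mr_joint_coefs"))
  if (!is.finite(r2) || r2 < 0) stop("'r2' must be finite and non-negative")
  a <- drop(colSums(jc$eig_Q))              # Q' 1
  g <- drop(crossprod(jc$eig_Q, jc$gamma_hat))
  z <- drop(crossprod(jc$eig_Q, jc$Gamma_hat))
  d <- 1 / (r2 + jc$eig_lambda)
  ls <- wls_intercept_eig(a, g, z, d)
  u <- z - ls$mu * a - ls$beta * g
  s2 <- sum(d * u^2) / jc$m
  nll <- if (s2 > 0) {
    (jc$m / 2) * log(2 * pi * s2) + 0.5 * sum(log(r2 + jc$eig_lambda)) + jc$m / 2
  } else {
    -Inf  # exact fit: likelihood unbounded, boundary case
  }
  list(mu_alpha = ls$mu, beta = ls$beta, sigma_y2 = s2, nll = nll)
}

# Minimize a 1-D objective over r2 in [0, r2_max]: coarse log-spaced
# bracket (plus the boundary point 0) followed by stats::optimize() on the
# bracketing interval; r2 = 0 is a legitimate boundary minimizer and wins
# ties. Returns list(r2, value).
minimize_over_r2 <- function(f, r2_max = 1e4, grid_points = 25L, tol = 1e-10) {
  grid <- c(0, 10^seq(-8, log10(r2_max), length.out = grid_points))
  vals <- vapply(grid, f, numeric(1))
  if (any(vals == -Inf)) {
    i <- which(vals == -Inf)[1L]  # exact fit: smallest such r2
    return(list(r2 = grid[i], value = -Inf))
  }
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  best_r2 <- grid[i]
  best_val <- vals[i]
  if (lo < hi) {
    opt <- stats::optimize(f, interval = c(lo, hi), tol = tol)
    if (opt$objective <= best_val) {
      best_r2 <- opt$minimum
      best_val <- opt$objective
    }
  }
  f0 <- vals[1L]
  if (f0 <= best_val + 1e-12) {
    best_r2 <- 0
    best_val <- f0
  }
  list(r2 = best_r2, value = best_val)
}
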