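# Independent oracles used across the suite. These deliberately avoid the
# package's eigenbasis shortcuts: dense matrix algebra and generic
# optimizers only.

# literal dense evaluation of the mixed-effects likelihood:
# NLL = m/2 log 2pi - 1/2 log|W| + 1/2 res' W res,
# W = [sigma_a2 I + sigma_y2 (G'G)^{-1}]^{-1}
oracle_dense_nll <- function(mu, beta, sigma_a2, sigma_y2, gram, Gamma_hat, gamma_hat) {
  m <- length(Gamma_hat)
  W <- solve(sigma_a2 * diag(m) + sigma_y2 * solve(gram))
  res <- Gamma_hat - mu - beta * gamma_hat
  as.numeric((m / 2) * log(2 * pi) -
               0.5 * determinant(W, logarithm = TRUE)$modulus +
               0.5 * t(res) %*% W %*% res)
}

# generalized least squares of y on columns of X with weight matrix W,
# via the augmented normal equations
oracle_gls <- function(y, X, W) {
  A <- t(X) %*% W %*% X
  b <- solve(A, t(X) %*% W %*% y)
  list(coef = drop(b), cov = solve(A))
}

# multi-start full-dimensional maximization of the likelihood over
# (mu_alpha, beta, r2) at a fixed sigma_y2 (the same objective fit_pldmr
# maximizes): Nelder-Mead on (mu, beta, log r2), r2 clamped to the same
# [0, 1e4] box the package searches (the likelihood can be maximized on
# that boundary, and at the r2 = 0 boundary via log r2 -> -Inf)
oracle_multistart_pldmr <- function(jc, sigma_y2, n_starts = 8, seed = 1) {
  set.seed(seed)
  clamp_r2 <- function(lr) min(exp(lr), 1e4)
  f <- function(p) {
    v <- try(pldmr_nll(p[1], p[2], clamp_r2(p[3]), sigma_y2, jc),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- c(rnorm(1, 0, 0.5), rnorm(1, 0, 0.5), runif(1, -14, log(1e4)))
    o <- try(stats::optim(p0, f, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-15)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    # restart from the incumbent to escape simplex collapse
    o <- stats::optim(o$par, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(mu_alpha = best$par[1], beta = best$par[2],
       r2 = clamp_r2(best$par[3]), nll = best$value)
}

# centered design with mutually orthogonal, zero-sum columns (Helmert
# contrasts), handy for engineered-Gram cases
orthogonal_centered_design <- function(n, m, scale = 1) {
  H <- stats::contr.helmert(n)[, seq_len(m), drop = FALSE]
  sweep(H, 2, sqrt(colSums(H^2)), "/") * scale
}

# quick seeded dataset off the package simulator
quick_dataset <- function(n = 400, m = 8, seed = 1, ...) {
  sc <- mr_scenario(n = n, m = m, seed = seed, ...)
  simulate_mr_data(sc, 1)
}

jc_of <- function(dat) joint_coefs(dat$genotypes, phenotype_pair(dat$exposure, dat$outcome))

# build an mr_joint_coefs object directly from a centered design and
# centered phenotypes (bypassing genotype dosage validation)
jc_from_design <- function(Gc, x, y) {
  G <- structure(list(values = Gc, sample_ids = paste0("S", seq_len(nrow(Gc))),
                      variant_ids = paste0("V", seq_len(ncol(Gc))),
                      centered = TRUE),
                 class = "genotype_matrix")
  joint_coefs(G, phenotype_pair(x, y))
}
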