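# model_core layer: centering, joint/marginal coefficients, weight matrix.

test_that("center_columns subtracts column means and is idempotent", {
  expect_equal(drop(center_columns(cbind(c(0, 1, 2)))), c(-1, 0, 1))
  cc <- cbind(c(-1, 0, 1))
  expect_equal(center_columns(cc), cc)
  set.seed(4)
  M <- matrix(sample(0:2, 6, replace = TRUE), 3, 2)
  out <- center_columns(M)
  expect_equal(dim(out), dim(M))
  # recompute means with an explicit loop
  for (j in 1:2) expect_equal(sum(out[, j]) / 3, 0)
})

test_that("joint_coefs matches closed forms and a normal-equations oracle", {
  n <- 60
  # orthonormal centered columns: Gram = I so Gamma_hat = G'Y
  Gc <- orthogonal_centered_design(n, 4)
  set.seed(11)
  y <- rnorm(n); y <- y - mean(y)
  x <- rnorm(n); x <- x - mean(x)
  jc <- jc_from_design(Gc, x, y)
  expect_equal(jc$Gamma_hat, drop(crossprod(Gc, y)), tolerance = 1e-12)

  # exact linear model: X = G c with no noise recovers c
  cvec <- c(2, -1, 0.5, 3)
  jc2 <- jc_from_design(Gc, drop(Gc %*% cvec), y)
  expect_equal(jc2$gamma_hat, cvec, tolerance = 1e-10)

  # seeded 50x4 dosage matrix vs brute-force solve of G'G b = G'X
  set.seed(42)
  G <- matrix(rbinom(50 * 4, 2, 0.35), 50, 4)
  X <- rnorm(50); Y <- rnorm(50)
  jc3 <- joint_coefs(G, phenotype_pair(X, Y))
  Gc3 <- center_columns(G)
  expect_equal(jc3$gamma_hat,
               drop(solve(crossprod(Gc3), crossprod(Gc3, X - mean(X)))),
               tolerance = 1e-10)
  expect_equal(jc3$Gamma_hat,
               drop(solve(crossprod(Gc3), crossprod(Gc3, Y - mean(Y)))),
               tolerance = 1e-10)
})

test_that("eigendecomposition reconstructs the inverse Gram", {
  dat <- quick_dataset(n = 300, m = 6, seed = 5, rho_g = 0.5)
  jc <- jc_of(dat)
  inv <- jc$eig_Q %*% (jc$eig_lambda * t(jc$eig_Q))
  expect_lt(norm(inv - solve(jc$gram), "F") / norm(inv, "F"), 1e-8)
  expect_true(all(jc$eig_lambda > 0))
  expect_true(all(diff(jc$eig_lambda) <= 0))  # sorted decreasing
})

test_that("joint_coefs is permutation-equivariant and shift-invariant", {
  set.seed(7)
  G <- matrix(rbinom(80 * 5, 2, 0.3), 80, 5)
  X <- rnorm(80); Y <- rnorm(80)
  jc <- joint_coefs(G, phenotype_pair(X, Y))
  perm <- c(3, 1, 5, 2, 4)
  jcp <- joint_coefs(G[, perm], phenotype_pair(X, Y))
  expect_equal(jcp$gamma_hat, unname(jc$gamma_hat[perm]), tolerance = 1e-10,
               ignore_attr = TRUE)
  # adding constants before centering changes nothing
  jcs <- joint_coefs(G, phenotype_pair(X + 100, Y - 7))
  expect_equal(jcs$gamma_hat, jc$gamma_hat, tolerance = 1e-10)
  expect_equal(jcs$Gamma_hat, jc$Gamma_hat, tolerance = 1e-10)
})

test_that("collinear or monomorphic genotypes are rejected with names", {
  set.seed(8)
  G <- matrix(rbinom(50 * 3, 2, 0.4), 50, 3)
  G <- cbind(G, G[, 1])  # exact duplicate column
  expect_error(joint_coefs(G, phenotype_pair(rnorm(50), rnorm(50))),
               "ill-conditioned|rank deficient")
  Gm <- matrix(rbinom(50 * 2, 2, 0.4), 50, 2)
  Gm[, 2] <- 1
  expect_error(center_genotypes(genotype_matrix(Gm)), "monomorphic")
  # n <= m refused before inversion
  expect_error(joint_coefs(matrix(rbinom(8, 2, 0.5), 2, 4),
                           phenotype_pair(rnorm(2), rnorm(2))),
               "n > m")
})

test_that("marginal_coefs match per-column least squares", {
  set.seed(12)
  G <- matrix(rbinom(200 * 5, 2, 0.3), 200, 5)
  X <- rnorm(200); Y <- rnorm(200)
  mc <- marginal_coefs(G, phenotype_pair(X, Y))
  Gc <- center_columns(G); Yc <- Y - mean(Y)
  for (j in 1:5) {
    b <- sum(Gc[, j] * Yc) / sum(Gc[, j]^2)
    expect_equal(mc$Gamma_tilde[[j]], b, tolerance = 1e-10)
    rss <- sum((Yc - b * Gc[, j])^2)
    expect_equal(mc$se_Gamma_tilde[[j]], sqrt(rss / 199 / sum(Gc[, j]^2)),
                 tolerance = 1e-10)
  }
  # exact fit: slope 3, SE ~ 0
  mc2 <- marginal_coefs(G[, 1, drop = FALSE],
                        phenotype_pair(rnorm(200), 3 * Gc[, 1]))
  expect_equal(mc2$Gamma_tilde[[1]], 3, tolerance = 1e-10)
  expect_lt(mc2$se_Gamma_tilde[[1]], 1e-6)
  # single regressor: marginal equals joint
  jc1 <- joint_coefs(G[, 1, drop = FALSE], phenotype_pair(X, Y))
  expect_equal(mc$Gamma_tilde[[1]], jc1$Gamma_hat[[1]], tolerance = 1e-10)
})

test_that("weight matrix agrees between direct inversion and eigenbasis", {
  dat <- quick_dataset(n = 250, m = 5, seed = 9, rho_g = 0.4)
  jc <- jc_of(dat)
  # sigma_a2 = 0: W = sigma_y^{-2} G'G
  W0 <- weight_matrix(variance_components(0, 0, 4), jc)
  expect_equal(W0, unname(jc$gram) / 4, tolerance = 1e-8, ignore_attr = TRUE)
  # engineered diagonal Gram: closed form (sigma_a2 + sigma_y2/n)^{-1} I
  n <- 40
  Gc <- orthogonal_centered_design(n, 3, scale = sqrt(n))
  jcd <- jc_from_design(Gc, rnorm(n), rnorm(n))
  Wd <- weight_matrix(variance_components(0, 0.01, 4), jcd)
  expect_equal(Wd, diag(3) / (0.01 + 4 / n), tolerance = 1e-8)
  # generic: dense inversion oracle
  W <- weight_matrix(variance_components(0, 0.01, 4), jc)
  Wdense <- solve(0.01 * diag(5) + 4 * solve(jc$gram))
  expect_lt(norm(W - Wdense, "F") / norm(W, "F"), 1e-8)
})

test_that("projection onto W^{1/2}1 is symmetric and idempotent", {
  dat <- quick_dataset(n = 200, m = 6, seed = 10, rho_g = 0.3)
  jc <- jc_of(dat)
  W <- weight_matrix(variance_components(0, 0.05, 2), jc)
  e <- eigen(W, symmetric = TRUE)
  Whalf <- e$vectors %*% (sqrt(e$values) * t(e$vectors))
  v <- drop(Whalf %*% rep(1, 6))
  P <- outer(v, v) / sum(v^2)
  expect_equal(P, t(P), tolerance = 1e-12)
  expect_lt(max(abs(P %*% P - P)), 1e-10)
})
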