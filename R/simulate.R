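# Genotype/phenotype simulator: Gaussian-copula genotypes with Toeplitz
# LD structure, and phenotypes from the pleiotropy mixed-effects model
#   X = G gamma + eps_X,  Y = G alpha + X beta + eps_Y,
#   (eps_X, eps_Y) bivariate normal with correlation rho,
#   alpha ~ N(mu_alpha 1, sigma_alpha^2 I).

#' Define a simulation scenario
#'
#' Bundles the full parameterization of one Monte-Carlo scenario. The
#' defaults are the simulation study's base conditions: minor allele
#' frequencies uniform on [0.2, 0.4], instrument strengths uniform on
#' [0.5, 4], \eqn{\sigma_X = \sigma_Y = 2}, confounding correlation
#' \eqn{\rho = 0.5}, nominal level 0.05. Minor allele frequencies and
#' instrument strengths are redrawn each replicate (set
#' \code{redraw_effects = FALSE} to fix them at the first replicate's draw).
#'
#' @param n sample size.
#' @param m number of variants (instruments).
#' @param rho_g LD decay base in [0, 1); genotype correlation falls off as
#'   \eqn{\rho_g^{|j_1-j_2|}}.
#' @param mu_alpha mean pleiotropic effect (0 = balanced pleiotropy).
#' @param sigma_alpha pleiotropic-effect standard deviation.
#' @param beta true causal effect.
#' @param sigma_x,sigma_y error standard deviations of exposure and outcome.
#' @param rho correlation of the exposure and outcome errors (confounding).
#' @param maf_low,maf_high bounds of the uniform MAF distribution.
#' @param gamma_low,gamma_high bounds of the uniform instrument-strength
#'   distribution.
#' @param n_reps number of Monte-Carlo replicates.
#' @param seed base RNG seed.
#' @param alpha_level nominal significance level of the tests.
#' @param redraw_effects redraw MAF and gamma each replicate (default TRUE).
#' @return An object of class \code{"mr_scenario"}.
#' @examples
#' mr_scenario(n = 1000, m = 25, rho_g = 0.3, mu_alpha = 0.1)
#' @export
mr_scenario <- function(n = 5000, m = 25, rho_g = 0, mu_alpha = 0,
                        sigma_alpha = 0.1, beta = 0, sigma_x = 2, sigma_y = 2,
                        rho = 0.5, maf_low = 0.2, maf_high = 0.4,
                        gamma_low = 0.5, gamma_high = 4, n_reps = 2000L,
                        seed = 1L, alpha_level = 0.05, redraw_effects = TRUE) {
  if (rho_g < 0 || rho_g >= 1) stop("'rho_g' must be in [0, 1)")
  if (rho <= -1 || rho >= 1) stop("'rho' must be in (-1, 1)")
  if (sigma_x <= 0 || sigma_y <= 0) stop("error scales must be positive")
  if (sigma_alpha < 0) stop("'sigma_alpha' must be non-negative")
  if (maf_low > maf_high || maf_low <= 0 || maf_high > 0.5) {
    stop("MAF bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  }
  if (gamma_low > gamma_high) stop("'gamma_low' must not exceed 'gamma_high'")
  if (!(n > m) || m < 3) stop("need n > m >= 3")
  if (alpha_level <= 0 || alpha_level >= 1) stop("'alpha_level' must be in (0, 1)")
  structure(list(n = as.integer(n), m = as.integer(m), rho_g = rho_g,
                 mu_alpha = mu_alpha, sigma_alpha = sigma_alpha, beta = beta,
                 sigma_x = sigma_x, sigma_y = sigma_y, rho = rho,
                 maf_low = maf_low, maf_high = maf_high,
                 gamma_low = gamma_low, gamma_high = gamma_high,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 alpha_level = alpha_level,
                 redraw_effects = isTRUE(redraw_effects)),
            class = "mr_scenario")
}

#' @export
print.mr_scenario <- function(x, ...) {
  cat(sprintf(
    "mr_scenario: n=%d m=%d rho_g=%g mu_alpha=%g sigma_alpha=%g beta=%g\n",
    x$n, x$m, x$rho_g, x$mu_alpha, x$sigma_alpha, x$beta))
  cat(sprintf("  sigma_x=%g sigma_y=%g rho=%g MAF~U[%g,%g] gamma~U[%g,%g]\n",
              x$sigma_x, x$sigma_y, x$rho, x$maf_low, x$maf_high,
              x$gamma_low, x$gamma_high))
  cat(sprintf("  n_reps=%d seed=%d level=%g\n", x$n_reps, x$seed, x$alpha_level))
  invisible(x)
}

#' Toeplitz LD correlation matrix
#'
#' The \eqn{(j_1, j_2)} entry is \eqn{\rho_g^{|j_1-j_2|}} — an AR(1)-type
#' correlation that weakens with the relative distance of two loci.
#'
#' @param m dimension.
#' @param rho_g decay base in [0, 1).
#' @return A symmetric positive-definite \code{m x m} matrix with unit
#'   diagonal.
#' @examples
#' toeplitz_sigma(3, 0.6)
#' @export
toeplitz_sigma <- function(m, rho_g) {
  if (rho_g < 0 || rho_g >= 1) stop("'rho_g' must be in [0, 1)")
  stats::toeplitz(rho_g^(0:(m - 1)))
}

# deterministic per-replicate seed below 2^31, mixing base seed and index
rep_seed <- function(seed, rep) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(rep) * 1664525 + 1013904223
  as.integer(s %% 2147483646 + 1)
}

#' Simulate additive genotypes in linkage disequilibrium
#'
#' Gaussian-copula construction: draw \eqn{z_i \sim MVN(0, \Sigma_g)} with
#' the Toeplitz correlation [toeplitz_sigma()], map each coordinate through
#' the standard normal CDF, and assign the genotype as the corresponding
#' quantile of Binomial(2, MAF_j) (smallest dosage whose binomial CDF
#' reaches \eqn{\Phi(z_{ij})}). Marginal allele frequencies therefore match
#' the requested MAFs under Hardy-Weinberg equilibrium while adjacent-locus
#' correlation decays as \eqn{\rho_g^{|j_1-j_2|}}. If a draw produces a
#' monomorphic column (possible at small \eqn{n \cdot} MAF) the whole
#' matrix is redrawn so the LD structure is preserved; the number of
#' attempts is recorded in attribute \code{"attempts"}.
#'
#' @param n number of individuals.
#' @param m number of variants.
#' @param rho_g LD decay base.
#' @param mafs length-\code{m} vector of minor allele frequencies in
#'   (0, 0.5].
#' @return A raw (uncentered) [genotype_matrix()].
#' @export
sim_genotypes <- function(n, m, rho_g, mafs) {
  if (length(mafs) != m) stop("'mafs' must have length m")
  if (any(mafs <= 0 | mafs > 0.5)) stop("MAFs must be in (0, 0.5]")
  R <- if (rho_g > 0) chol(toeplitz_sigma(m, rho_g)) else NULL
  # The inverse-CDF map G = min{k : F_Bin(2,maf)(k) >= Phi(z)} reduces to
  # counting exceeded normal thresholds: G = 1(z > t0) + 1(z > t1) with
  # t0 = qnorm((1-maf)^2), t1 = qnorm(1 - maf^2). Equivalent to
  # qbinom(pnorm(z), 2, maf) but without 2*n*m distribution-function calls.
  t0 <- rep(stats::qnorm((1 - mafs)^2), each = n)
  t1 <- rep(stats::qnorm(1 - mafs^2), each = n)
  for (attempt in 1:50) {
    Z <- matrix(stats::rnorm(n * m), n, m)
    if (!is.null(R)) Z <- Z %*% R
    G <- matrix((Z > t0) + (Z > t1), n, m)
    cm <- colMeans(G)
    if (all(colMeans(G * G) - cm * cm > 0)) {
      out <- structure(list(values = G,
                            sample_ids = paste0("S", seq_len(n)),
                            variant_ids = paste0("V", seq_len(m)),
                            centered = FALSE),
                       class = "genotype_matrix")
      dimnames(out$values) <- list(out$sample_ids, out$variant_ids)
      attr(out, "attempts") <- attempt
      return(out)
    }
  }
  stop("could not draw a polymorphic genotype matrix in 50 attempts; increase n or MAF")
}

#' Simulate one replicate dataset from a scenario
#'
#' Draws minor allele frequencies, genotypes, instrument effects
#' \eqn{\gamma}, pleiotropic effects \eqn{\alpha} and the correlated error
#' pair, then forms \eqn{X = G\gamma + \epsilon_X} and
#' \eqn{Y = G\alpha + X\beta + \epsilon_Y} with column-centered genotypes.
#' The confounder influence is realized solely through
#' \eqn{corr(\epsilon_X, \epsilon_Y) = \rho}.
#'
#' One seeded generator drives each replicate, with fixed stream order
#' (MAFs, copula normals, gamma, alpha, errors), so an identical seed and
#' replicate index reproduce the dataset bit for bit.
#'
#' @param cfg an [mr_scenario()].
#' @param rep replicate index (default 1); combined with \code{cfg$seed} to
#'   seed the generator.
#' @return An object of class \code{"mr_dataset"}: list with
#'   \code{genotypes} (raw dosages), \code{exposure}, \code{outcome} and a
#'   \code{truth} record (gamma, alpha, mafs and all generating
#'   parameters).
#' @export
simulate_mr_data <- function(cfg, rep = 1L) {
  stopifnot(inherits(cfg, "mr_scenario"))
  if (cfg$redraw_effects) {
    set.seed(rep_seed(cfg$seed, rep))
    mafs <- stats::runif(cfg$m, cfg$maf_low, cfg$maf_high)
    G <- sim_genotypes(cfg$n, cfg$m, cfg$rho_g, mafs)
    gamma <- stats::runif(cfg$m, cfg$gamma_low, cfg$gamma_high)
  } else {
    # fixed effects: MAF and gamma come from the replicate-0 stream
    set.seed(rep_seed(cfg$seed, 0L))
    mafs <- stats::runif(cfg$m, cfg$maf_low, cfg$maf_high)
    gamma <- stats::runif(cfg$m, cfg$gamma_low, cfg$gamma_high)
    set.seed(rep_seed(cfg$seed, rep))
    G <- sim_genotypes(cfg$n, cfg$m, cfg$rho_g, mafs)
  }
  alpha <- stats::rnorm(cfg$m, cfg$mu_alpha, cfg$sigma_alpha)
  e1 <- stats::rnorm(cfg$n)
  e2 <- stats::rnorm(cfg$n)
  eps_x <- cfg$sigma_x * e1
  eps_y <- cfg$sigma_y * (cfg$rho * e1 + sqrt(1 - cfg$rho^2) * e2)
  Gc <- center_columns(G$values)
  X <- unname(drop(Gc %*% gamma)) + eps_x
  Y <- unname(drop(Gc %*% alpha)) + X * cfg$beta + eps_y
  structure(list(genotypes = G, exposure = X, outcome = Y,
                 truth = list(gamma = gamma, alpha = alpha, beta = cfg$beta,
                              mu_alpha = cfg$mu_alpha,
                              sigma_alpha2 = cfg$sigma_alpha^2,
                              sigma_x2 = cfg$sigma_x^2,
                              sigma_y2 = cfg$sigma_y^2, rho = cfg$rho,
                              mafs = mafs),
                 config = cfg, rep = as.integer(rep)),
            class = "mr_dataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("mr_dataset: replicate %d of scenario (n=%d, m=%d)\n",
              x$rep, x$config$n, x$config$m))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Genotypes go to \code{genotypes.raw} (PLINK .raw dialect), phenotypes to
#' \code{phenotypes.tsv} (columns \code{IID}, \code{exposure},
#' \code{outcome}), and the generating truth to \code{truth.json}.
#'
#' @param dat an \code{mr_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_mr_dataset <- function(dat, dir) {
  stopifnot(inherits(dat, "mr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(dat$genotypes, file.path(dir, "genotypes.raw"), format = "plink_raw")
  ph <- data.frame(IID = dat$genotypes$sample_ids,
                   exposure = dat$exposure, outcome = dat$outcome,
                   stringsAsFactors = FALSE)
  write_tsv17(ph, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(dat$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
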