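# Preprocessing pipeline: missingness filter -> Hardy-Weinberg test ->
# covariate residualization -> instrument selection -> centering.

#' Drop high-missingness variants and mean-impute the rest
#'
#' Variants whose missing-entry proportion exceeds \code{max_missing}
#' (default 0.20) are dropped; remaining missing entries are imputed with
#' the column mean of the observed dosages (imputed entries stay flagged in
#' the mask).
#'
#' @param G a [genotype_matrix()] with a missingness mask (from
#'   [read_genotypes()]); a mask-free matrix passes through unchanged.
#' @param max_missing maximum tolerated missing proportion, in [0, 1].
#' @return List with \code{genotypes} (complete matrix) and \code{report}
#'   (per-variant \code{data.frame}: id, missing_rate, kept).
#' @export
filter_missingness <- function(G, max_missing = 0.20) {
  G <- as_genotype_matrix(G)
  if (max_missing < 0 || max_missing > 1) stop("'max_missing' must be in [0, 1]")
  mask <- if (is.null(G$mask)) is.na(G$values) else G$mask
  rate <- colMeans(mask)
  keep <- rate <= max_missing
  report <- data.frame(id = G$variant_ids, missing_rate = rate, kept = keep,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!any(keep)) stop("all variants exceed the missingness threshold")
  vals <- G$values[, keep, drop = FALSE]
  kmask <- mask[, keep, drop = FALSE]
  if (any(kmask)) {
    for (j in which(colSums(kmask) > 0)) {
      mj <- mean(vals[!kmask[, j], j])
      vals[kmask[, j], j] <- mj
    }
  }
  out <- genotype_matrix(vals, G$sample_ids, G$variant_ids[keep],
                         centered = FALSE, mask = kmask)
  # imputed values are no longer raw 0/1/2; mark via attribute
  attr(out, "imputed") <- sum(kmask)
  list(genotypes = out, report = report)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness of fit of the observed genotype counts
#' against the Hardy-Weinberg expectation at the sample allele frequency.
#' Monomorphic variants return \eqn{p = 1} by convention.
#'
#' @param dosages vector of dosages in \{0, 1, 2\} (NA ignored).
#' @return The p-value.
#' @examples
#' hwe_test(c(rep(0, 25), rep(1, 50), rep(2, 25)))  # perfect HWE: p = 1
#' @export
hwe_test <- function(dosages) {
  dosages <- dosages[!is.na(dosages)]
  if (!length(dosages)) stop("need at least one non-missing genotype")
  if (!all(dosages %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  n <- length(dosages)
  obs <- c(sum(dosages == 0), sum(dosages == 1), sum(dosages == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expect <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expect)^2 / expect)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Residualize a phenotype on covariates
#'
#' Least-squares residuals of the (optionally log-transformed) phenotype on
#' an intercept plus the covariate columns — e.g. sex, age and age squared
#' — used as the adjusted phenotype in downstream analysis.
#'
#' @param y numeric phenotype vector.
#' @param covariates \code{n x k} numeric matrix or data.frame (no
#'   intercept column; one is added). \code{NULL} means intercept only, so
#'   the result is just the centered phenotype.
#' @param transform \code{"none"} or \code{"log"}.
#' @return The residual vector (mean zero, orthogonal to every covariate).
#' @export
residualize <- function(y, covariates = NULL, transform = c("none", "log")) {
  transform <- match.arg(transform)
  y <- as.numeric(y)
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires strictly positive phenotype values")
    y <- log(y)
  }
  X <- if (is.null(covariates) || NCOL(covariates) == 0) {
    matrix(1, length(y), 1)
  } else {
    cbind(1, as.matrix(covariates))
  }
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  stats::lsfit(X, y, intercept = FALSE)$residuals
}

#' Select instruments by joint multiple regression on the exposure
#'
#' Fits one multiple linear regression of the exposure on all candidate
#' variants jointly (centered, intercept-free) and keeps variants whose
#' coefficient is significant at \code{p_threshold} — and positive, when
#' \code{positive_only} (the default) — recording a per-variant decision
#' table.
#'
#' @param G QC-passed [genotype_matrix()].
#' @param exposure length-\code{n} exposure vector.
#' @param p_threshold selection p-value threshold (default \code{5e-8};
#'   \code{1e-4} is a common lenient alternative).
#' @param positive_only keep only positively associated variants.
#' @return List with \code{genotypes} (selected subset, raw),
#'   \code{report} (id, estimate, selection_p, kept).
#' @export
select_instruments <- function(G, exposure, p_threshold = 5e-8,
                               positive_only = TRUE) {
  G <- as_genotype_matrix(G)
  n <- nrow(G$values); m <- ncol(G$values)
  if (n <= m) {
    stop("more candidate variants than samples; pre-screen (e.g. marginally) ",
         "before joint selection")
  }
  Gc <- center_columns(G$values)
  x <- exposure - mean(exposure)
  fit <- stats::lm.fit(Gc, x)
  rss <- sum(fit$residuals^2)
  df <- n - m
  XtXinv <- chol2inv(chol(crossprod(Gc)))
  se <- sqrt(diag(XtXinv) * rss / df)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  keep <- pval < p_threshold & (!positive_only | fit$coefficients > 0)
  report <- data.frame(id = G$variant_ids, estimate = unname(fit$coefficients),
                       selection_p = unname(pval), kept = unname(keep),
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!any(keep)) stop("no variant passes the selection threshold")
  sel <- genotype_matrix(G$values[, keep, drop = FALSE], G$sample_ids,
                         G$variant_ids[keep], centered = FALSE,
                         mask = if (!is.null(G$mask)) G$mask[, keep, drop = FALSE])
  list(genotypes = sel, report = report)
}

#' Run the full preprocessing pipeline
#'
#' Fixed order: missingness filter, Hardy-Weinberg exclusion, covariate
#' residualization of the phenotypes, instrument selection on the adjusted
#' exposure, and finally centering. Produces a QC report accounting for
#' every input variant exactly once per stage.
#'
#' @param G a [genotype_matrix()] (mask allowed).
#' @param exposure,outcome phenotype vectors aligned with \code{G}.
#' @param covariates optional covariate matrix/data.frame for
#'   residualization.
#' @param transform_exposure,transform_outcome \code{"none"} or
#'   \code{"log"}.
#' @param max_missing missingness threshold (default 0.20).
#' @param hwe_threshold exclude variants with HWE p below this (default
#'   \code{1e-6}).
#' @param p_threshold,positive_only instrument-selection controls, see
#'   [select_instruments()].
#' @return List with centered \code{genotypes}, adjusted \code{exposure}
#'   and \code{outcome}, and \code{qc} (an object of class
#'   \code{"qc_report"}).
#' @export
mr_preprocess <- function(G, exposure, outcome, covariates = NULL,
                          transform_exposure = "none",
                          transform_outcome = "none",
                          max_missing = 0.20, hwe_threshold = 1e-6,
                          p_threshold = 5e-8, positive_only = TRUE) {
  G <- as_genotype_matrix(G)
  n_in <- ncol(G$values)
  fm <- filter_missingness(G, max_missing)
  n_miss <- sum(!fm$report$kept)

  hwe_p <- apply(fm$genotypes$values, 2L, function(col) {
    d <- round(col)  # imputed entries are fractional; nearest dosage class
    hwe_test(d)
  })
  hwe_keep <- hwe_p >= hwe_threshold
  if (!any(hwe_keep)) stop("all variants fail the Hardy-Weinberg filter")
  n_hwe <- sum(!hwe_keep)
  Gh <- genotype_matrix(fm$genotypes$values[, hwe_keep, drop = FALSE],
                        fm$genotypes$sample_ids,
                        fm$genotypes$variant_ids[hwe_keep], centered = FALSE,
                        mask = fm$genotypes$mask[, hwe_keep, drop = FALSE])

  if (!is.null(covariates)) {
    exposure <- residualize(exposure, covariates, transform_exposure)
    outcome <- residualize(outcome, covariates, transform_outcome)
  } else {
    if (transform_exposure == "log") exposure <- log(exposure)
    if (transform_outcome == "log") outcome <- log(outcome)
  }

  sel <- select_instruments(Gh, exposure, p_threshold, positive_only)

  decisions <- data.frame(id = G$variant_ids,
                          missing_rate = fm$report$missing_rate,
                          hwe_p = NA_real_, selection_p = NA_real_,
                          kept = FALSE, stringsAsFactors = FALSE)
  decisions$hwe_p[match(fm$genotypes$variant_ids, decisions$id)] <- hwe_p
  decisions$selection_p[match(sel$report$id, decisions$id)] <- sel$report$selection_p
  decisions$kept[match(sel$report$id[sel$report$kept], decisions$id)] <- TRUE

  qc <- structure(list(n_variants_in = n_in, n_dropped_missingness = n_miss,
                       n_dropped_hwe = n_hwe,
                       n_dropped_selection = sum(!sel$report$kept),
                       n_kept = sum(sel$report$kept),
                       n_imputed_entries = attr(fm$genotypes, "imputed"),
                       variant_decisions = decisions),
                  class = "qc_report")
  # imputed dosages can be fractional: bypass the raw 0/1/2 check by
  # centering the values directly
  Gsel <- sel$genotypes
  vals <- center_columns(Gsel$values)
  if (any(sqrt(colSums(vals^2)) == 0)) stop("selected variant became monomorphic")
  Gc <- genotype_matrix(vals, Gsel$sample_ids, Gsel$variant_ids, centered = TRUE)
  list(genotypes = Gc, exposure = exposure - mean(exposure),
       outcome = outcome - mean(outcome), qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat(sprintf("  variants in:            %d\n", x$n_variants_in))
  cat(sprintf("  dropped (missingness):  %d\n", x$n_dropped_missingness))
  cat(sprintf("  dropped (HWE):          %d\n", x$n_dropped_hwe))
  cat(sprintf("  dropped (selection):    %d\n", x$n_dropped_selection))
  cat(sprintf("  kept:                   %d\n", x$n_kept))
  cat(sprintf("  imputed entries:        %d\n", x$n_imputed_entries))
  invisible(x)
}
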