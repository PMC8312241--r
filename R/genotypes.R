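#' Construct a genotype matrix
#'
#' Wraps an \code{n x m} matrix of additive genotype dosages (0/1/2 copies of
#' the effect allele, or real values after column centering) together with
#' sample and variant labels. Missing entries are allowed only when a
#' missingness mask is attached by [read_genotypes()]; all modelling
#' functions require a complete matrix.
#'
#' @param values numeric \code{n x m} matrix of dosages.
#' @param sample_ids character vector of length \code{n}; defaults to
#'   rownames or \code{"S1".."Sn"}.
#' @param variant_ids character vector of length \code{m}; defaults to
#'   colnames or \code{"V1".."Vm"}.
#' @param centered logical; \code{TRUE} when every column has been centered
#'   to mean zero.
#' @param mask optional logical \code{n x m} matrix marking entries that were
#'   missing in the source file (after imputation bookkeeping).
#' @return An object of class \code{"genotype_matrix"}: a list with elements
#'   \code{values}, \code{sample_ids}, \code{variant_ids}, \code{centered}
#'   and optionally \code{mask}.
#' @examples
#' G <- genotype_matrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3))
#' center_genotypes(G)
#' @export
genotype_matrix <- function(values, sample_ids = NULL, variant_ids = NULL,
                            centered = FALSE, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (n < 1L || m < 1L) stop("genotype matrix must have at least one row and one column")
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(values))) rownames(values) else paste0("S", seq_len(n))
  }
  if (is.null(variant_ids)) {
    variant_ids <- if (!is.null(colnames(values))) colnames(values) else paste0("V", seq_len(m))
  }
  if (length(sample_ids) != n) stop("length of 'sample_ids' must equal nrow(values)")
  if (length(variant_ids) != m) stop("length of 'variant_ids' must equal ncol(values)")
  if (is.null(mask) && anyNA(values)) {
    stop("genotype matrix contains missing values; read with read_genotypes() and run filter_missingness() first")
  }
  if (!centered && is.null(mask)) {
    ok <- values %in% c(0, 1, 2)
    if (!all(ok)) stop("raw genotype dosages must be 0, 1 or 2")
  }
  dimnames(values) <- list(sample_ids, variant_ids)
  out <- list(values = values, sample_ids = as.character(sample_ids),
              variant_ids = as.character(variant_ids), centered = isTRUE(centered))
  if (!is.null(mask)) out$mask <- mask
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$centered) "centered" else "raw dosages"))
  if (!is.null(x$mask)) {
    cat(sprintf("  missingness mask present: %d masked entries\n", sum(x$mask)))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

as_genotype_matrix <- function(G, centered = FALSE) {
  if (inherits(G, "genotype_matrix")) G else genotype_matrix(G, centered = centered)
}

#' Center the columns of a matrix
#'
#' Subtracts the column mean from every column. Centering absorbs the
#' intercept of the structural models, so all downstream regressions are fit
#' without one.
#'
#' @param matrix a numeric matrix with at least one row.
#' @return A matrix of the same dimensions whose columns each sum to zero.
#' @examples
#' center_columns(cbind(c(0, 1, 2)))
#' @export
center_columns <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1L) stop("'matrix' must have at least one row")
  sweep(matrix, 2L, colMeans(matrix), "-")
}

#' Center a genotype matrix and check it is usable as instruments
#'
#' Centers every dosage column and rejects monomorphic (zero-variance)
#' variants, which carry no instrument information and would make the Gram
#' matrix singular.
#'
#' @param G a [genotype_matrix()] or plain dosage matrix.
#' @return A centered \code{genotype_matrix}.
#' @export
center_genotypes <- function(G) {
  G <- as_genotype_matrix(G)
  if (G$centered) return(G)
  v <- center_columns(G$values)
  sds <- sqrt(colSums(v^2))
  if (any(sds == 0)) {
    stop("monomorphic variant(s) with zero variance: ",
         paste(G$variant_ids[sds == 0], collapse = ", "))
  }
  genotype_matrix(v, G$sample_ids, G$variant_ids, centered = TRUE)
}

#' Pair centered exposure and outcome vectors
#'
#' @param exposure numeric length-\code{n} exposure vector (X).
#' @param outcome numeric length-\code{n} outcome vector (Y).
#' @param center logical; center both vectors (default \code{TRUE}).
#' @return An object of class \code{"phenotype_pair"} with centered
#'   \code{exposure} and \code{outcome}.
#' @export
phenotype_pair <- function(exposure, outcome, center = TRUE) {
  exposure <- as.numeric(exposure)
  outcome <- as.numeric(outcome)
  if (length(exposure) != length(outcome)) {
    stop("exposure and outcome must have the same length")
  }
  if (anyNA(exposure) || anyNA(outcome)) stop("phenotypes contain missing values")
  if (center) {
    exposure <- exposure - mean(exposure)
    outcome <- outcome - mean(outcome)
  }
  structure(list(exposure = exposure, outcome = outcome),
            class = "phenotype_pair")
}

check_pair <- function(G, P) {
  if (!inherits(P, "phenotype_pair")) P <- phenotype_pair(P$exposure, P$outcome)
  if (length(P$exposure) != nrow(G$values)) {
    stop("phenotype length does not match number of genotyped samples")
  }
  P
}
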