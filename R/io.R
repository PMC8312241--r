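# Plain-text genotype and phenotype I/O. Supported genotype formats:
#   tsv       — header row of variant ids, one sample per line, optional
#               leading IID column
#   plink_raw — PLINK .raw dialect: FID IID PAT MAT SEX PHENOTYPE then one
#               additive dosage column per variant, NA for missing

# all floating point at 17 significant digits for round-trip fidelity
write_tsv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

plink_meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Read an additive genotype matrix
#'
#' Reads either a plain TSV dosage table or a PLINK \code{.raw}-dialect
#' file. Entries must be 0, 1, 2 or NA; anything else is a parse error
#' reported with its line number. Missing entries are kept as \code{NA}
#' with a missingness mask attached; run [filter_missingness()] before any
#' model fitting.
#'
#' @param path input file.
#' @param format \code{"auto"} (by header inspection), \code{"tsv"} or
#'   \code{"plink_raw"}.
#' @return A [genotype_matrix()] with a \code{mask} marking missing
#'   entries.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  if (format == "auto") {
    format <- if (length(header) >= 6 && all(header[1:6] == plink_meta_cols)) {
      "plink_raw"
    } else "tsv"
  }
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA")
  if (format == "plink_raw") {
    if (ncol(tab) < 7 || !all(names(tab)[1:6] == plink_meta_cols)) {
      stop("malformed PLINK .raw header in ", path,
           ": expected columns FID IID PAT MAT SEX PHENOTYPE then variants")
    }
    ids <- as.character(tab$IID)
    vals <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    first <- names(tab)[1]
    if (toupper(first) %in% c("IID", "ID", "SAMPLE")) {
      ids <- as.character(tab[[1]])
      vals <- as.matrix(tab[, -1, drop = FALSE])
    } else {
      ids <- paste0("S", seq_len(nrow(tab)))
      vals <- as.matrix(tab)
    }
  }
  storage.mode(vals) <- "double"
  bad <- which(!(is.na(vals) | vals %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid genotype value %s at line %d of %s (must be 0/1/2/NA)",
                 format(vals[bad[1, 1], bad[1, 2]]), bad[1, 1] + 1L, path))
  }
  mask <- is.na(vals)
  genotype_matrix(vals, sample_ids = ids, variant_ids = colnames(vals),
                  centered = FALSE, mask = mask)
}

#' Write an additive genotype matrix
#'
#' @param G a raw [genotype_matrix()].
#' @param path output file.
#' @param format \code{"plink_raw"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("plink_raw", "tsv")) {
  format <- match.arg(format)
  G <- as_genotype_matrix(G)
  if (G$centered) stop("only raw dosage matrices can be written")
  vals <- G$values
  if (format == "plink_raw") {
    df <- data.frame(FID = G$sample_ids, IID = G$sample_ids, PAT = 0L,
                     MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  } else {
    df <- cbind(data.frame(IID = G$sample_ids, stringsAsFactors = FALSE),
                as.data.frame(vals, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' A TSV with a header; must contain a sample-id column (\code{IID},
#' \code{ID} or \code{SAMPLE}, case-insensitive) plus named numeric
#' phenotype and covariate columns.
#'
#' @param path input file.
#' @return A \code{data.frame} with the id column renamed to \code{IID}.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  idcol <- which(toupper(names(tab)) %in% c("IID", "ID", "SAMPLE"))[1]
  if (is.na(idcol)) stop("phenotype table needs an IID/ID/SAMPLE column")
  names(tab)[idcol] <- "IID"
  tab$IID <- as.character(tab$IID)
  if (anyDuplicated(tab$IID)) stop("duplicate sample ids in phenotype table")
  tab
}

# 1:1 join of a genotype matrix with a phenotype table on sample id;
# mismatches are fatal. Returns the table reordered to the genotype order.
join_phenotypes <- function(G, pheno) {
  idx <- match(G$sample_ids, pheno$IID)
  if (anyNA(idx)) {
    stop("samples missing from phenotype table: ",
         paste(utils::head(G$sample_ids[is.na(idx)], 5), collapse = ", "))
  }
  pheno[idx, , drop = FALSE]
}
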