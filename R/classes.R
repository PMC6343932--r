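#' Expression matrix container
#'
#' A features x samples real matrix with scale metadata. `scale` records
#' whether the values are raw abundances, TPM, or log2-transformed values,
#' and `offset` records the offset used at log transform (0 otherwise).
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param scale One of `"raw"`, `"tpm"`, `"log2"`.
#' @param offset Non-negative offset used at the log2 transform; must be 0
#'   unless `scale == "log2"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale = c("raw", "tpm", "log2"),
                              offset = 0) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames",
         call. = FALSE)
  if (nrow(values) == 0L)
    stop("no features", call. = FALSE)
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate feature ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite expression values", call. = FALSE)
  if (scale != "log2" && any(values < 0))
    stop("negative values not allowed on scale '", scale, "'",
         call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0)
    stop("`offset` must be a single non-negative number", call. = FALSE)
  if (scale != "log2" && offset != 0)
    stop("`offset` must be 0 unless scale is 'log2'", call. = FALSE)
  structure(
    list(values = values, scale = scale, offset = offset),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [scale=%s%s]\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$scale == "log2") sprintf(", offset=%g", x$offset) else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature and sample identifiers
#' @param x An `ExpressionMatrix` or `GenotypeMatrix`.
#' @return Character vector of identifiers.
#' @export
feature_ids <- function(x) UseMethod("feature_ids")

#' @export
feature_ids.ExpressionMatrix <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.ExpressionMatrix <- function(x) colnames(x$values)

#' @export
sample_ids.GenotypeMatrix <- function(x) colnames(x$dosage)

#' @export
sample_ids.PcaCovariates <- function(x) x$sample_ids

#' Subset an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @param features,samples Identifiers or indices to retain (`NULL` = all).
#' @return An `ExpressionMatrix`.
#' @export
subset_expression <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, scale = x$scale, offset = x$offset)
}

#' Genotype matrix container
#'
#' SNPs x samples minor-allele dosage calls ({0,1,2} or `NA`) with allele
#' labels and genomic coordinates. On construction, any SNP whose stated
#' minor allele in fact has cohort frequency > 0.5 is re-polarized: dosages
#' are flipped (d -> 2 - d) and the allele labels swapped, so that dosage
#' always counts the cohort-minor allele.
#'
#' @param dosage Integer matrix (SNPs x samples) with entries in
#'   `{0, 1, 2, NA}`; rownames = SNP ids, colnames = sample ids.
#' @param info `data.frame` with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `major_allele`, `minor_allele`.
#' @return An object of class `GenotypeMatrix`. The number of re-polarized
#'   SNPs is recorded in attribute `n_repolarized`.
#' @export
genotype_matrix <- function(dosage, info) {
  if (!is.matrix(dosage))
    stop("`dosage` must be a matrix", call. = FALSE)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("`dosage` must have SNP rownames and sample colnames",
         call. = FALSE)
  if (ncol(dosage) == 0L) stop("no samples", call. = FALSE)
  dup <- unique(rownames(dosage)[duplicated(rownames(dosage))])
  if (length(dup))
    stop("duplicate SNP ids: ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(dosage)))
    stop("duplicate sample ids", call. = FALSE)
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(dosage))
    stop(sprintf("invalid dosage value '%s' at SNP %s, sample %s",
                 dosage[idx], rownames(dosage)[rc[1L]],
                 colnames(dosage)[rc[2L]]), call. = FALSE)
  }
  storage.mode(dosage) <- "integer"
  req <- c("snp_id", "chrom", "pos", "major_allele", "minor_allele")
  if (!is.data.frame(info) || !all(req %in% names(info)))
    stop("`info` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!identical(as.character(info$snp_id), rownames(dosage)))
    stop("`info$snp_id` must match dosage rownames in order", call. = FALSE)
  if (any(is.na(info$chrom)) || any(is.na(info$pos)))
    stop("coordinates required for every SNP", call. = FALSE)

  # re-polarize so dosage counts the cohort-minor allele
  n_nonmiss <- rowSums(!is.na(dosage))
  af <- rowSums(dosage, na.rm = TRUE) / (2 * pmax(n_nonmiss, 1L))
  flip <- n_nonmiss > 0L & af > 0.5
  if (any(flip)) {
    dosage[flip, ] <- 2L - dosage[flip, , drop = FALSE]
    tmp <- info$major_allele[flip]
    info$major_allele[flip] <- info$minor_allele[flip]
    info$minor_allele[flip] <- tmp
  }
  rownames(info) <- NULL
  structure(
    list(dosage = dosage, info = info),
    n_repolarized = sum(flip),
    class = "GenotypeMatrix"
  )
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d samples (%d re-polarized on load)\n",
              nrow(x$dosage), ncol(x$dosage),
              attr(x, "n_repolarized") %||% 0L))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

#' @export
feature_ids.GenotypeMatrix <- function(x) rownames(x$dosage)

#' Subset a GenotypeMatrix
#' @param x A `GenotypeMatrix`.
#' @param snps,samples Identifiers or indices to retain (`NULL` = all).
#' @return A `GenotypeMatrix` (not re-polarized: subsetting preserves the
#'   cohort polarization of the full matrix).
#' @export
subset_genotypes <- function(x, snps = NULL, samples = NULL) {
  d <- x$dosage
  info <- x$info
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, rownames(d))
    d <- d[snps, , drop = FALSE]
    info <- info[snps, , drop = FALSE]
  }
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  rownames(info) <- NULL
  structure(list(dosage = d, info = info),
            n_repolarized = 0L, class = "GenotypeMatrix")
}

#' Genotype PCA covariates
#'
#' Per-sample scores of the leading genotype principal components; the
#' first two are the PC1/PC2 population-structure covariates entering the
#' interaction model.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param scores Numeric matrix, samples x components.
#' @param variance_explained Fractions of total variance per component,
#'   non-increasing, each in \[0, 1\].
#' @return An object of class `PcaCovariates` with elements `sample_ids`,
#'   `scores`, `pc1`, `pc2`, `variance_explained`.
#' @export
pca_covariates <- function(sample_ids, scores, variance_explained) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(sample_ids))
    stop("scores rows must match sample_ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  ve <- as.numeric(variance_explained)
  if (any(ve < -1e-12 | ve > 1 + 1e-12))
    stop("variance_explained entries must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(rev(ve + 1e-12)))
    stop("variance_explained must be non-increasing", call. = FALSE)
  colnames(scores) <- paste0("pc", seq_len(ncol(scores)))
  rownames(scores) <- sample_ids
  structure(
    list(sample_ids = as.character(sample_ids),
         scores = scores,
         pc1 = scores[, 1L],
         pc2 = if (ncol(scores) >= 2L) scores[, 2L] else
           stats::setNames(rep(0, nrow(scores)), sample_ids),
         variance_explained = ve),
    class = "PcaCovariates"
  )
}

#' @export
print.PcaCovariates <- function(x, ...) {
  cat(sprintf("PcaCovariates: %d samples, %d components (VE: %s)\n",
              length(x$sample_ids), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.PcaCovariates <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, x$scores, row.names = NULL,
             check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
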