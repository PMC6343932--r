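# Expression transforms and feature/variant filters applied before trio
# enumeration.

#' TPM transform
#'
#' Converts raw abundances to transcripts per million:
#' `TPM_i = 1e6 * (count_i / length_i) / sum_j(count_j / length_j)`
#' per sample, so every column sums to 1e6.
#'
#' @param counts An [expression_matrix()] with `scale = "raw"`.
#' @param lengths_kb Positive feature lengths in kilobases, named by
#'   feature id or in matrix row order.
#' @return An `ExpressionMatrix` with `scale = "tpm"`.
#' @export
tpm_transform <- function(counts, lengths_kb) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$scale != "raw")
    stop("TPM conversion expects a raw-scale matrix", call. = FALSE)
  if (!is.null(names(lengths_kb))) {
    miss <- setdiff(feature_ids(counts), names(lengths_kb))
    if (length(miss))
      stop("lengths missing for feature(s): ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    lengths_kb <- lengths_kb[feature_ids(counts)]
  }
  if (length(lengths_kb) != nrow(counts$values))
    stop("one length per feature required", call. = FALSE)
  if (any(!is.finite(lengths_kb)) || any(lengths_kb <= 0))
    stop("feature lengths must be positive", call. = FALSE)
  rate <- counts$values / lengths_kb
  denom <- colSums(rate)
  if (any(denom == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts$values)[denom == 0], collapse = ", "),
         call. = FALSE)
  tpm <- sweep(rate, 2L, denom, "/") * 1e6
  expression_matrix(tpm, scale = "tpm")
}

#' log2 transform with offset
#'
#' Maps every value v to `log2(v + offset)`; the offset is recorded on the
#' result so downstream code can recover the raw scale (`2^v - offset`)
#' and identify raw zeros.
#'
#' @param matrix An `ExpressionMatrix` with scale `"raw"` or `"tpm"`.
#' @param offset Positive offset added before the log.
#' @return An `ExpressionMatrix` with `scale = "log2"`.
#' @export
log2_transform <- function(matrix, offset = 1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale == "log2")
    stop("matrix is already log2-transformed", call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("`offset` must be a single positive number", call. = FALSE)
  expression_matrix(log2(matrix$values + offset), scale = "log2",
                    offset = offset)
}

#' Remove genes with low median raw expression
#'
#' Retains features whose per-feature median across samples is `>=`
#' `threshold` (removal rule is strict-less); applied on the raw abundance
#' scale before TPM conversion.
#'
#' @param matrix An `ExpressionMatrix` with `scale = "raw"`.
#' @param threshold Median threshold; default `1e-9`.
#' @return Filtered `ExpressionMatrix`, row order preserved.
#' @export
filter_genes_by_median <- function(matrix, threshold = 1e-9) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "raw")
    stop("gene median filter is defined on the raw scale", call. = FALSE)
  med <- apply(matrix$values, 1L, stats::median)
  keep <- med >= threshold
  out <- matrix
  out$values <- matrix$values[keep, , drop = FALSE]
  out
}

#' Remove miRNAs with poor detection
#'
#' Removes a miRNA when its raw expression is `<= level` in more than
#' `fraction` of samples (strictly more; a miRNA at exactly half is
#' retained).
#'
#' @param matrix An `ExpressionMatrix` with `scale = "raw"`.
#' @param level Detection level; default 1 (reads-per-million scale).
#' @param fraction Sample fraction; default 0.5.
#' @return Filtered `ExpressionMatrix`, row order preserved.
#' @export
filter_mirnas_by_detection <- function(matrix, level = 1, fraction = 0.5) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "raw")
    stop("miRNA detection filter is defined on the raw scale",
         call. = FALSE)
  n <- ncol(matrix$values)
  n_low <- rowSums(matrix$values <= level)
  keep <- n_low <= fraction * n
  out <- matrix
  out$values <- matrix$values[keep, , drop = FALSE]
  out
}

#' Minor allele frequency of a dosage vector
#'
#' `sum(dosage) / (2 * n_non_missing)`. The input is assumed polarized
#' (dosage counts the minor allele), so a result above 0.5 is an error.
#'
#' @param dosages Vector over samples of `{0, 1, 2, NA}`.
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all genotype calls missing", call. = FALSE)
  maf <- sum(dosages[ok]) / (2 * sum(ok))
  if (maf > 0.5)
    stop("minor-allele frequency > 0.5: matrix polarization violated",
         call. = FALSE)
  maf
}

#' Relative genotype-class frequencies
#'
#' Frequencies of the three genotype classes over non-missing calls;
#' absent classes are reported with frequency 0.
#'
#' @param dosages Vector over samples of `{0, 1, 2, NA}`.
#' @return Named numeric vector `c("0" = ., "1" = ., "2" = .)`.
#' @export
genotype_class_frequencies <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all genotype calls missing", call. = FALSE)
  d <- dosages[ok]
  stats::setNames(
    c(mean(d == 0), mean(d == 1), mean(d == 2)),
    c("0", "1", "2")
  )
}

#' SNP filters: MAF and genotype-class frequency
#'
#' Retains SNPs that satisfy all of: MAF `>= maf_min`; at least two
#' observed genotype classes; every *observed* class has relative
#' frequency `>= class_freq_min` (unobserved classes do not count against
#' a SNP, otherwise every two-class SNP would be removed).
#'
#' @param genotypes A polarized [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency; default 0.01.
#' @param class_freq_min Minimum observed genotype-class frequency;
#'   default 0.05.
#' @return Filtered `GenotypeMatrix`, SNP order preserved.
#' @export
filter_snps <- function(genotypes, maf_min = 0.01, class_freq_min = 0.05) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  d <- genotypes$dosage
  keep <- vapply(seq_len(nrow(d)), function(i) {
    v <- d[i, ]
    if (!any(!is.na(v))) return(FALSE)
    maf <- compute_maf(v)
    if (maf < maf_min) return(FALSE)
    cf <- genotype_class_frequencies(v)
    observed <- cf[cf > 0]
    length(observed) >= 2L && all(observed >= class_freq_min)
  }, logical(1L))
  subset_genotypes(genotypes, snps = which(keep))
}
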