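# Genotype PCA for population-structure covariates (PC1, PC2 of the
# interaction model).

#' Normalize genotypes for PCA
#'
#' EIGENSTRAT-style normalization: missing calls are mean-imputed per SNP,
#' then each SNP column is centered by `2*p_hat` and (optionally) scaled
#' by `sqrt(2*p_hat*(1-p_hat))`, where `p_hat` is its minor allele
#' frequency estimated from the non-missing calls. Monomorphic
#' (zero-variance) SNPs are dropped. Mean imputation is used for PCA
#' only — trio fits never impute.
#'
#' @param genotypes A filtered, polarized [genotype_matrix()].
#' @param method `"eigenstrat"` (default) or `"center"` (no variance
#'   scaling).
#' @return Real matrix, samples x SNPs, each column mean zero.
#' @export
normalize_genotypes <- function(genotypes,
                                method = c("eigenstrat", "center")) {
  method <- match.arg(method)
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  d <- t(genotypes$dosage)            # samples x SNPs
  if (nrow(d) < 2L) stop("need at least 2 samples for PCA", call. = FALSE)
  p_hat <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  if (!any(poly)) stop("no polymorphic SNPs", call. = FALSE)
  d <- d[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  # mean-impute missing calls, then center at 2*p_hat (== column mean)
  for (j in which(colSums(is.na(d)) > 0L)) d[is.na(d[, j]), j] <- 2 * p_hat[j]
  x <- sweep(d, 2L, 2 * p_hat, "-")
  if (method == "eigenstrat")
    x <- sweep(x, 2L, sqrt(2 * p_hat * (1 - p_hat)), "/")
  # drop columns that became constant through imputation
  keep <- matrixStats_colVars(x) > 0
  x[, keep, drop = FALSE]
}

matrixStats_colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1L)
}

#' Genotype principal components
#'
#' Computes sample scores of the leading principal components of the
#' normalized genotype matrix via SVD (equivalently, eigenvectors of the
#' sample-by-sample covariance). Component signs are fixed
#' deterministically (the score of largest magnitude is positive) so
#' results are reproducible and invariant to sample order up to the
#' corresponding permutation.
#'
#' @param normalized Samples x SNPs matrix from [normalize_genotypes()].
#' @param n_components Number of components to retain; default 6.
#' @return A [pca_covariates()] object; `variance_explained` holds the
#'   fraction of total variance per retained component.
#' @export
genotype_pca <- function(normalized, n_components = 6L) {
  if (nrow(normalized) < 2L)
    stop("need at least 2 samples for PCA", call. = FALSE)
  k <- min(n_components, nrow(normalized) - 1L, ncol(normalized))
  sv <- svd(normalized, nu = k, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  # deterministic sign: largest-|score| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  ve <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  pca_covariates(rownames(normalized), scores, ve)
}

#' Genotype PCA covariates in one step
#'
#' Convenience wrapper: [normalize_genotypes()] then [genotype_pca()].
#'
#' @inheritParams normalize_genotypes
#' @inheritParams genotype_pca
#' @return A [pca_covariates()] object.
#' @export
compute_pca_covariates <- function(genotypes, n_components = 6L,
                                   method = c("eigenstrat", "center")) {
  genotype_pca(normalize_genotypes(genotypes, method = method),
               n_components = n_components)
}
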