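# Readers/writers for the standard input formats and the results table.
# No statistics here.

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = 1L),
                      data.table = FALSE, showProgress = FALSE),
    error = function(e) stop("malformed TSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L) stop("no features in ", path, call. = FALSE)
  if (ncol(dt) < 2L) stop("no sample columns in ", path, call. = FALSE)
  ids <- dt[[1L]]
  for (j in seq(2L, ncol(dt))) {
    if (!is.numeric(dt[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[j]]))) &
                     !is.na(dt[[j]]))[1L]
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                   path, ids[bad %||% 1L], names(dt)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read an expression matrix from TSV
#'
#' The file must have a header row of sample ids and feature ids in the
#' first column. Values are taken as raw abundances (`scale = "raw"`).
#'
#' @param path Path to a TSV file.
#' @param format File format; only `"tsv"` is supported.
#' @return An [expression_matrix()] with `scale = "raw"`.
#' @export
read_expression <- function(path, format = c("tsv")) {
  format <- match.arg(format)
  m <- read_tsv_matrix(path)
  expression_matrix(m, scale = "raw")
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF input (v4.x, `GT` field) is parsed with `VariantAnnotation`;
#' multi-allelic records are skipped with a logged count, and dosages count
#' ALT alleles before re-polarization. Dosage TSV input has columns
#' `snp_id`, `chrom`, `pos`, `major_allele`, `minor_allele` followed by one
#' column per sample with entries in `{0, 1, 2, NA}`.
#'
#' In the returned matrix, dosage counts the cohort-minor allele: SNPs
#' whose stated ALT (or minor) allele is in fact the cohort-major allele
#' are re-polarized (dosage d -> 2 - d, allele labels swapped).
#'
#' @param path Path to the genotype file.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) "vcf" else "dosage_tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) == 0L) stop("no samples in VCF ", path, call. = FALSE)
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  multi <- nalt != 1L
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) skipped in ", path)
    vcf <- vcf[!multi]
  }
  if (nrow(vcf) == 0L) stop("no biallelic records in VCF ", path,
                            call. = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path, call. = FALSE)
  dose <- function(g) {
    if (g %in% c(".", "./.", ".|.")) return(NA_integer_)
    parts <- strsplit(g, "[/|]")[[1L]]
    al <- suppressWarnings(as.integer(parts))
    if (anyNA(al) || any(al > 1L)) return(-1L)  # unparseable / out of range
    sum(al)
  }
  d <- matrix(vapply(gt, dose, integer(1L)), nrow = nrow(gt),
              dimnames = dimnames(gt))
  if (any(d == -1L, na.rm = TRUE)) {
    idx <- which(d == -1L, arr.ind = TRUE)[1L, ]
    rr0 <- SummarizedExperiment::rowRanges(vcf)
    stop(sprintf("unparseable GT '%s' at %s:%d",
                 gt[idx[1L], idx[2L]],
                 as.character(GenomeInfoDb::seqnames(rr0))[idx[1L]],
                 BiocGenerics::start(rr0)[idx[1L]]), call. = FALSE)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- data.frame(
    snp_id = rownames(gt),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    major_allele = as.character(VariantAnnotation::ref(vcf)),
    minor_allele = as.character(unlist(VariantAnnotation::alt(vcf))),
    stringsAsFactors = FALSE
  )
  genotype_matrix(d, info)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  meta <- c("snp_id", "chrom", "pos", "major_allele", "minor_allele")
  if (!all(meta %in% names(dt)))
    stop("dosage TSV must have columns ", paste(meta, collapse = ", "),
         call. = FALSE)
  samp <- setdiff(names(dt), meta)
  if (length(samp) == 0L) stop("no samples in ", path, call. = FALSE)
  d <- as.matrix(dt[, samp, drop = FALSE])
  rownames(d) <- dt$snp_id
  info <- dt[, meta]
  genotype_matrix(d, info)  # validates the {0,1,2,NA} domain
}

#' Read gene sets from a GMT file
#'
#' One pathway per line: name, description, then gene identifiers.
#' Duplicate genes within a line are deduplicated.
#'
#' @param path Path to a GMT file.
#' @return Named list mapping pathway id to a character vector of unique
#'   gene ids, with pathway descriptions in attribute `descriptions`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate pathway id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0L))
    stop("empty pathway in GMT", call. = FALSE)
  names(sets) <- ids
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  sets
}

#' Read the candidate miRNA-pathway pair table
#'
#' TSV with columns `mirna_id`, `pathway_id`, `p` — the differential
#' association p-value from the upstream miRNA-pathway dysregulation
#' analysis (consumed here as a precomputed input).
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `mirna_id`, `pathway_id`, `p`.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  req <- c("mirna_id", "pathway_id", "p")
  if (!all(req %in% names(dt)))
    stop("pair table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  p <- suppressWarnings(as.numeric(dt$p))
  if (any(is.na(p)))
    stop("non-numeric p in pair table row ", which(is.na(p))[1L],
         call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("p outside [0,1] in pair table row ", which(p < 0 | p > 1)[1L],
         call. = FALSE)
  key <- paste(dt$mirna_id, dt$pathway_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (mirna_id, pathway_id) pair in row ",
         which(duplicated(key))[1L], call. = FALSE)
  data.frame(mirna_id = as.character(dt$mirna_id),
             pathway_id = as.character(dt$pathway_id),
             p = p, stringsAsFactors = FALSE)
}

#' Read the SNP-to-gene assignment
#'
#' Either a headered 2-column TSV (`snp_id`, `gene_id`) or a BED file
#' (chrom, 0-based start, end, gene id); BED input requires `genotypes`
#' so that SNP ids are resolved by coordinate overlap. Multi-gene
#' assignment of one SNP is permitted.
#'
#' @param path Path to the map file.
#' @param genotypes Optional [genotype_matrix()], required for BED input.
#' @return `data.frame` with columns `snp_id`, `gene_id` (unique rows).
#' @export
read_snp_gene_map <- function(path, genotypes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1L]]
  is_bed <- length(first) >= 4L &&
    !any(is.na(suppressWarnings(as.numeric(first[2:3]))))
  if (is_bed) {
    if (is.null(genotypes))
      stop("BED SNP-gene map requires `genotypes` to resolve SNP ids",
           call. = FALSE)
    bed <- data.table::fread(path, sep = "\t", header = FALSE,
                             data.table = FALSE, showProgress = FALSE)
    info <- genotypes$info
    out <- vector("list", 0L)
    for (chr in unique(bed[[1L]])) {
      bi <- bed[bed[[1L]] == chr, , drop = FALSE]
      gi <- info[info$chrom == chr, , drop = FALSE]
      if (nrow(gi) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = gi$pos, width = 1L),
        IRanges::IRanges(start = bi[[2L]] + 1L, end = bi[[3L]]))
      if (length(hits))
        out[[length(out) + 1L]] <- data.frame(
          snp_id = gi$snp_id[S4Vectors::queryHits(hits)],
          gene_id = bi[[4L]][S4Vectors::subjectHits(hits)],
          stringsAsFactors = FALSE)
    }
    map <- if (length(out)) do.call(rbind, out) else
      data.frame(snp_id = character(), gene_id = character())
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE, showProgress = FALSE)
    if (!all(c("snp_id", "gene_id") %in% names(dt)))
      stop("SNP-gene map must have columns snp_id, gene_id", call. = FALSE)
    map <- data.frame(snp_id = as.character(dt$snp_id),
                      gene_id = as.character(dt$gene_id),
                      stringsAsFactors = FALSE)
  }
  unique(map)
}

# fixed schema of the results TSV (order matters; see write_results)
RESULT_COLUMNS <- c(
  "mirna_id", "gene_id", "snp_id", "chrom", "pos",
  "n_total", "n_used", "n_removed_low_mirna", "n_removed_cooks",
  "reference_genotype",
  "beta_mirna", "beta_het", "beta_hom_minor",
  "beta_inter_het", "beta_inter_hom_minor",
  "slope_ref", "slope_het", "slope_hom_minor",
  "f_stat", "df_num", "df_den", "p_interaction", "q_value", "status"
)

RESULT_INTEGER <- c(
  "pos", "n_total", "n_used", "n_removed_low_mirna", "n_removed_cooks",
  "df_num", "df_den"
)

RESULT_NUMERIC <- c(
  "pos", "n_total", "n_used", "n_removed_low_mirna", "n_removed_cooks",
  "beta_mirna", "beta_het", "beta_hom_minor",
  "beta_inter_het", "beta_inter_hom_minor",
  "slope_ref", "slope_het", "slope_hom_minor",
  "f_stat", "df_num", "df_den", "p_interaction", "q_value"
)

#' Write a screen result table to TSV
#'
#' Columns are written in the fixed schema order; floats are serialized
#' with 17 significant digits so that [read_results()] reproduces every
#' numeric value bit-for-bit.
#'
#' @param table Result `data.frame` from [run_screen()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(table, path) {
  missing_cols <- setdiff(RESULT_COLUMNS, names(table))
  if (length(missing_cols))
    stop("result table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- table[, RESULT_COLUMNS, drop = FALSE]
  for (cn in RESULT_NUMERIC) {
    v <- out[[cn]]
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- "NA"
    out[[cn]] <- s
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a screen result table written by [write_results()]
#' @param path Path to the results TSV.
#' @return Result `data.frame` in the fixed schema.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE,
                          na.strings = "NA",
                          colClasses = list(character =
                             setdiff(RESULT_COLUMNS, RESULT_NUMERIC)))
  if (!identical(names(dt), RESULT_COLUMNS))
    stop("unexpected results schema in ", path, call. = FALSE)
  for (cn in RESULT_NUMERIC) dt[[cn]] <- as.numeric(dt[[cn]])
  for (cn in RESULT_INTEGER) dt[[cn]] <- as.integer(dt[[cn]])
  dt
}

#' Write a PcaCovariates object to TSV
#'
#' Variance-explained fractions are stored in a `#variance_explained`
#' header comment.
#' @param pcs A [pca_covariates()] object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pca <- function(pcs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#variance_explained\t",
                    paste(sprintf("%.17g", pcs$variance_explained),
                          collapse = "\t")), con)
  df <- as.data.frame(pcs)
  for (j in seq(2L, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a PcaCovariates TSV written by [write_pca()]
#' @param path Path to the PCA TSV.
#' @return A [pca_covariates()] object.
#' @export
read_pca <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  ve <- as.numeric(strsplit(first, "\t")[[1L]][-1L])
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = 1L,
                          data.table = FALSE, showProgress = FALSE)
  pca_covariates(dt$sample_id,
                 as.matrix(dt[, -1L, drop = FALSE]),
                 ve)
}
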