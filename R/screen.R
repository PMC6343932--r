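# Trio enumeration, screen orchestration, FDR control, summaries and
# plot-ready exports.

#' Enumerate unique miRNA-gene-SNP trios
#'
#' For each candidate miRNA-pathway pair with differential-association
#' p-value strictly below `p_threshold`, crosses the miRNA with every
#' pathway gene present in `expressed_genes` and every retained SNP
#' mapped to that gene. Trios are deduplicated globally (a gene shared by
#' two selected pathways of the same miRNA contributes its trios once)
#' and returned in deterministic (mirna, gene, snp) lexicographic order.
#'
#' @param pairs `data.frame` from [read_pair_table()].
#' @param sets Named list from [read_gene_sets()].
#' @param snp_map `data.frame` (`snp_id`, `gene_id`) from
#'   [read_snp_gene_map()].
#' @param expressed_genes,expressed_mirnas,kept_snps Identifier vectors
#'   surviving the preprocessing filters.
#' @param p_threshold Pair-selection threshold; default 0.01 (strict
#'   inequality).
#' @return `data.frame` with columns `mirna_id`, `gene_id`, `snp_id`.
#' @export
enumerate_trios <- function(pairs, sets, snp_map, expressed_genes,
                            expressed_mirnas, kept_snps,
                            p_threshold = 0.01) {
  missing_pw <- setdiff(unique(pairs$pathway_id), names(sets))
  if (length(missing_pw))
    stop("pathway id(s) absent from gene sets: ",
         paste(missing_pw, collapse = ", "), call. = FALSE)
  sel <- pairs[pairs$p < p_threshold &
                 pairs$mirna_id %in% expressed_mirnas, , drop = FALSE]
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      snp_id = character(), stringsAsFactors = FALSE)
  if (nrow(sel) == 0L) return(empty)
  map <- snp_map[snp_map$snp_id %in% kept_snps, , drop = FALSE]
  gene_snps <- split(map$snp_id, map$gene_id)
  out <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    genes <- intersect(sets[[sel$pathway_id[i]]], expressed_genes)
    genes <- genes[genes %in% names(gene_snps)]
    if (length(genes) == 0L) next
    per_gene <- gene_snps[genes]
    out[[i]] <- data.frame(
      mirna_id = sel$mirna_id[i],
      gene_id = rep(genes, lengths(per_gene)),
      snp_id = unlist(per_gene, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) return(empty)
  trios <- unique(do.call(rbind, out))
  trios <- trios[order(trios$mirna_id, trios$gene_id, trios$snp_id), ,
                 drop = FALSE]
  rownames(trios) <- NULL
  trios
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) (p_(j) * m / j)`, capped at 1 and mapped back to
#' input order. Valid under the positive-regression dependency expected
#' among trios sharing a miRNA or gene.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0L))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Run the screen over enumerated trios
#'
#' Intersects sample ids across expression, genotype and covariate
#' inputs (optionally restricted to `samples` for subtype/subset runs),
#' applies [fit_trio()] to every trio over the common samples, and
#' BH-adjusts the interaction p-values over all `ok`-status trios.
#' Fully deterministic: no randomness anywhere in the pipeline.
#'
#' @param trios `data.frame` from [enumerate_trios()].
#' @param mrna,mirna log2-scale [expression_matrix()] objects; raw zeros
#'   of the miRNA matrix are recovered from its recorded offset
#'   (`2^v - offset <= mirna_zero_max`).
#' @param genotypes A filtered [genotype_matrix()].
#' @param pcs A [pca_covariates()] object, or `NULL` to omit structure
#'   covariates.
#' @param options [trio_options()].
#' @param samples Optional sample-id restriction.
#' @param verbose Log progress and skip-reason counts; default `FALSE`.
#' @return Result `data.frame` in the fixed schema (see
#'   [write_results()]), one row per trio in enumeration order.
#' @export
run_screen <- function(trios, mrna, mirna, genotypes, pcs,
                       options = trio_options(), samples = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(mrna, "ExpressionMatrix"),
            inherits(mirna, "ExpressionMatrix"))
  if (mrna$scale != "log2" || mirna$scale != "log2")
    stop("screen expects log2-scale expression matrices", call. = FALSE)
  common <- Reduce(intersect, list(sample_ids(mrna), sample_ids(mirna),
                                   sample_ids(genotypes)))
  if (!is.null(pcs)) common <- intersect(common, sample_ids(pcs))
  if (!is.null(samples)) common <- intersect(common, samples)
  if (length(common) == 0L)
    stop("empty sample intersection across inputs", call. = FALSE)

  ym <- mrna$values[, common, drop = FALSE]
  xm <- mirna$values[, common, drop = FALSE]
  # raw zero: 2^v - offset <= mirna_zero_max (within fp tolerance)
  zero_cut <- log2(mirna$offset + options$mirna_zero_max) + 1e-9
  gm <- genotypes$dosage[, common, drop = FALSE]
  pc_df <- if (!is.null(pcs)) {
    sc <- pcs$scores[common, , drop = FALSE]
    data.frame(pc1 = sc[, 1L],
               pc2 = if (ncol(sc) >= 2L) sc[, 2L] else 0)
  } else NULL
  info <- genotypes$info
  info_idx <- stats::setNames(seq_len(nrow(info)), info$snp_id)

  n_trios <- nrow(trios)
  rows <- vector("list", n_trios)
  skip_counts <- c(skipped_degenerate = 0L, skipped_rank_deficient = 0L)
  for (i in seq_len(n_trios)) {
    g <- trios$gene_id[i]; mi <- trios$mirna_id[i]; s <- trios$snp_id[i]
    if (!(g %in% rownames(ym)) || !(mi %in% rownames(xm)) ||
        !(s %in% names(info_idx)))
      stop(sprintf("trio (%s, %s, %s) references unknown feature",
                   mi, g, s), call. = FALSE)
    x <- xm[mi, ]
    fit <- fit_trio(y = ym[g, ], x_mir = x, genotype_class = gm[s, ],
                    pcs = pc_df, raw_zero = x <= zero_cut,
                    options = options)
    ii <- info_idx[[s]]
    if (fit$status != "ok")
      skip_counts[fit$status] <- skip_counts[fit$status] + 1L
    co <- fit$coefficients
    pick <- function(nm) if (!is.null(co) && nm %in% names(co))
      unname(co[nm]) else NA_real_
    rows[[i]] <- data.frame(
      mirna_id = mi, gene_id = g, snp_id = s,
      chrom = info$chrom[ii], pos = info$pos[ii],
      n_total = fit$n_total, n_used = fit$n_used,
      n_removed_low_mirna = fit$n_removed_low_mirna,
      n_removed_cooks = fit$n_removed_cooks,
      reference_genotype = fit$reference_genotype,
      beta_mirna = pick("x_mir"),
      beta_het = pick("g_het"),
      beta_hom_minor = pick("g_hom_minor"),
      beta_inter_het = pick("x_mir:g_het"),
      beta_inter_hom_minor = pick("x_mir:g_hom_minor"),
      slope_ref = fit$genotype_slopes[["ref"]],
      slope_het = fit$genotype_slopes[["het"]],
      slope_hom_minor = fit$genotype_slopes[["hom_minor"]],
      f_stat = fit$f_stat, df_num = fit$df_num, df_den = fit$df_den,
      p_interaction = fit$p_interaction, q_value = NA_real_,
      status = fit$status, stringsAsFactors = FALSE)
    if (verbose && i %% 500L == 0L)
      message("fitted ", i, "/", n_trios, " trios")
  }
  tbl <- if (n_trios) do.call(rbind, rows) else
    utils::read.table(text = paste(RESULT_COLUMNS, collapse = "\t"),
                      header = TRUE, sep = "\t",
                      colClasses = "character")[0, ]
  if (n_trios == 0L) {
    for (cn in RESULT_NUMERIC) tbl[[cn]] <- numeric(0L)
    tbl <- tbl[, RESULT_COLUMNS]
  }
  ok <- which(tbl$status == "ok")
  if (length(ok)) tbl$q_value[ok] <- bh_adjust(tbl$p_interaction[ok])
  if (verbose)
    message(sprintf("screen: %d trios, %d ok, %d degenerate, %d rank-deficient",
                    n_trios, length(ok), skip_counts[[1L]],
                    skip_counts[[2L]]))
  attr(tbl, "n_samples") <- length(common)
  attr(tbl, "skip_counts") <- skip_counts
  rownames(tbl) <- NULL
  tbl
}

#' Significant regQTL trios at an FDR threshold
#'
#' @param table Result table from [run_screen()].
#' @param fdr FDR cutoff; default 0.1. Strict inequality (`q < fdr`).
#' @return Subset of rows with `q_value < fdr`, sorted by q then p.
#' @export
flag_significant <- function(table, fdr = 0.1) {
  sig <- table[!is.na(table$q_value) & table$q_value < fdr, ,
               drop = FALSE]
  sig <- sig[order(sig$q_value, sig$p_interaction), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Per miRNA-gene pair summary of significant regQTLs
#'
#' One row per (miRNA, gene) pair with at least one significant trio:
#' number of significant SNPs, total SNPs tested on the gene for that
#' miRNA, the minimum q and p over the pair's trios, the mean MAF of the
#' significant SNPs (when `genotypes` is supplied), and the chromosome(s)
#' involved. Sorted by significant-SNP count, descending.
#'
#' @param table Result table from [run_screen()].
#' @param fdr FDR cutoff; default 0.1.
#' @param genotypes Optional [genotype_matrix()] used to compute MAFs.
#' @return Summary `data.frame`.
#' @export
summarize_pairs <- function(table, fdr = 0.1, genotypes = NULL) {
  sig <- flag_significant(table, fdr)
  if (nrow(sig) == 0L)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      n_significant = integer(), n_snps = integer(),
                      min_q = numeric(), min_p = numeric(),
                      mean_maf = numeric(), chrom = character(),
                      stringsAsFactors = FALSE))
  maf_of <- function(snp_ids) {
    if (is.null(genotypes)) return(NA_real_)
    mean(vapply(snp_ids, function(s)
      compute_maf(genotypes$dosage[s, ]), numeric(1L)))
  }
  key <- paste(sig$mirna_id, sig$gene_id, sep = "\r")
  groups <- split(seq_len(nrow(sig)), key)
  all_key <- paste(table$mirna_id, table$gene_id, sep = "\r")
  out <- lapply(groups, function(ix) {
    rows <- sig[ix, , drop = FALSE]
    pair_rows <- table[all_key == paste(rows$mirna_id[1L],
                                        rows$gene_id[1L], sep = "\r"), ]
    data.frame(
      mirna_id = rows$mirna_id[1L], gene_id = rows$gene_id[1L],
      n_significant = nrow(rows),
      n_snps = nrow(pair_rows),
      min_q = min(rows$q_value),
      min_p = min(rows$p_interaction),
      mean_maf = maf_of(rows$snp_id),
      chrom = paste(unique(rows$chrom), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$n_significant, out$min_q), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot-ready data: QQ, Manhattan and genotype-stratified trio scatter
#'
#' QQ expected quantiles are `-log10((i - 0.5) / m)` over the sorted
#' `ok`-status p-values; Manhattan rows carry chrom/pos and `-log10(q)`;
#' trio data (when the underlying matrices and a trio subset are given)
#' reproduces the genotype-stratified miRNA-vs-gene expression scatter
#' for each requested trio.
#'
#' @param table Result table from [run_screen()].
#' @param mrna,mirna,genotypes Optional matrices for trio scatter data.
#' @param trios Optional `data.frame` of trios to export scatter data
#'   for (columns `mirna_id`, `gene_id`, `snp_id`).
#' @return List with `qq`, `manhattan` and (optionally) `trio_data`
#'   data.frames.
#' @export
export_plot_data <- function(table, mrna = NULL, mirna = NULL,
                             genotypes = NULL, trios = NULL) {
  ok <- table[table$status == "ok" & !is.na(table$p_interaction), ,
              drop = FALSE]
  m <- nrow(ok)
  qq <- if (m) {
    p_sorted <- sort(ok$p_interaction)
    data.frame(expected = -log10((seq_len(m) - 0.5) / m),
               observed = -log10(p_sorted))
  } else data.frame(expected = numeric(), observed = numeric())
  man <- ok[is.finite(ok$q_value), , drop = FALSE]
  manhattan <- data.frame(snp_id = man$snp_id, chrom = man$chrom,
                          pos = man$pos,
                          neg_log10_q = -log10(pmax(man$q_value,
                                                    .Machine$double.xmin)),
                          stringsAsFactors = FALSE)
  out <- list(qq = qq, manhattan = manhattan)
  if (!is.null(trios) && !is.null(mrna) && !is.null(mirna) &&
      !is.null(genotypes)) {
    common <- Reduce(intersect, list(sample_ids(mrna), sample_ids(mirna),
                                     sample_ids(genotypes)))
    td <- lapply(seq_len(nrow(trios)), function(i) {
      data.frame(mirna_id = trios$mirna_id[i], gene_id = trios$gene_id[i],
                 snp_id = trios$snp_id[i], sample_id = common,
                 x_mir = mirna$values[trios$mirna_id[i], common],
                 y = mrna$values[trios$gene_id[i], common],
                 genotype = genotypes$dosage[trios$snp_id[i], common],
                 stringsAsFactors = FALSE)
    })
    out$trio_data <- do.call(rbind, td)
    rownames(out$trio_data) <- NULL
  }
  out
}
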