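# Synthetic cohorts with the statistical structure the interaction model
# assumes: HWE genotypes (optionally with two-subpopulation allele
# frequency divergence), log2-scale expression, eQTL main effects,
# genotype-specific miRNA->gene slopes, Gaussian noise, raw-zero miRNA
# dropout and optional gross-outlier contamination.

#' Simulation scenario
#'
#' Full generative parameterization of a synthetic cohort. Defaults
#' describe a realistic single-cohort eQTL setting: 500 samples (mid-range
#' of the 300-700 cohorts the method targets), MAF 0.3, miRNA log2
#' expression ~ N(5, 1) with 2% raw-zero dropout, a moderate repressive
#' miRNA slope (b3 = -0.5), unit residual SD, and no interaction
#' (b6 = b7 = 0: a null scenario unless effects are requested).
#'
#' @param n_samples Cohort size.
#' @param subpop_props Subpopulation mixing proportions (sums to 1).
#' @param allele_freqs Minor-allele frequencies in (0, 0.5]: a matrix
#'   (subpopulations x SNPs), or a vector/scalar recycled across
#'   subpopulations and SNPs.
#' @param n_snps Number of SNPs to simulate.
#' @param beta Named vector `b0..b7` of model coefficients (intercept,
#'   pc1, pc2, miRNA slope, het and hom-minor eQTL shifts, het and
#'   hom-minor interaction slopes).
#' @param noise_sd Residual SD of the gene-expression noise (log2 scale).
#' @param mirna_mean,mirna_sd miRNA log2-expression mean and SD.
#' @param mirna_zero_prob Probability a sample's raw miRNA count is zero.
#' @param outlier_frac Fraction of samples receiving a gross expression
#'   shift.
#' @param outlier_shift_sd SD of the shift, in units of `noise_sd`.
#' @param seed Integer seed; all scenario-level randomness flows from it.
#' @return A `SimulationScenario` list.
#' @export
simulation_scenario <- function(n_samples = 500L,
                                subpop_props = 1,
                                allele_freqs = 0.3,
                                n_snps = 1L,
                                beta = c(b0 = 8, b1 = 0, b2 = 0,
                                         b3 = -0.5, b4 = 0, b5 = 0,
                                         b6 = 0, b7 = 0),
                                noise_sd = 1,
                                mirna_mean = 5, mirna_sd = 1,
                                mirna_zero_prob = 0.02,
                                outlier_frac = 0,
                                outlier_shift_sd = 0,
                                seed = 1L) {
  subpop_props <- as.numeric(subpop_props)
  if (abs(sum(subpop_props) - 1) > 1e-8)
    stop("subpop_props must sum to 1", call. = FALSE)
  n_pop <- length(subpop_props)
  if (!is.matrix(allele_freqs))
    allele_freqs <- matrix(allele_freqs, nrow = n_pop, ncol = n_snps)
  if (nrow(allele_freqs) != n_pop || ncol(allele_freqs) != n_snps)
    stop("allele_freqs must be subpopulations x SNPs", call. = FALSE)
  if (any(allele_freqs <= 0 | allele_freqs > 0.5))
    stop("allele frequencies must lie in (0, 0.5]", call. = FALSE)
  b <- c(b0 = 0, b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 0, b6 = 0, b7 = 0)
  b[names(beta)] <- beta
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 subpop_props = subpop_props,
                 allele_freqs = allele_freqs,
                 n_snps = as.integer(n_snps),
                 beta = b, noise_sd = noise_sd,
                 mirna_mean = mirna_mean, mirna_sd = mirna_sd,
                 mirna_zero_prob = mirna_zero_prob,
                 outlier_frac = outlier_frac,
                 outlier_shift_sd = outlier_shift_sd,
                 seed = as.integer(seed)),
            class = "SimulationScenario")
}

#' Simulate HWE genotypes with optional subpopulation structure
#'
#' Each sample's subpopulation is drawn from `subpop_props`; each SNP
#' dosage is Binomial(2, f) with f the sample's subpopulation allele
#' frequency, i.e. Hardy-Weinberg genotype classes. Reproducible from
#' `scenario$seed`.
#'
#' @param scenario A [simulation_scenario()].
#' @return List: `genotypes` (a [genotype_matrix()]) and `subpop`
#'   (integer labels per sample).
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  set.seed(scenario$seed)
  n <- scenario$n_samples
  m <- scenario$n_snps
  subpop <- sample.int(length(scenario$subpop_props), n, replace = TRUE,
                       prob = scenario$subpop_props)
  d <- matrix(0L, nrow = m, ncol = n,
              dimnames = list(sprintf("snp%05d", seq_len(m)),
                              sprintf("S%05d", seq_len(n))))
  for (i in seq_len(m))
    d[i, ] <- stats::rbinom(n, 2L, scenario$allele_freqs[subpop, i])
  info <- data.frame(snp_id = rownames(d),
                     chrom = as.character(((seq_len(m) - 1L) %% 22L) + 1L),
                     pos = 1e4L * seq_len(m),
                     major_allele = "A", minor_allele = "B",
                     stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(d, info), subpop = subpop)
}

#' Simulate one trio's expression from the generative model
#'
#' `x_mir ~ N(mirna_mean, mirna_sd)`, masked to raw-zero with probability
#' `mirna_zero_prob`; `y` is the interaction-model right-hand side with
#' `eps ~ N(0, noise_sd)`; a fraction `outlier_frac` of samples receive
#' an additional shift `N(0, outlier_shift_sd * noise_sd)`. Draws from
#' the caller's RNG stream (seed the stream once per scenario; see
#' [simulate_screen()]).
#'
#' @param genotype_class Dosage vector in `{0, 1, 2, NA}`.
#' @param pcs Matrix/data.frame with columns `pc1`, `pc2` per sample, or
#'   `NULL` for zeros.
#' @param scenario A [simulation_scenario()].
#' @return List: `x_mir` (log2 values), `raw_zero` (mask), `y`, and
#'   `truth` (beta, noise_sd, per-class slopes, outlier indices).
#' @export
simulate_trio_expression <- function(genotype_class, pcs, scenario) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  n <- length(genotype_class)
  if (is.null(pcs)) pcs <- data.frame(pc1 = rep(0, n), pc2 = rep(0, n))
  pcs <- as.data.frame(pcs)
  b <- scenario$beta
  x <- stats::rnorm(n, scenario$mirna_mean, scenario$mirna_sd)
  raw_zero <- stats::runif(n) < scenario$mirna_zero_prob
  x[raw_zero] <- log2(0 + 1)  # raw zero under the default offset of 1
  het <- as.numeric(genotype_class == 1L)
  hom <- as.numeric(genotype_class == 2L)
  het[is.na(het)] <- 0; hom[is.na(hom)] <- 0
  y <- b["b0"] + b["b1"] * pcs$pc1 + b["b2"] * pcs$pc2 + b["b3"] * x +
    b["b4"] * het + b["b5"] * hom +
    b["b6"] * het * x + b["b7"] * hom * x +
    stats::rnorm(n, 0, scenario$noise_sd)
  outliers <- integer(0L)
  if (scenario$outlier_frac > 0) {
    outliers <- which(stats::runif(n) < scenario$outlier_frac)
    y[outliers] <- y[outliers] +
      stats::rnorm(length(outliers), 0,
                   scenario$outlier_shift_sd * scenario$noise_sd)
  }
  list(x_mir = unname(x), raw_zero = raw_zero, y = unname(y),
       truth = list(beta = b, noise_sd = scenario$noise_sd,
                    slopes = c(ref = unname(b["b3"]),
                               het = unname(b["b3"] + b["b6"]),
                               hom_minor = unname(b["b3"] + b["b7"])),
                    outliers = outliers))
}

#' Simulate a complete screen input bundle
#'
#' Generates an internally consistent set of inputs in the containers of
#' the IO layer — raw-scale mRNA and miRNA expression matrices, a
#' genotype matrix, GMT-style gene sets, a SNP-gene map, a candidate
#' pair table (including a decoy pair above the 0.01 selection threshold,
#' to exercise enumeration), and a truth table marking which trios carry
#' nonzero interaction effects. Each trio gets its own gene and SNP;
#' trios are grouped into pathways sharing one miRNA. Effect sizes:
#' "strong" trios have `|b6| = noise_sd / mirna_sd` (interaction slope
#' equal to one residual SD per miRNA-expression SD) and `b7 = b6`;
#' "weak" trios have half that. Raw matrices are `2^log2value - 1`
#' (clamped at 0), so a log2 transform with offset 1 recovers the
#' generative scale exactly.
#'
#' @param scenario Base [simulation_scenario()]; its `beta` supplies the
#'   non-interaction coefficients. `n_snps` is overridden by `n_trios`.
#' @param n_trios Number of trios in the bundle.
#' @param effect_fracs Named fractions `c(null = , weak = , strong = )`
#'   summing to 1.
#' @param trios_per_pathway Pathway (and miRNA block) size; default 20.
#' @return List: `mrna`, `mirna` (raw [expression_matrix()]), `genotypes`,
#'   `gene_sets`, `snp_map`, `pairs`, `truth` (`data.frame` with trio
#'   ids, class, b6, b7, true slopes), `subpop`, `pcs_true`.
#' @export
simulate_screen <- function(scenario, n_trios,
                            effect_fracs = c(null = 0.7, weak = 0.15,
                                             strong = 0.15),
                            trios_per_pathway = 20L) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  if (abs(sum(effect_fracs) - 1) > 1e-8)
    stop("effect_fracs must sum to 1", call. = FALSE)
  n_trios <- as.integer(n_trios)
  sc <- scenario
  sc$n_snps <- max(n_trios, 1L)
  sc$allele_freqs <- scenario$allele_freqs[,
    rep(seq_len(ncol(scenario$allele_freqs)), length.out = sc$n_snps),
    drop = FALSE]
  g <- simulate_genotypes(sc)   # seeds the RNG stream from scenario$seed
  n <- sc$n_samples
  samples <- colnames(g$genotypes$dosage)
  pc1_true <- g$subpop - mean(g$subpop)
  pcs_true <- data.frame(pc1 = pc1_true, pc2 = rep(0, n))

  n_pw <- max(1L, ceiling(n_trios / trios_per_pathway))
  pw_of_trio <- rep(seq_len(n_pw), each = trios_per_pathway,
                    length.out = n_trios)
  mirna_ids <- sprintf("mir%04d", seq_len(n_pw))
  gene_ids <- sprintf("gene%05d", seq_len(max(n_trios, 1L)))
  snp_ids <- rownames(g$genotypes$dosage)[seq_len(max(n_trios, 1L))]

  pool <- rep(names(effect_fracs), times = round(effect_fracs * n_trios))
  if (length(pool) < n_trios)                       # rounding guard
    pool <- c(pool, rep("null", n_trios - length(pool)))
  cls <- if (n_trios > 0L) sample(pool)[seq_len(n_trios)] else character(0L)
  b6_strong <- sc$noise_sd / sc$mirna_sd
  b6 <- ifelse(cls == "null", 0,
               ifelse(cls == "weak", 0.5, 1) * b6_strong *
                 ifelse(seq_len(n_trios) %% 2L == 0L, -1, 1))
  b7 <- b6

  # one miRNA expression vector (with raw-zero mask) per pathway block
  x_list <- vector("list", n_pw)
  for (k in seq_len(n_pw)) {
    xk <- stats::rnorm(n, sc$mirna_mean, sc$mirna_sd)
    zk <- stats::runif(n) < sc$mirna_zero_prob
    xk[zk] <- 0  # log2(0 + 1)
    x_list[[k]] <- list(x = xk, z = zk)
  }

  ylog <- matrix(0, nrow = max(n_trios, 1L), ncol = n,
                 dimnames = list(gene_ids, samples))
  b <- sc$beta
  for (i in seq_len(n_trios)) {
    xk <- x_list[[pw_of_trio[i]]]
    gcl <- g$genotypes$dosage[snp_ids[i], ]
    het <- as.numeric(gcl == 1L); hom <- as.numeric(gcl == 2L)
    y <- b["b0"] + b["b1"] * pcs_true$pc1 + b["b2"] * pcs_true$pc2 +
      b["b3"] * xk$x + b["b4"] * het + b["b5"] * hom +
      (b6[i] * het + b7[i] * hom) * xk$x +
      stats::rnorm(n, 0, sc$noise_sd)
    if (sc$outlier_frac > 0) {
      oi <- which(stats::runif(n) < sc$outlier_frac)
      y[oi] <- y[oi] + stats::rnorm(length(oi), 0,
                                    sc$outlier_shift_sd * sc$noise_sd)
    }
    ylog[i, ] <- y
  }
  xlog <- do.call(rbind, lapply(x_list, function(e) e$x))
  rownames(xlog) <- mirna_ids; colnames(xlog) <- samples

  # decoy miRNA/pair above the selection threshold
  decoy_x <- stats::rnorm(n, sc$mirna_mean, sc$mirna_sd)
  xlog <- rbind(xlog, mir_decoy = decoy_x)

  mrna_raw <- expression_matrix(pmax(2^ylog - 1, 0), scale = "raw")
  mirna_raw <- expression_matrix(pmax(2^xlog - 1, 0), scale = "raw")

  gene_sets <- split(gene_ids[seq_len(n_trios)], pw_of_trio)
  names(gene_sets) <- sprintf("pw%04d", seq_len(length(gene_sets)))
  if (length(gene_sets) == 0L)
    gene_sets <- list(pw0001 = gene_ids[1L])
  attr(gene_sets, "descriptions") <-
    stats::setNames(rep("synthetic pathway", length(gene_sets)),
                    names(gene_sets))

  pairs <- data.frame(
    mirna_id = c(mirna_ids[seq_len(length(gene_sets))], "mir_decoy"),
    pathway_id = c(names(gene_sets), names(gene_sets)[1L]),
    p = c(rep(0.001, length(gene_sets)), 0.02),
    stringsAsFactors = FALSE)

  snp_map <- data.frame(snp_id = snp_ids[seq_len(max(n_trios, 1L))],
                        gene_id = gene_ids[seq_len(max(n_trios, 1L))],
                        stringsAsFactors = FALSE)

  truth <- data.frame(
    mirna_id = if (n_trios) mirna_ids[pw_of_trio] else character(0L),
    gene_id = gene_ids[seq_len(n_trios)],
    snp_id = snp_ids[seq_len(n_trios)],
    class = cls[seq_len(n_trios)],
    b6 = b6[seq_len(n_trios)], b7 = b7[seq_len(n_trios)],
    stringsAsFactors = FALSE)

  list(mrna = mrna_raw, mirna = mirna_raw, genotypes = g$genotypes,
       gene_sets = gene_sets, snp_map = snp_map, pairs = pairs,
       truth = truth, subpop = g$subpop, pcs_true = pcs_true,
       scenario = sc)
}

#' Write a simulated bundle to disk in the standard input formats
#'
#' @param bundle Output of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mrna = file.path(dir, "mrna.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             gene_sets = file.path(dir, "pathways.gmt"),
             snp_map = file.path(dir, "snp_map.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expr <- function(em, path) {
    df <- data.frame(feature_id = rownames(em$values), em$values,
                     check.names = FALSE)
    for (j in seq(2L, ncol(df))) df[[j]] <- sprintf("%.17g", df[[j]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_expr(bundle$mrna, paths[["mrna"]])
  write_expr(bundle$mirna, paths[["mirna"]])
  gdf <- data.frame(bundle$genotypes$info, bundle$genotypes$dosage,
                    check.names = FALSE)
  utils::write.table(gdf, paths[["genotypes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt <- vapply(seq_along(bundle$gene_sets), function(i)
    paste(c(names(bundle$gene_sets)[i], "synthetic pathway",
            bundle$gene_sets[[i]]), collapse = "\t"), character(1L))
  writeLines(gmt, paths[["gene_sets"]])
  utils::write.table(bundle$snp_map, paths[["snp_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$pairs, paths[["pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
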