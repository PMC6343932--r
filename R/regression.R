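# Per-trio interaction model:
#   Y = b0 + b1*PC1 + b2*PC2 + b3*X_miR
#       + b4*1(het) + b5*1(hom_minor)
#       + b6*1(het)*X_miR + b7*1(hom_minor)*X_miR + eps
# The genotype-by-miRNA interaction is tested by comparing the full model
# to the model without the interaction columns (Type III / partial F:
# identical for the highest-order term).

condition_stop <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Build full and reduced design matrices for one trio
#'
#' Columns of the full design: intercept, pc1, pc2 (when covariates are
#' supplied), `x_mir`, one indicator per non-reference genotype class, and
#' one `x_mir` x indicator interaction per non-reference class. The
#' reduced design omits exactly the interaction columns. The reference
#' class is the homozygous-major class (dosage 0) when present, otherwise
#' the most frequent remaining class (ties to the lower dosage).
#'
#' @param x_mir miRNA log2-expression vector.
#' @param genotype_class Integer dosage vector in `{0, 1, 2}` (no
#'   missing), aligned with `x_mir`.
#' @param pcs Optional matrix/data.frame with columns `pc1`, `pc2` aligned
#'   with `x_mir`, or `NULL` to omit structure covariates.
#' @return List with elements `full`, `reduced` (design matrices),
#'   `reference` (reference class as character dosage), `classes`
#'   (observed classes), `interaction_cols` (names of interaction
#'   columns).
#' @export
encode_design <- function(x_mir, genotype_class, pcs = NULL) {
  n <- length(x_mir)
  if (length(genotype_class) != n)
    stop("x_mir and genotype_class lengths differ", call. = FALSE)
  if (anyNA(genotype_class))
    stop("genotype_class must not contain missing values", call. = FALSE)
  tab <- table(factor(genotype_class, levels = c(0, 1, 2)))
  classes <- as.integer(names(tab)[tab > 0L])
  if (length(classes) < 2L)
    condition_stop("regqtl_degenerate", "fewer than 2 genotype classes")
  reference <- if (0L %in% classes) 0L else
    classes[which.max(unname(tab[as.character(classes)]))]
  nonref <- setdiff(classes, reference)

  cols <- list("(Intercept)" = rep(1, n))
  if (!is.null(pcs)) {
    pcs <- as.data.frame(pcs)
    if (!all(c("pc1", "pc2") %in% names(pcs)))
      stop("pcs must have columns pc1 and pc2", call. = FALSE)
    if (nrow(pcs) != n) stop("pcs rows must align with x_mir", call. = FALSE)
    cols$pc1 <- pcs$pc1
    cols$pc2 <- pcs$pc2
  }
  cols$x_mir <- x_mir
  class_label <- c(`0` = "hom_major", `1` = "het", `2` = "hom_minor")
  for (cl in nonref)
    cols[[paste0("g_", class_label[as.character(cl)])]] <-
      as.numeric(genotype_class == cl)
  inter <- character(0L)
  for (cl in nonref) {
    nm <- paste0("x_mir:g_", class_label[as.character(cl)])
    cols[[nm]] <- x_mir * (genotype_class == cl)
    inter <- c(inter, nm)
  }
  full <- do.call(cbind, cols)
  colnames(full) <- names(cols)
  list(full = full,
       reduced = full[, setdiff(colnames(full), inter), drop = FALSE],
       reference = unname(class_label[as.character(reference)]),
       reference_dosage = reference,
       classes = classes,
       interaction_cols = inter)
}

#' Ordinary least squares fit with diagnostics
#'
#' QR-based least squares. Rank deficiency is detected and signalled
#' (condition class `regqtl_rank_deficient`) rather than silently
#' pseudo-inverted; too few observations signal
#' `regqtl_insufficient_data`.
#'
#' @param design Design matrix (n x k) with column names.
#' @param y Response vector of length n.
#' @return List: `coefficients`, `fitted`, `residuals`, `rss`, `leverage`
#'   (hat diagonal), `df_residual`, `sigma2` (residual variance),
#'   `vcov` (coefficient covariance), `k` (columns), `n`.
#' @export
fit_ols <- function(design, y) {
  n <- length(y)
  if (nrow(design) != n) stop("design rows must match y", call. = FALSE)
  k <- ncol(design)
  if (n <= k)
    condition_stop("regqtl_insufficient_data",
                   sprintf("n = %d observations for %d columns", n, k))
  qrd <- qr(design)
  if (qrd$rank < k)
    condition_stop("regqtl_rank_deficient",
                   paste0("design is rank deficient (rank ", qrd$rank,
                          " < ", k, " columns)"))
  beta <- qr.coef(qrd, y)
  fitted <- drop(design %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  q1 <- qr.Q(qrd)[, seq_len(k), drop = FALSE]
  leverage <- rowSums(q1^2)
  df_residual <- n - k
  sigma2 <- rss / df_residual
  r <- qr.R(qrd)[seq_len(k), seq_len(k), drop = FALSE]
  xtx_inv <- chol2inv(r)
  # undo any column pivoting in the qr
  piv <- qrd$pivot[seq_len(k)]
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(design), colnames(design))
  list(coefficients = beta, fitted = fitted, residuals = res, rss = rss,
       leverage = leverage, df_residual = df_residual, sigma2 = sigma2,
       vcov = vcov, k = k, n = n)
}

# numerically exact fit: zero residual variance to working precision.
# The threshold is far below any plausible biological noise floor but
# far above double-precision rounding of a genuinely exact fit.
is_exact_fit <- function(fit) {
  fit$rss <= 1e-22 * max(1, sum(fit$fitted^2))
}

#' Cook's distances from a fitted record
#'
#' `D_i = r_i^2 * h_ii / (k * s^2 * (1 - h_ii)^2)` with `k` the number of
#' design columns and `s^2` the residual variance; equals the scaled shift
#' in fitted values from deleting sample i. Exact leverage points
#' (`h_ii = 1`) report `Inf`.
#'
#' @param fit A record from [fit_ols()].
#' @return Non-negative vector of per-sample distances.
#' @export
cooks_distances <- function(fit) {
  if (is_exact_fit(fit)) return(rep(0, fit$n))
  h <- fit$leverage
  d <- fit$residuals^2 * h / (fit$k * fit$sigma2 * (1 - h)^2)
  d[h >= 1 - 1e-12] <- Inf
  d
}

#' Partial F-test of the interaction terms
#'
#' `F = ((RSS_red - RSS_full) / df_num) / (RSS_full / df_den)` where
#' `df_num` is the number of interaction columns dropped and `df_den` the
#' full-model residual df. Because the genotype-by-miRNA interaction is
#' the highest-order term in the model, this partial F equals the Type III
#' (Yates weighted squares of means) F for the interaction.
#'
#' @param full,reduced Records from [fit_ols()] on the same samples; the
#'   reduced design must be the full design minus the interaction columns.
#' @return List `f_stat`, `df_num`, `df_den`, `p`.
#' @export
interaction_f_test <- function(full, reduced) {
  if (full$n != reduced$n)
    stop("full and reduced fits use different samples", call. = FALSE)
  df_num <- full$k - reduced$k
  if (df_num < 1L) stop("reduced model is not nested", call. = FALSE)
  df_den <- full$df_residual
  if (df_den < 1L)
    condition_stop("regqtl_insufficient_data", "no residual df")
  if (is_exact_fit(full))
    condition_stop("regqtl_degenerate",
                   "zero residual sum of squares: F undefined")
  f <- max(0, (reduced$rss - full$rss) / df_num) / (full$rss / df_den)
  list(f_stat = f, df_num = df_num, df_den = df_den,
       p = stats::pf(f, df_num, df_den, lower.tail = FALSE))
}

#' Options for per-trio fitting
#'
#' @param cooks_threshold Cook's distance above which a sample is removed
#'   before the single refit; default 1 (the conventional cutoff).
#'   `Inf` disables outlier removal.
#' @param min_class_n Minimum retained samples per observed genotype class
#'   after masking; trios violating it are skipped. Default 5; 0 disables.
#' @param mirna_zero_max Raw miRNA expression at or below which a sample
#'   counts as having no appreciable miRNA expression; default 0 (only
#'   exact raw zeros).
#' @return Named list of options.
#' @export
trio_options <- function(cooks_threshold = 1, min_class_n = 5L,
                         mirna_zero_max = 0) {
  list(cooks_threshold = cooks_threshold,
       min_class_n = as.integer(min_class_n),
       mirna_zero_max = mirna_zero_max)
}

empty_trio_fit <- function(status, n_total = 0L, n_missing_genotype = 0L,
                           n_removed_low_mirna = 0L) {
  list(reference_genotype = NA_character_,
       coefficients = NULL, vcov = NULL,
       genotype_slopes = c(ref = NA_real_, het = NA_real_,
                           hom_minor = NA_real_),
       genotype_slope_se = c(ref = NA_real_, het = NA_real_,
                             hom_minor = NA_real_),
       f_stat = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
       p_interaction = NA_real_, q_value = NA_real_,
       n_total = n_total,
       n_used = n_total - n_missing_genotype - n_removed_low_mirna,
       n_missing_genotype = n_missing_genotype,
       n_removed_low_mirna = n_removed_low_mirna,
       n_removed_cooks = 0L,
       status = status)
}

slope_and_se <- function(fit, term) {
  # slope for a non-reference class = b3 + its interaction coefficient
  b <- fit$coefficients
  v <- fit$vcov
  if (is.null(term)) {
    c(slope = unname(b["x_mir"]), se = sqrt(v["x_mir", "x_mir"]))
  } else {
    c(slope = unname(b["x_mir"] + b[term]),
      se = sqrt(v["x_mir", "x_mir"] + v[term, term] +
                  2 * v["x_mir", term]))
  }
}

#' Fit the interaction model for one trio
#'
#' Pipeline: (1) drop samples with missing genotype, then samples with no
#' appreciable miRNA expression (`raw_zero` mask); (2) skip the trio if
#' fewer than 2 genotype classes remain, the design is rank deficient, or
#' any retained class has fewer than `min_class_n` samples; (3) fit the
#' full and reduced models and compute Cook's distances on the full model;
#' (4) if any distance exceeds `cooks_threshold`, remove those samples and
#' refit both models exactly once; (5) report F, p, coefficients,
#' per-genotype miRNA slopes, and full sample accounting.
#'
#' @param y Gene log2-expression vector.
#' @param x_mir miRNA log2-expression vector.
#' @param genotype_class Dosage vector in `{0, 1, 2, NA}`.
#' @param pcs Optional structure covariates (`pc1`, `pc2`), aligned.
#' @param raw_zero Logical mask: samples with no appreciable raw miRNA
#'   expression (dropped before fitting). `NULL` = none.
#' @param options [trio_options()].
#' @return A `TrioFit` list; `status` is `"ok"`, `"skipped_degenerate"` or
#'   `"skipped_rank_deficient"`, and `p_interaction` is present iff
#'   status is `"ok"`.
#' @export
fit_trio <- function(y, x_mir, genotype_class, pcs = NULL,
                     raw_zero = NULL, options = trio_options()) {
  n_total <- length(y)
  if (length(x_mir) != n_total || length(genotype_class) != n_total)
    stop("y, x_mir and genotype_class must be aligned", call. = FALSE)
  if (is.null(raw_zero)) raw_zero <- rep(FALSE, n_total)
  if (length(raw_zero) != n_total)
    stop("raw_zero mask must be aligned with y", call. = FALSE)
  if (n_total == 0L) stop("empty sample set", call. = FALSE)

  has_gt <- !is.na(genotype_class)
  n_missing_genotype <- sum(!has_gt)
  keep <- has_gt & !raw_zero
  n_removed_low_mirna <- sum(has_gt & raw_zero)

  pcs_df <- if (!is.null(pcs)) as.data.frame(pcs) else NULL

  build_and_fit <- function(idx) {
    des <- encode_design(x_mir[idx], genotype_class[idx],
                         if (!is.null(pcs_df))
                           pcs_df[idx, , drop = FALSE] else NULL)
    list(design = des,
         full = fit_ols(des$full, y[idx]),
         reduced = fit_ols(des$reduced, y[idx]))
  }

  idx <- which(keep)
  skip <- function(status, n_removed_cooks = 0L) {
    out <- empty_trio_fit(status, n_total, n_missing_genotype,
                          n_removed_low_mirna)
    out$n_removed_cooks <- n_removed_cooks
    out$n_used <- n_total - n_missing_genotype - n_removed_low_mirna -
      n_removed_cooks
    out
  }
  if (length(idx) == 0L) return(skip("skipped_degenerate"))

  tab <- table(genotype_class[idx])
  if (length(tab) < 2L) return(skip("skipped_degenerate"))
  if (options$min_class_n > 0L && any(tab < options$min_class_n))
    return(skip("skipped_degenerate"))

  first <- tryCatch(build_and_fit(idx), regqtl_degenerate = function(e) e,
                    regqtl_rank_deficient = function(e) e,
                    regqtl_insufficient_data = function(e) e)
  if (inherits(first, "condition"))
    return(skip(if (inherits(first, "regqtl_rank_deficient"))
      "skipped_rank_deficient" else "skipped_degenerate"))

  n_removed_cooks <- 0L
  current <- first
  d <- cooks_distances(current$full)
  out_idx <- which(d > options$cooks_threshold)
  if (length(out_idx)) {
    n_removed_cooks <- length(out_idx)
    idx <- idx[-out_idx]
    if (length(idx) == 0L ||
        length(unique(genotype_class[idx])) < 2L)
      return(skip("skipped_degenerate", n_removed_cooks))
    current <- tryCatch(build_and_fit(idx),
                        regqtl_degenerate = function(e) e,
                        regqtl_rank_deficient = function(e) e,
                        regqtl_insufficient_data = function(e) e)
    if (inherits(current, "condition"))
      return(skip(if (inherits(current, "regqtl_rank_deficient"))
        "skipped_rank_deficient" else "skipped_degenerate",
        n_removed_cooks))
  }

  ft <- tryCatch(interaction_f_test(current$full, current$reduced),
                 regqtl_degenerate = function(e) e,
                 regqtl_insufficient_data = function(e) e)
  if (inherits(ft, "condition"))
    return(skip("skipped_degenerate", n_removed_cooks))

  des <- current$design
  full <- current$full
  slopes <- c(ref = NA_real_, het = NA_real_, hom_minor = NA_real_)
  slope_se <- slopes
  ref_lab <- des$reference
  # slope of the reference class is b3 itself
  s <- slope_and_se(full, NULL)
  slopes[["ref"]] <- s[["slope"]]
  slope_se[["ref"]] <- s[["se"]]
  if (ref_lab %in% c("het", "hom_minor")) {
    slopes[[ref_lab]] <- s[["slope"]]
    slope_se[[ref_lab]] <- s[["se"]]
  }
  for (nm in des$interaction_cols) {
    lab <- sub("^x_mir:g_", "", nm)
    s <- slope_and_se(full, nm)
    slot <- if (lab == "hom_major") "ref" else lab
    slopes[[slot]] <- s[["slope"]]
    slope_se[[slot]] <- s[["se"]]
  }

  list(reference_genotype = ref_lab,
       coefficients = full$coefficients,
       vcov = full$vcov,
       genotype_slopes = slopes,
       genotype_slope_se = slope_se,
       f_stat = ft$f_stat, df_num = ft$df_num, df_den = ft$df_den,
       p_interaction = ft$p, q_value = NA_real_,
       n_total = n_total,
       n_used = length(idx),
       n_missing_genotype = n_missing_genotype,
       n_removed_low_mirna = n_removed_low_mirna,
       n_removed_cooks = n_removed_cooks,
       status = "ok")
}
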