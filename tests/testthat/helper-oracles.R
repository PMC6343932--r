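# Independent oracles. These deliberately avoid the package's QR-based
# code paths: normal equations via solve(crossprod()), explicit
# leave-one-out refits, a double-loop BH step-up, and direct
# eigendecomposition of the small covariance matrix.

oracle_ols_rss <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

# nested-regression F for dropping `drop_cols` from X
oracle_nested_f <- function(X, y, drop_cols) {
  rss_full <- oracle_ols_rss(X, y)
  rss_red <- oracle_ols_rss(X[, setdiff(colnames(X), drop_cols),
                              drop = FALSE], y)
  df1 <- length(drop_cols)
  df2 <- nrow(X) - ncol(X)
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

# Cook's distance as the scaled fitted-value shift from deleting sample i,
# computed by explicit leave-one-out refits
oracle_cooks_loo <- function(X, y) {
  n <- nrow(X); k <- ncol(X)
  beta <- solve(crossprod(X), crossprod(X, y))
  yhat <- drop(X %*% beta)
  s2 <- sum((y - yhat)^2) / (n - k)
  vapply(seq_len(n), function(i) {
    bi <- solve(crossprod(X[-i, , drop = FALSE]),
                crossprod(X[-i, , drop = FALSE], y[-i]))
    dy <- yhat - drop(X %*% bi)
    sum(dy^2) / (k * s2)
  }, numeric(1))
}

# hand-applied BH step-up: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(m - i + 1L)
    for (j in i:m) vals[j - i + 1L] <- ps[j] * m / j
    q_sorted[i] <- min(vals, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# PCA oracle: eigendecomposition of the sample covariance X X^T / (m - 1)
oracle_pca_scores <- function(X, k) {
  e <- eigen(tcrossprod(X), symmetric = TRUE)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), nrow = k)
  list(scores = scores, values = e$values)
}

# simulate one analyzable trio dataset (no masking/outliers by default)
make_trio_data <- function(n = 100, maf = 0.3,
                           beta = c(b0 = 8, b1 = 0.3, b2 = -0.2,
                                    b3 = -0.5, b4 = 0.4, b5 = 0.2,
                                    b6 = 0, b7 = 0),
                           noise_sd = 1, with_pcs = TRUE) {
  repeat {
    g <- rbinom(n, 2, maf)
    if (length(unique(g)) >= 2 && min(table(g)) >= 5) break
  }
  pcs <- if (with_pcs) data.frame(pc1 = rnorm(n), pc2 = rnorm(n)) else NULL
  x <- rnorm(n, 5, 1)
  b <- c(b0 = 0, b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 0, b6 = 0, b7 = 0)
  b[names(beta)] <- beta
  y <- b["b0"] + b["b3"] * x + b["b4"] * (g == 1) + b["b5"] * (g == 2) +
    b["b6"] * (g == 1) * x + b["b7"] * (g == 2) * x +
    rnorm(n, 0, noise_sd)
  if (with_pcs) y <- y + b["b1"] * pcs$pc1 + b["b2"] * pcs$pc2
  list(y = unname(y), x = x, g = g, pcs = pcs, beta = b)
}

# hand-built SNPs with known survival under MAF >= 1%, class >= 5%
toy_genotypes <- function() {
  n <- 100
  rows <- list(
    keep_common   = c(rep(0, 49), rep(1, 42), rep(2, 9)),  # MAF .30
    drop_rare     = c(rep(0, 99), 1),                      # MAF .005
    drop_class    = c(rep(0, 90), rep(1, 8), rep(2, 2)),   # class .02
    keep_twoclass = c(rep(0, 90), rep(1, 10)),             # MAF .05
    drop_mono     = rep(0, n),                             # one class
    drop_boundary = c(rep(0, 93), rep(1, 5), rep(2, 2))    # hom class .02
  )
  d <- do.call(rbind, rows)
  colnames(d) <- sprintf("s%03d", seq_len(n))
  genotype_matrix(d, data.frame(
    snp_id = rownames(d), chrom = "1", pos = seq_along(rows) * 100L,
    major_allele = "A", minor_allele = "B"))
}

# independent full-pipeline trio oracle: model.matrix design, normal
# equations, LOO Cook's distances, single refit
oracle_fit_trio <- function(y, x, g, pcs = NULL, cooks_threshold = 1) {
  keep <- !is.na(g)
  y <- y[keep]; x <- x[keep]; g <- g[keep]
  if (!is.null(pcs)) pcs <- pcs[keep, , drop = FALSE]
  run <- function(y, x, g, pcs) {
    gf <- factor(g)
    ref <- if ("0" %in% levels(gf)) "0" else
      names(which.max(table(gf)))
    gf <- stats::relevel(gf, ref = ref)
    X <- stats::model.matrix(~ gf * x)
    if (!is.null(pcs))
      X <- cbind(X, pc1 = pcs$pc1, pc2 = pcs$pc2)
    inter <- grep(":", colnames(X), value = TRUE)
    rss_f <- oracle_ols_rss(X, y)
    rss_r <- oracle_ols_rss(X[, setdiff(colnames(X), inter),
                              drop = FALSE], y)
    df1 <- length(inter); df2 <- nrow(X) - ncol(X)
    f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
    list(f = f, p = pf(f, df1, df2, lower.tail = FALSE), X = X)
  }
  r1 <- run(y, x, g, pcs)
  d <- oracle_cooks_loo(r1$X, y)
  out <- which(d > cooks_threshold)
  if (length(out)) {
    y <- y[-out]; x <- x[-out]; g <- g[-out]
    if (!is.null(pcs)) pcs <- pcs[-out, , drop = FALSE]
    r1 <- run(y, x, g, pcs)
  }
  list(f = r1$f, p = r1$p, n_cooks = length(out))
}

# write a small toy expression TSV and return its path
write_expr_fixture <- function(values, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(feature_id = rownames(values), values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
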