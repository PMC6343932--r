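test_that("encode_design builds the stated column structure", {
  set.seed(31)
  x <- rnorm(30, 5)
  pcs <- data.frame(pc1 = rnorm(30), pc2 = rnorm(30))

  g3 <- rep(c(0L, 1L, 2L), each = 10)
  d3 <- encode_design(x, g3, pcs)
  expect_identical(colnames(d3$full),
                   c("(Intercept)", "pc1", "pc2", "x_mir",
                     "g_het", "g_hom_minor",
                     "x_mir:g_het", "x_mir:g_hom_minor"))
  expect_identical(ncol(d3$full), 8L)
  expect_identical(ncol(d3$reduced), 6L)
  expect_identical(d3$reference, "hom_major")

  g2 <- rep(c(0L, 1L), each = 15)
  d2 <- encode_design(x, g2, pcs)
  expect_identical(ncol(d2$full), 6L)
  expect_identical(ncol(d2$reduced), 5L)

  # homozygous-major is the reference even when not modal
  gm <- c(rep(0L, 5), rep(1L, 15), rep(2L, 10))
  expect_identical(encode_design(x, gm, pcs)$reference, "hom_major")
  # and falls back to the modal class when absent
  gn <- c(rep(1L, 20), rep(2L, 10))
  expect_identical(encode_design(x, gn, pcs)$reference, "het")
  expect_error(encode_design(x, rep(1L, 30), pcs),
               class = "regqtl_degenerate")
})

test_that("fit_ols: exact fit, hand-solved slope, rank deficiency", {
  X <- cbind(`(Intercept)` = 1, x = c(0, 1, 2, 3, 4, 5))
  f0 <- fit_ols(X, 2 * X[, "x"])
  expect_equal(unname(f0$coefficients), c(0, 2), tolerance = 1e-12)
  expect_lt(f0$rss, 1e-20)

  # Sxy = 16.5, Sxx = 17.5 -> slope 33/35, intercept 19/6 - slope*2.5
  f1 <- fit_ols(X, c(1, 2, 2, 4, 4, 6))
  expect_equal(unname(f1$coefficients["x"]), 33 / 35, tolerance = 1e-12)
  expect_equal(unname(f1$coefficients["(Intercept)"]),
               19 / 6 - 33 / 35 * 2.5, tolerance = 1e-12)

  Xc <- cbind(a = 1, b = rep(2, 6))  # collinear with intercept
  expect_error(fit_ols(Xc, rnorm(6)), class = "regqtl_rank_deficient")
  expect_error(fit_ols(X[1:2, ], 1:2), class = "regqtl_insufficient_data")
})

test_that("Cook's distances equal the explicit leave-one-out shift", {
  set.seed(32)
  for (rep in 1:3) {
    td <- make_trio_data(n = 40)
    des <- encode_design(td$x, td$g, td$pcs)
    fit <- fit_ols(des$full, td$y)
    d <- cooks_distances(fit)
    d_loo <- oracle_cooks_loo(des$full, td$y)
    expect_equal(d, d_loo, tolerance = 1e-8)
  }
  # duplicating every sample changes leverages and distances; the LOO
  # oracle must still agree
  td <- make_trio_data(n = 25)
  des <- encode_design(td$x, td$g, td$pcs)
  X2 <- rbind(des$full, des$full)
  y2 <- c(td$y, td$y)
  f2 <- fit_ols(X2, y2)
  expect_equal(cooks_distances(f2), oracle_cooks_loo(X2, y2),
               tolerance = 1e-8)
  f1 <- fit_ols(des$full, td$y)
  expect_equal(f2$leverage[1:25], f1$leverage / 2, tolerance = 1e-10)

  # exact fit -> all distances zero, F undefined
  X <- cbind(`(Intercept)` = 1, x = 1:10)
  y <- 3 + 2 * (1:10)
  f <- fit_ols(X, y)
  expect_equal(cooks_distances(f), rep(0, 10))
  expect_error(interaction_f_test(f, fit_ols(X[, 1, drop = FALSE], y)),
               class = "regqtl_degenerate")
})

test_that("interaction_f_test equals brute-force nested OLS and Type III", {
  set.seed(33)
  td <- make_trio_data(n = 60, beta = c(b0 = 8, b1 = .3, b2 = -.2,
                                        b3 = -.5, b4 = .4, b5 = .2,
                                        b6 = .5, b7 = -.4))
  des <- encode_design(td$x, td$g, td$pcs)
  full <- fit_ols(des$full, td$y)
  red <- fit_ols(des$reduced, td$y)
  ft <- interaction_f_test(full, red)
  orc <- oracle_nested_f(des$full, td$y, des$interaction_cols)
  expect_equal(ft$f_stat, orc$f, tolerance = 1e-10)
  expect_equal(ft$p, orc$p, tolerance = 1e-10)

  # equals the Type III F from car-style marginal comparison via lm/anova
  gf <- factor(td$g)
  m1 <- lm(td$y ~ td$pcs$pc1 + td$pcs$pc2 + td$x * gf)
  m0 <- lm(td$y ~ td$pcs$pc1 + td$pcs$pc2 + td$x + gf)
  a <- anova(m0, m1)
  expect_equal(ft$f_stat, a$F[2], tolerance = 1e-10)
  expect_equal(ft$p, a$`Pr(>F)`[2], tolerance = 1e-10)

  # invariance under joint row permutation
  perm <- sample(60)
  des_p <- encode_design(td$x[perm], td$g[perm],
                         td$pcs[perm, , drop = FALSE])
  ft_p <- interaction_f_test(fit_ols(des_p$full, td$y[perm]),
                             fit_ols(des_p$reduced, td$y[perm]))
  expect_equal(ft_p$f_stat, ft$f_stat, tolerance = 1e-10)

  # RSS_red == RSS_full boundary -> F = 0, p = 1
  red2 <- full; red2$k <- full$k - 2L; red2$rss <- full$rss
  expect_equal(interaction_f_test(full, red2)$p, 1)
})

test_that("fit_trio sample accounting: masking, missing genotype", {
  set.seed(34)
  td <- make_trio_data(n = 300)
  mask <- rep(FALSE, 300); mask[1:20] <- TRUE
  ft <- fit_trio(td$y, td$x, td$g, td$pcs, raw_zero = mask)
  expect_identical(ft$status, "ok")
  expect_identical(ft$n_removed_low_mirna, 20L)
  expect_identical(ft$n_used, 280L)
  expect_identical(ft$n_removed_cooks, 0L)

  g2 <- td$g; g2[21:25] <- NA
  ft2 <- fit_trio(td$y, td$x, g2, td$pcs, raw_zero = mask)
  expect_identical(ft2$n_missing_genotype, 5L)
  expect_identical(ft2$n_used, 275L)
  expect_identical(ft2$n_total - ft2$n_missing_genotype -
                     ft2$n_removed_low_mirna - ft2$n_removed_cooks,
                   ft2$n_used)

  # all retained samples in one genotype class -> skipped, no p
  g3 <- td$g; g3[td$g != 0] <- NA
  ft3 <- fit_trio(td$y, td$x, g3, td$pcs)
  expect_identical(ft3$status, "skipped_degenerate")
  expect_true(is.na(ft3$p_interaction))
})

test_that("Cook's refit removes a gross outlier and changes inference", {
  set.seed(35)
  td <- make_trio_data(n = 120)
  y <- td$y
  first <- fit_trio(y, td$x, td$g, td$pcs,
                    options = trio_options(cooks_threshold = Inf,
                                           min_class_n = 0))
  # a pure response shift at a low-leverage point has Cook's D bounded
  # near h*(n-k)/(k*(1-h)) ~ 1; inject at the highest-leverage sample,
  # where a 100-sigma shift is always influential
  des <- encode_design(td$x, td$g, td$pcs)
  i <- which.max(fit_ols(des$full, y)$leverage)
  y[i] <- y[i] + 100 * sd(y)
  ft <- fit_trio(y, td$x, td$g, td$pcs)
  expect_gte(ft$n_removed_cooks, 1L)
  single <- fit_trio(y, td$x, td$g, td$pcs,
                     options = trio_options(cooks_threshold = Inf,
                                            min_class_n = 0))
  expect_false(isTRUE(all.equal(ft$p_interaction, single$p_interaction)))

  # with no outliers the refit path is a no-op: identical output
  clean <- fit_trio(td$y, td$x, td$g, td$pcs)
  expect_identical(clean$n_removed_cooks, 0L)
  expect_identical(clean$f_stat, first$f_stat)
  expect_identical(clean$coefficients, first$coefficients)
  # and re-running is idempotent
  again <- fit_trio(td$y, td$x, td$g, td$pcs)
  expect_identical(again, clean)
})

test_that("genotype_slopes identity: slope(c) - slope(ref) = interaction coef", {
  set.seed(36)
  for (rep in 1:5) {
    td <- make_trio_data(n = 90, beta = c(b0 = 8, b3 = -.5, b4 = .3,
                                          b5 = .1, b6 = runif(1, -1, 1),
                                          b7 = runif(1, -1, 1)))
    ft <- fit_trio(td$y, td$x, td$g, td$pcs)
    co <- ft$coefficients
    expect_equal(ft$genotype_slopes[["ref"]], unname(co["x_mir"]))
    if ("x_mir:g_het" %in% names(co))
      expect_equal(ft$genotype_slopes[["het"]] - ft$genotype_slopes[["ref"]],
                   unname(co["x_mir:g_het"]), tolerance = 1e-12)
    if ("x_mir:g_hom_minor" %in% names(co))
      expect_equal(ft$genotype_slopes[["hom_minor"]] -
                     ft$genotype_slopes[["ref"]],
                   unname(co["x_mir:g_hom_minor"]), tolerance = 1e-12)
  }
})

test_that("noiseless data recovers every coefficient exactly", {
  set.seed(37)
  g <- rep(c(0L, 1L, 2L), each = 10)
  pcs <- data.frame(pc1 = rnorm(30), pc2 = rnorm(30))
  x <- rnorm(30, 5)
  b <- c(8, 0.3, -0.2, -0.5, 0.4, 0.2, 0.6, -0.3)
  y <- b[1] + b[2] * pcs$pc1 + b[3] * pcs$pc2 + b[4] * x +
    b[5] * (g == 1) + b[6] * (g == 2) +
    b[7] * (g == 1) * x + b[8] * (g == 2) * x
  # exact fit has RSS 0, so the F test is undefined; perturb minutely
  ft <- fit_trio(y + rnorm(30, 0, 1e-8), x, g, pcs,
                 options = trio_options(cooks_threshold = Inf,
                                        min_class_n = 0))
  expect_equal(unname(ft$coefficients), b, tolerance = 1e-5)
  expect_equal(ft$genotype_slopes[["het"]], b[4] + b[7], tolerance = 1e-5)
})

test_that("two-class trios are tested with df_num = 1", {
  set.seed(38)
  g <- rep(c(0L, 1L), each = 40)
  x <- rnorm(80, 5)
  y <- 8 - 0.5 * x + 1.5 * (g == 1) * x + rnorm(80)
  ft <- fit_trio(y, x, g, NULL)
  expect_identical(ft$status, "ok")
  expect_identical(ft$df_num, 1L)
  expect_lt(ft$p_interaction, 0.01)
})
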