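test_that("dummy coding follows the common-homozygote reference convention", {
  cd <- code_snp(c(0, 0, 1, 2))
  expect_equal(cd$df, 2L)
  expect_equal(cd$reference, 0L)
  expect_equal(unname(cd$columns[, "g1"]), c(0, 0, 1, 0))
  expect_equal(unname(cd$columns[, "g2"]), c(0, 0, 0, 1))
  expect_true(all(rowSums(cd$columns) <= 1))

  cd2 <- code_snp(c(0, 1, 0, 1))
  expect_equal(cd2$df, 1L)
  expect_equal(colnames(cd2$columns), "g1")
  expect_equal(cd2$dropped_classes, 2L)

  # rare-homozygote-heavy column: reference flips to genotype 2
  cd3 <- code_snp(c(2, 2, 2, 1, 0))
  expect_equal(cd3$reference, 2L)
  # tie between homozygote counts breaks toward genotype 0
  cd4 <- code_snp(c(0, 2, 1))
  expect_equal(cd4$reference, 0L)

  expect_error(code_snp(c(2, 2, 2)), "monomorphic")
})

test_that("main-effect test equals one-way ANOVA with the closed-form example", {
  g <- rep(0:2, each = 3)
  y <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  names(g) <- names(y) <- paste0("i", 1:9)
  tt <- snp_main_test(y, code_snp(g), "s1")
  expect_equal(tt$statistic, 3.0, tolerance = 1e-12)
  expect_equal(tt$df, 2L)
  # closed form: P(F(2,6) > f) = (1 + 2f/6)^(-3)
  expect_equal(tt$p.value, (1 + 2 * 3 / 6)^(-3), tolerance = 1e-12)
  expect_equal(tt$p.value, 0.125, tolerance = 1e-12)

  # identical within-class residual patterns: no between-class variance
  y0 <- rep(c(-1, 0, 1), times = 3)
  names(y0) <- names(g)
  t0 <- snp_main_test(y0, code_snp(g), "s1")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p.value, 1)
})

test_that("main-effect p-values are uniform under the null", {
  set.seed(51)
  ps <- replicate(2000, {
    g <- rbinom(60, 2, 0.3)
    y <- rnorm(60)
    names(g) <- names(y) <- paste0("i", 1:60)
    tryCatch(snp_main_test(y, code_snp(g))$p.value, error = function(e) NA)
  })
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 1900)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("SNP-covariate interaction test holds its type-I error and df accounting", {
  set.seed(52)
  rej <- replicate(1000, {
    n <- 300
    g <- rbinom(n, 2, 0.3)
    cv <- rnorm(n)
    y <- 0.2 * (g == 1) + 0.1 * (g == 2) + 0.3 * cv + rnorm(n)
    names(g) <- names(y) <- names(cv) <- paste0("i", 1:n)
    tryCatch(snp_covariate_test(y, code_snp(g), cv)$p.value < 0.05,
             error = function(e) NA)
  })
  rate <- mean(rej, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!is.na(rej))))

  # binary covariate absent within a genotype class: df equals the rank oracle
  g <- rep(c(0, 1, 2), times = c(30, 20, 10))
  cv <- c(rbinom(50, 1, 0.5), rep(0, 10))   # cv == 0 whenever g == 2
  set.seed(53)
  y <- rnorm(60)
  names(g) <- names(cv) <- names(y) <- paste0("i", 1:60)
  tt <- snp_covariate_test(y, code_snp(g), cv)
  d <- cbind(g == 1, g == 2)
  X_red <- cbind(1, d, cv)
  X_full <- cbind(X_red, d * cv)
  rank_oracle <- qr(X_full)$rank - qr(X_red)$rank
  expect_equal(tt$df, rank_oracle)
  expect_lt(tt$df, 2L)

  cv_const <- rep(1, 60); names(cv_const) <- names(g)
  expect_error(snp_covariate_test(y, code_snp(g), cv_const), "constant")
})

test_that("SNP-SNP test equals the cell-means-vs-additive two-way ANOVA oracle", {
  set.seed(54)
  for (rep_ in 1:5) {
    n <- 180
    g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.45)
    # ensure all 9 cells occupied
    g1[1:9] <- rep(0:2, each = 3); g2[1:9] <- rep(0:2, times = 3)
    y <- rnorm(n) + 0.3 * (g1 == 1) * (g2 == 1)
    names(g1) <- names(g2) <- names(y) <- paste0("i", 1:n)
    tt <- snp_snp_test(y, code_snp(g1), code_snp(g2))
    oracle <- twoway_anova_oracle(y, g1, g2)
    expect_equal(tt$df, 4L)
    expect_equal(tt$df, oracle$df1)
    expect_equal(tt$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(tt$p.value, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("pure epistasis is invisible to marginal tests but caught by the interaction test", {
  fix <- make_epistatic_cohort(n_sibships = 900, seed = 55)
  co <- fix$cohort
  rs <- adjusted_residual_sets(co, n_components = 10)
  g <- co$genotypes
  c1 <- code_snp(g[, fix$snp1]); c2 <- code_snp(g[, fix$snp2])
  m1 <- snp_main_test(rs$default, c1, "a")
  m2 <- snp_main_test(rs$default, c2, "b")
  ss <- snp_snp_test(rs$default, c1, c2, "a", "b")
  expect_gt(m1$p.value, 0.01)
  expect_gt(m2$p.value, 0.01)
  expect_lt(ss$p.value, 1e-8)
  expect_lt(ss$model_p, 1e-4)
})

test_that("partial-F machinery satisfies its structural invariants", {
  set.seed(56)
  n <- 120
  g1 <- rbinom(n, 2, 0.3); g2 <- rbinom(n, 2, 0.4)
  y <- rnorm(n)
  names(g1) <- names(g2) <- names(y) <- paste0("i", 1:n)
  tt <- snp_snp_test(y, code_snp(g1), code_snp(g2))
  expect_gte(tt$statistic, 0)
  # affine rescaling of the residuals leaves p unchanged
  t2 <- snp_snp_test(3.7 * y - 11, code_snp(g1), code_snp(g2))
  expect_equal(tt$p.value, t2$p.value, tolerance = 1e-10)
  expect_equal(tt$statistic, t2$statistic, tolerance = 1e-10)

  # partial F and the chi-square LRT approximation rank-agree on null data
  set.seed(57)
  pf_p <- numeric(300); lrt_p <- numeric(300)
  for (i in 1:300) {
    gg <- rbinom(1000, 2, 0.3); yy <- rnorm(1000)
    names(gg) <- names(yy) <- paste0("i", 1:1000)
    tt <- snp_main_test(yy, code_snp(gg))
    pf_p[i] <- tt$p.value
    # LRT: n log(SSE_r / SSE_f) ~ chisq(df)
    sse_f <- sum((yy - ave(yy, gg))^2)
    sse_r <- sum((yy - mean(yy))^2)
    lrt_p[i] <- pchisq(1000 * log(sse_r / sse_f), tt$df, lower.tail = FALSE)
  }
  expect_gt(cor(pf_p, lrt_p, method = "spearman"), 0.999)
})

test_that("run_scan honors counting contracts, ordering and determinism", {
  co <- make_null_cohort(n_sibships = 40, n_snps = 12, seed = 58)
  # force a monomorphic column
  co$genotypes[, 3] <- 0L
  rs <- suppressWarnings(adjusted_residual_sets(co, n_components = 4))
  sc_main <- run_scan(co, rs, kinds = "snp_main")
  expect_equal(nrow(sc_main), 11L)   # 12 SNPs minus the monomorphic one
  skips <- attr(sc_main, "skips")
  expect_true(any(grepl("monomorphic", skips$reason)))

  sc_cov <- run_scan(co, rs, kinds = "snp_covariate")
  expect_lte(nrow(sc_cov), 15L * 12L)

  sc_pair <- run_scan(co, rs, kinds = "snp_snp")
  expect_lte(nrow(sc_pair), choose(12, 2))
  key <- paste(sc_pair$snp1, sc_pair$snp2)
  expect_false(any(duplicated(key)))

  sc_pair2 <- run_scan(co, rs, kinds = "snp_snp")
  expect_identical(sc_pair, sc_pair2)
})
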