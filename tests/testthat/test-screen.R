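test_that("q-values implement BH step-up with its boundary behavior", {
  expect_equal(qvalues(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  set.seed(61)
  p <- runif(500)^1.5
  q <- qvalues(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(qvalues(c(0.5, NA)))
  # Storey rescaling never increases q
  expect_true(all(qvalues(p, storey_pi0 = TRUE) <= q + 1e-15))
})

test_that("BH q-values control the false discovery proportion under the null", {
  set.seed(62)
  fdp <- replicate(200, {
    p <- runif(2000)
    q <- qvalues(p)
    disc <- sum(q < 0.3)
    if (disc == 0) 0 else 1    # all discoveries are false under global null
  })
  # expected fraction of replicates with any (false) discovery is <= 0.3
  expect_lte(mean(fdp), 0.3 + 3 * sqrt(0.3 * 0.7 / 200))
})

test_that("cross-validated R2 recovers known predictive signal and penalizes none", {
  # a model with no information has slightly negative expected CV R2
  set.seed(63)
  v <- replicate(50, {
    y <- rnorm(150)
    as.numeric(cv_r2(y, matrix(1, 150, 1), seed = sample.int(1e6, 1)))
  })
  expect_lte(mean(v), 0.005)
  expect_lt(mean(v), 0)

  # known population R2 = 0.20 at n = 5000
  set.seed(64)
  n <- 5000
  x <- rnorm(n)
  y <- sqrt(0.2 / 0.8) * x + rnorm(n)
  est <- as.numeric(cv_r2(y, cbind(1, x), seed = 9))
  expect_lt(abs(est - 0.2), 0.02)

  # determinism under a fixed seed
  e1 <- cv_r2(y[1:400], cbind(1, x[1:400]), seed = 7)
  e2 <- cv_r2(y[1:400], cbind(1, x[1:400]), seed = 7)
  expect_identical(as.numeric(e1), as.numeric(e2))
})

test_that("incremental CV R2 isolates the interaction contribution", {
  set.seed(65)
  n <- 400
  x <- rnorm(n)
  X <- cbind(1, x)
  y <- rnorm(n)
  expect_equal(as.numeric(cv_delta(y, X, X, seed = 3)), 0)

  fix <- make_epistatic_cohort(n_sibships = 590, seed = 66)
  co <- fix$cohort
  rs <- adjusted_residual_sets(co, n_components = 10)
  des <- episcreen:::test_designs(
    data.frame(test_kind = "snp_snp",
               snp1 = colnames(co$genotypes)[fix$snp1],
               snp2 = colnames(co$genotypes)[fix$snp2],
               covariate = NA),
    rs, co$genotypes, co$covariates)
  dl <- cv_delta(des$y, des$X_full, des$X_reduced, seed = 5)
  expect_lt(abs(as.numeric(dl) - 0.03), 0.015)
  expect_equal(as.numeric(dl),
               attr(dl, "cv_r2_full") - attr(dl, "cv_r2_reduced"))
})

test_that("replication split samples one sibling per sibship into disjoint subsets", {
  ped <- simulate_pedigree(sim_config(n_sibships = 120,
                                      sibship_size_probs = c(0, 1), seed = 67))
  sp <- split_replication(ped, seed = 2)
  expect_length(sp$subset1, 120L)
  expect_length(sp$subset2, 120L)
  expect_length(intersect(sp$subset1, sp$subset2), 0L)
  sib1 <- ped$sibship_id[match(sp$subset1, ped$individual_id)]
  expect_false(any(duplicated(sib1)))
  expect_identical(sp, split_replication(ped, seed = 2))

  # singleton sibships land in subset1 only
  ped2 <- data.frame(individual_id = c("a", "b", "c"),
                     sibship_id = c("F1", "F2", "F2"))
  sp2 <- split_replication(ped2, seed = 3)
  expect_true("a" %in% sp2$subset1)
  expect_false("a" %in% sp2$subset2)
  expect_length(sp2$subset2, 1L)
  expect_error(split_replication(ped2[0, ], seed = 1), "empty")
})

test_that("strong simulated interactions replicate in both sibling subsets", {
  fix <- make_epistatic_cohort(n_sibships = 590, r2 = 0.06, seed = 68)
  co <- fix$cohort
  sp <- split_replication(co$pedigree, seed = 4)
  row <- data.frame(test_kind = "snp_snp",
                    snp1 = colnames(co$genotypes)[fix$snp1],
                    snp2 = colnames(co$genotypes)[fix$snp2],
                    covariate = NA)
  rep_ <- replication_test(row, co, sp, alpha = 0.10)
  expect_lt(rep_$p1, 0.10)
  expect_lt(rep_$p2, 0.10)
  expect_true(rep_$pass)
})

test_that("homogeneity verdicts follow sign concordance and the z-test calibration", {
  cf <- data.frame(term = c("a:b", "c:d"), estimate = c(0.5, -0.3),
                   se = c(0.1, 0.1))
  expect_equal(homogeneity_test(cf, cf)$verdict, "homogeneous")
  cf2 <- cf; cf2$estimate <- -cf$estimate
  h <- homogeneity_test(cf, cf2)
  expect_equal(h$verdict, "heterogeneous")
  expect_false(h$direction_ok)
  expect_equal(homogeneity_test(cf[0, ], cf[0, ])$verdict, "not assessable")

  # per-term false-heterogeneity rate of the magnitude z-test ~ 5%
  set.seed(69)
  b <- 2; se <- 0.4
  flag <- replicate(1000, {
    c1 <- data.frame(term = "x:y", estimate = rnorm(1, b, se), se = se)
    c2 <- data.frame(term = "x:y", estimate = rnorm(1, b, se), se = se)
    !homogeneity_test(c1, c2)$magnitude_ok
  })
  expect_lt(abs(mean(flag) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("permutation calibration hits its boundary cases", {
  set.seed(70)
  n <- 120
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  y <- rnorm(n)
  X_red <- cbind(1, g1 == 1, g1 == 2, g2 == 1, g2 == 2)
  X_full <- cbind(X_red, (g1 == 1) * (g2 == 1))
  pc_lo <- permutation_calibrate(y, X_full, X_red, threshold = -Inf,
                                 n_permutations = 100, repeats = 2, seed = 1)
  expect_equal(pc_lo$exceedance, 1)
  pc_hi <- permutation_calibrate(y, X_full, X_red, threshold = Inf,
                                 n_permutations = 100, repeats = 2, seed = 1)
  expect_equal(pc_hi$exceedance, 0)
  expect_error(permutation_calibrate(y, X_full, X_red, n_permutations = 10),
               "100")
})

test_that("gate logic vetoes on any single failed criterion", {
  cfg <- criteria_config()
  # screened interaction with q = 0.0142, delta CV R2 = 0.0165,
  # replication p = 0.0202 and 4.21e-6: positive association
  expect_true(criteria_pass(0.0142, 0.0165, 0.0202, 4.21e-6, cfg)$pass_all)
  # failing q alone vetoes
  expect_false(criteria_pass(0.35, 0.0165, 0.0202, 4.21e-6, cfg)$pass_all)
  # delta CV R2 at 0.4% fails the 0.5% threshold despite q and replication
  expect_false(criteria_pass(0.01, 0.004, 0.0202, 4.21e-6, cfg)$pass_all)
  # one failed replication subset vetoes
  expect_false(criteria_pass(0.0142, 0.0165, 0.0202, 0.2, cfg)$pass_all)
})

test_that("apply_criteria annotates, gates and is order-independent", {
  fix <- make_epistatic_cohort(n_sibships = 200, n_snps = 12, seed = 71,
                               r2 = 0.08, snp1 = 2L, snp2 = 9L)
  co <- fix$cohort
  rs <- adjusted_residual_sets(co, n_components = 5)
  pairs <- rbind(c(2L, 9L), c(1L, 3L), c(4L, 5L), c(6L, 7L), c(8L, 10L))
  sc <- run_scan(co, rs, kinds = "snp_snp", pairs = pairs)
  cfg <- criteria_config(seed = 5)
  s1 <- apply_criteria(sc, co, cfg, residual_sets = rs)
  expect_true(all(s1$pass_all ==
                    (s1$pass_q & episcreen:::isTRUE_vec(s1$pass_cv) &
                       episcreen:::isTRUE_vec(s1$pass_rep))))
  expect_true(all(s1$q_value >= s1$p_value - 1e-15))
  true_row <- s1$snp1 == colnames(co$genotypes)[2] &
    s1$snp2 == colnames(co$genotypes)[9]
  expect_true(s1$pass_all[true_row])
  expect_true(!is.na(s1$homogeneity[true_row]))

  # order independence over the result table
  perm <- c(3, 1, 5, 2, 4)
  s2 <- apply_criteria(sc[perm, ], co, cfg, residual_sets = rs)
  key <- function(d) paste(d$snp1, d$snp2)
  m <- match(key(s1), key(s2))
  expect_equal(s1$q_value, s2$q_value[m])
  expect_equal(s1$cv_delta, s2$cv_delta[m])
  expect_equal(s1$pass_all, s2$pass_all[m])

  # evaluate = "passing" short-circuit gives identical verdicts
  s3 <- apply_criteria(sc, co, cfg, residual_sets = rs, evaluate = "passing")
  expect_equal(s1$pass_all, s3$pass_all)

  summ <- criteria_summary(s1)
  expect_equal(names(summ), c("criterion", "snp_snp"))
  expect_equal(summ$snp_snp[summ$criterion == "total_tests"], nrow(sc))
})
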