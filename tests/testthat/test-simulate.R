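test_that("pedigree sizes follow the configured distribution", {
  cfg <- sim_config(n_sibships = 100, sibship_size_probs = c(0, 1),
                    n_snps = 5, seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 200L)
  expect_equal(length(unique(ped$sibship_id)), 100L)
  expect_true(all(table(ped$sibship_id) == 2L))
  expect_false(any(duplicated(ped$individual_id)))

  # mean size under probs {2: .5, 3: .5} within 3 SE of 2.5
  cfg2 <- sim_config(n_sibships = 10000, sibship_size_probs = c(0, 0.5, 0.5),
                     n_snps = 1, seed = 4)
  sizes <- as.integer(table(simulate_pedigree(cfg2)$sibship_id))
  se <- 0.5 / sqrt(10000)  # sd of a {2,3} coin is 0.5
  expect_lt(abs(mean(sizes) - 2.5), 3 * se)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_sibships = 40, n_snps = 20, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$covariates, b$covariates)
  expect_error(sim_config(sibship_size_probs = numeric(0)))
  expect_error(sim_config(missing_rate = 1))
})

test_that("unstructured founders are in Hardy-Weinberg proportions", {
  cfg <- sim_config(n_sibships = 10000, sibship_size_probs = 1,
                    n_snps = 2, maf_low = 0.5, maf_high = 0.5,
                    ancestral_freq_divergence = 0, missing_rate = 0, seed = 5)
  g <- simulate_genotypes(simulate_pedigree(cfg), cfg)$genotypes[, 1]
  n <- length(g)
  props <- c(mean(g == 0), mean(g == 1), mean(g == 2))
  for (k in 1:3) {
    p0 <- c(0.25, 0.5, 0.25)[k]
    expect_lt(abs(props[k] - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("siblings share parental gametes: genotype correlation near 0.5", {
  cfg <- sim_config(n_sibships = 5000, sibship_size_probs = c(0, 1),
                    n_snps = 5, maf_low = 0.3, maf_high = 0.4,
                    ancestral_freq_divergence = 0, missing_rate = 0, seed = 6)
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)$genotypes
  first <- !duplicated(ped$sibship_id)
  cors <- vapply(seq_len(ncol(g)), function(j)
    cor(g[first, j], g[!first, j]), numeric(1))
  # Fisher-z SE per SNP ~ 1/sqrt(K-3), averaged over 5 SNPs
  se <- (1 - 0.5^2) / sqrt(5000 - 3) / sqrt(5)
  expect_lt(abs(mean(cors) - 0.5), 3 * se)
})

test_that("ancestry proportion is recovered by the first genotype PC", {
  cfg <- sim_config(n_sibships = 800, sibship_size_probs = 1, n_snps = 400,
                    maf_low = 0.2, maf_high = 0.4,
                    ancestral_freq_divergence = 0.4, missing_rate = 0,
                    seed = 7)
  ped <- simulate_pedigree(cfg)
  sg <- simulate_genotypes(ped, cfg)
  pcs <- compute_pcs(sg$genotypes, n_components = 2)
  expect_gt(abs(cor(sg$theta, pcs$scores[, 1])), 0.9)
})

test_that("covariate table carries the 15-covariate panel with valid types", {
  ped <- simulate_pedigree(sim_config(n_sibships = 200, seed = 8))
  cov <- simulate_covariates(ped, seed = 8)
  panel <- c("age", "sex", "sbp", "dbp", "height", "weight", "diabetes",
             "hypertension", "antihtn", "htn_duration", "smoker", "mi",
             "chol", "ldl", "trig")
  expect_true(all(panel %in% names(cov)))
  expect_length(intersect(names(cov), panel), 15L)
  for (b in c("sex", "diabetes", "hypertension", "antihtn", "smoker", "mi"))
    expect_true(all(cov[[b]] %in% c(0, 1)))
  expect_true(all(is.finite(as.matrix(cov[, panel]))))
  expect_identical(cov, simulate_covariates(ped, seed = 8))
})

test_that("null trait is log-normal with the configured noise variance", {
  cfg <- sim_config(n_sibships = 2000, sibship_size_probs = 1, n_snps = 2,
                    missing_rate = 0, seed = 10)
  ped <- simulate_pedigree(cfg)
  sg <- simulate_genotypes(ped, cfg)
  cov <- simulate_covariates(ped, seed = 10)
  eff <- effects_spec(covariate_effects = numeric(0), family_sd = 0,
                      noise_sd = 1, intercept = 0)
  tr <- simulate_trait(sg, cov, eff, seed = 10)
  expect_true(all(tr$trait > 0))
  v <- var(log(tr$trait))
  expect_lt(abs(v - 1), 3 * sqrt(2 / (2000 - 1)))

  # family effects only: within-sibship log-trait variance is zero
  cfg2 <- sim_config(n_sibships = 50, sibship_size_probs = c(0, 0, 1),
                     n_snps = 2, missing_rate = 0, seed = 11)
  ped2 <- simulate_pedigree(cfg2)
  sg2 <- simulate_genotypes(ped2, cfg2)
  cov2 <- simulate_covariates(ped2, seed = 11)
  eff2 <- effects_spec(covariate_effects = numeric(0), family_sd = 1,
                       noise_sd = 0)
  tr2 <- simulate_trait(sg2, cov2, eff2, seed = 11)
  wv <- tapply(log(tr2$trait), ped2$sibship_id, var)
  expect_true(all(wv < 1e-20))
})

test_that("injected effect sizes are recoverable by OLS on the true design", {
  cfg <- sim_config(n_sibships = 800, sibship_size_probs = 1, n_snps = 10,
                    maf_low = 0.2, maf_high = 0.4, missing_rate = 0,
                    ancestral_freq_divergence = 0, seed = 12)
  ped <- simulate_pedigree(cfg)
  sg <- simulate_genotypes(ped, cfg)
  cov <- simulate_covariates(ped, seed = 12)
  eff <- effects_spec(
    main_effects = list(list(snp = 1, beta = c(0.15, 0.3))),
    epistatic_pairs = list(list(snp1 = 2, snp2 = 3,
                                gamma = matrix(c(0.25, 0, 0, 0), 2, 2))),
    covariate_effects = c(age = 0.01), family_sd = 0, noise_sd = 0.3)
  tr <- simulate_trait(sg, cov, eff, seed = 12)
  g <- sg$complete
  X <- cbind(1, cov$age, g[, 1] == 1, g[, 1] == 2,
             g[, 2] == 1, g[, 2] == 2, g[, 3] == 1, g[, 3] == 2,
             (g[, 2] == 1) * (g[, 3] == 1))
  fit <- summary(lm(log(tr$trait) ~ X - 1))$coefficients
  truth <- c(eff$intercept, 0.01, 0.15, 0.3, 0, 0, 0, 0, 0.25)
  expect_true(all(abs(fit[, "Estimate"] - truth) < 3 * fit[, "Std. Error"]))
})

test_that("effects referencing missing SNPs are rejected", {
  cfg <- sim_config(n_sibships = 10, n_snps = 4, seed = 13)
  ped <- simulate_pedigree(cfg)
  sg <- simulate_genotypes(ped, cfg)
  cov <- simulate_covariates(ped, seed = 13)
  bad <- effects_spec(main_effects = list(list(snp = 99, beta = c(1, 1))))
  expect_error(simulate_trait(sg, cov, bad, seed = 1), "out of range")
  bad2 <- effects_spec(main_effects = list(list(snp = "nope", beta = c(1, 1))))
  expect_error(simulate_trait(sg, cov, bad2, seed = 1), "unknown SNP")
})

test_that("pure-epistasis construction equalizes marginal genotype means", {
  fix <- make_epistatic_cohort(n_sibships = 800, seed = 14, family_sd = 0,
                               noise_sd = 0.2)
  g <- fix$cohort$truth$complete_genotypes
  lt <- log(fix$cohort$covariates$lvm)
  # genetic value has (near-)equal means across each SNP's genotype classes
  gen <- fix$cohort$truth$individuals$genetic_value
  m1 <- tapply(gen, g[, fix$snp1], mean)
  m2 <- tapply(gen, g[, fix$snp2], mean)
  expect_lt(diff(range(m1)), 1e-10)
  expect_lt(diff(range(m2)), 1e-10)
  # while the product cell carries the full interaction effect
  expect_gt(fix$gamma, 0)
})
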