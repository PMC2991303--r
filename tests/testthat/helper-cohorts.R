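# Shared fixture builders: all synthetic, generated at test time.

# Cohort with no genetic effects (covariate + family + noise only).
make_null_cohort <- function(n_sibships = 136, n_snps = 100, seed = 1,
                             missing_rate = 0.02, divergence = 0.2,
                             family_sd = 0.10) {
  simulate_cohort(
    sim_config(n_sibships = n_sibships, n_snps = n_snps,
               missing_rate = missing_rate,
               ancestral_freq_divergence = divergence, seed = seed),
    effects_spec(family_sd = family_sd)
  )
}

# Cohort with one embedded pure-epistasis pair (equalized marginal means).
# Returns the cohort plus the pair's column indices and true gamma.
make_epistatic_cohort <- function(n_sibships = 590, n_snps = 30, seed = 1,
                                  snp1 = 5L, snp2 = 12L, r2 = 0.03,
                                  missing_rate = 0, maf_low = 0.2,
                                  family_sd = 0.10, noise_sd = 0.25) {
  cfg <- sim_config(n_sibships = n_sibships, n_snps = n_snps,
                    maf_low = maf_low, missing_rate = missing_rate,
                    seed = seed)
  ped <- simulate_pedigree(cfg)
  sg <- simulate_genotypes(ped, cfg)
  cov <- simulate_covariates(ped, seed = seed)
  eff <- pure_epistasis_effects(sg, snp1, snp2, r2 = r2,
                                noise_sd = noise_sd, family_sd = family_sd)
  tr <- simulate_trait(sg, cov, eff, seed = seed)
  cov$lvm <- as.numeric(tr$trait)
  cohort <- structure(list(genotypes = sg$genotypes, covariates = cov,
                           pedigree = ped, snp_meta = sg$snp_meta,
                           trait_name = "lvm",
                           truth = list(theta = sg$theta,
                                        complete_genotypes = sg$complete,
                                        individuals = tr$truth,
                                        effects = eff)),
                      class = "cohort")
  list(cohort = cohort, snp1 = snp1, snp2 = snp2,
       gamma = attr(eff, "gamma"), effects = eff)
}

# Cohort with several embedded pure-epistasis pairs of varying strength
# (disjoint SNPs), mirroring a multivariable model's selected interactions.
make_multi_epistatic_cohort <- function(n_sibships = 590, n_snps = 30,
                                        seed = 1,
                                        pairs = list(c(2L, 7L), c(4L, 9L),
                                                     c(11L, 14L), c(16L, 19L)),
                                        r2s = c(0.03, 0.02, 0.015, 0.01),
                                        family_sd = 0.10, noise_sd = 0.25) {
  cfg <- sim_config(n_sibships = n_sibships, n_snps = n_snps, maf_low = 0.2,
                    missing_rate = 0, seed = seed)
  ped <- simulate_pedigree(cfg)
  sg <- simulate_genotypes(ped, cfg)
  cov <- simulate_covariates(ped, seed = seed)
  me <- list(); ep <- list()
  for (i in seq_along(pairs)) {
    e <- pure_epistasis_effects(sg, pairs[[i]][1], pairs[[i]][2], r2 = r2s[i],
                                noise_sd = noise_sd, family_sd = family_sd)
    me <- c(me, e$main_effects)
    ep <- c(ep, e$epistatic_pairs)
  }
  eff <- effects_spec(main_effects = me, epistatic_pairs = ep,
                      family_sd = family_sd, noise_sd = noise_sd)
  tr <- simulate_trait(sg, cov, eff, seed = seed)
  cov$lvm <- as.numeric(tr$trait)
  structure(list(genotypes = sg$genotypes, covariates = cov, pedigree = ped,
                 snp_meta = sg$snp_meta, trait_name = "lvm",
                 truth = list(theta = sg$theta,
                              complete_genotypes = sg$complete,
                              individuals = tr$truth, effects = eff)),
            class = "cohort")
}

# Independent two-way ANOVA oracle: partial F of the cell-means (saturated)
# model against the additive model, computed from factor-level group sums.
twoway_anova_oracle <- function(y, g1, g2) {
  f1 <- factor(g1); f2 <- factor(g2)
  fit_add <- stats::lm(y ~ f1 + f2)
  fit_cell <- stats::lm(y ~ interaction(f1, f2))
  a <- stats::anova(fit_add, fit_cell)
  list(statistic = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
       p.value = a$`Pr(>F)`[2])
}

# Exact HWE enumeration oracle: absolute configuration probabilities summed
# directly (no normalization shortcut).
hwe_exact_oracle <- function(counts) {
  n <- sum(counts)
  na_ <- 2 * counts[3] + counts[2]
  if (na_ > n) { counts <- rev(counts); na_ <- 2 * counts[3] + counts[2] }
  nb_ <- 2 * n - na_
  hets <- seq(na_ %% 2, na_, by = 2)
  probs <- vapply(hets, function(h) {
    n2 <- (na_ - h) / 2; n0 <- n - h - n2
    exp(lfactorial(n) - lfactorial(n0) - lfactorial(h) - lfactorial(n2) +
          h * log(2) + lfactorial(na_) + lfactorial(nb_) - lfactorial(2 * n))
  }, numeric(1))
  p_obs <- probs[match(counts[2], hets)]
  sum(probs[probs <= p_obs + 1e-12])
}
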