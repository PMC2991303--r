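#' Simulation configuration for sibship-structured cohorts
#'
#' Bundles the knobs of the synthetic cohort generator: number of sibships,
#' the distribution of sibship sizes, SNP panel size and minor-allele
#' frequency range, the two-way admixture model (per-sibship ancestry
#' proportion drawn from a Beta distribution, ancestral allele-frequency
#' divergence between the two parental populations), and the genotype
#' missingness rate.
#'
#' Defaults describe a desk-scale stand-in for a hypertensive sibship cohort:
#' 150 sibships with sizes 1..5 (mean 2.2), 300 candidate-gene SNPs with MAF
#' between 0.015 and 0.49, ancestry proportion ~ Beta(8, 2) (mean 0.8,
#' two-way admixture), ancestral allele-frequency divergence 0.2, and 2%
#' missing genotypes.
#'
#' @param n_sibships number of sibships to simulate.
#' @param sibship_size_probs probability vector over sibship sizes
#'   `1:length(sibship_size_probs)`; must sum to 1.
#' @param n_snps number of biallelic SNPs.
#' @param maf_low,maf_high bounds in (0, 0.5] for the per-SNP mean
#'   minor-allele frequency.
#' @param admixture_beta_params length-2 positive shape parameters of the
#'   Beta distribution of the per-sibship ancestry proportion theta.
#' @param ancestral_freq_divergence per-SNP allele-frequency difference
#'   between the two ancestral populations (population A at `p + d/2`,
#'   population B at `p - d/2`, clipped away from 0 and 1).
#' @param missing_rate probability in [0, 1) that a genotype call is missing.
#' @param seed integer seed governing all randomness downstream.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sibships = 150,
                       sibship_size_probs = c(0.25, 0.45, 0.18, 0.09, 0.03),
                       n_snps = 300,
                       maf_low = 0.015,
                       maf_high = 0.49,
                       admixture_beta_params = c(8, 2),
                       ancestral_freq_divergence = 0.2,
                       missing_rate = 0.02,
                       seed = 1L) {
  if (length(sibship_size_probs) < 1L || any(sibship_size_probs < 0))
    stop("sibship_size_probs must be a non-empty vector of non-negative probabilities")
  if (abs(sum(sibship_size_probs) - 1) > 1e-8)
    stop("sibship_size_probs must sum to 1")
  if (n_sibships < 1L) stop("n_sibships must be >= 1")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (length(admixture_beta_params) != 2L || any(admixture_beta_params <= 0))
    stop("admixture_beta_params must be two positive shapes")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(
    n_sibships = as.integer(n_sibships),
    sibship_size_probs = sibship_size_probs,
    n_snps = as.integer(n_snps),
    maf_low = maf_low, maf_high = maf_high,
    admixture_beta_params = admixture_beta_params,
    ancestral_freq_divergence = ancestral_freq_divergence,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a sibship map
#'
#' Draws a sibship size for each family from `sibship_size_probs` and assigns
#' unique individual ids within zero-padded sibship ids.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `individual_id` and `sibship_id`, one row
#'   per simulated individual.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- sample.int(length(config$sibship_size_probs), config$n_sibships,
                      replace = TRUE, prob = config$sibship_size_probs)
  fid <- sprintf("F%05d", seq_len(config$n_sibships))
  data.frame(
    individual_id = paste0(rep(fid, sizes), "_",
                           unlist(lapply(sizes, seq_len), use.names = FALSE)),
    sibship_id = rep(fid, sizes),
    stringsAsFactors = FALSE
  )
}

#' Simulate admixed sibship genotypes
#'
#' Founder allele frequencies are drawn per SNP; the two ancestral populations
#' sit at `p +/- divergence/2`. Each sibship receives an ancestry proportion
#' theta ~ Beta(a, b) shared by its members (admixture is a family-level
#' confounder), giving family allele frequencies
#' `p_fam = theta * p_A + (1 - theta) * p_B`. Two unobserved parents are drawn
#' per sibship in Hardy-Weinberg proportions at `p_fam`, and each child
#' receives one uniformly chosen allele from each parent (Mendelian
#' transmission), so sibling genotype correlation is ~0.5. Missing calls are
#' then masked uniformly at `missing_rate`.
#'
#' @param pedigree data.frame from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return list of class `sim_genotypes` with elements
#'   \describe{
#'     \item{genotypes}{individuals x SNPs matrix of minor-allele counts with
#'       `NA` for missing calls.}
#'     \item{complete}{the same matrix before missingness masking.}
#'     \item{theta}{named per-individual ancestry proportion.}
#'     \item{snp_meta}{per-SNP id, gene label, chromosome, position and the
#'       two ancestral allele frequencies.}
#'   }
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(pedigree) == 0L) stop("pedigree is empty")
  set.seed(config$seed + 1L)
  S <- config$n_snps
  K <- length(unique(pedigree$sibship_id))
  fids <- unique(pedigree$sibship_id)
  p <- stats::runif(S, config$maf_low, config$maf_high)
  d <- config$ancestral_freq_divergence
  p_a <- pmin(pmax(p + d / 2, 0.005), 0.995)
  p_b <- pmin(pmax(p - d / 2, 0.005), 0.995)
  theta_s <- stats::rbeta(K, config$admixture_beta_params[1],
                          config$admixture_beta_params[2])
  names(theta_s) <- fids
  # family allele frequencies: K x S
  p_fam <- outer(theta_s, p_a) + outer(1 - theta_s, p_b)
  draw <- function() (matrix(stats::runif(K * S), K, S) < p_fam) + 0L
  m1 <- draw(); m2 <- draw(); f1 <- draw(); f2 <- draw()
  sib_row <- match(pedigree$sibship_id, fids)
  n <- nrow(pedigree)
  pick <- function(a1, a2) {
    u <- matrix(stats::runif(n * S), n, S) < 0.5
    ifelse(u, a1[sib_row, , drop = FALSE], a2[sib_row, , drop = FALSE])
  }
  g <- pick(m1, m2) + pick(f1, f2)
  storage.mode(g) <- "integer"
  rownames(g) <- pedigree$individual_id
  colnames(g) <- sprintf("snp%04d", seq_len(S))
  complete <- g
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * S) < config$missing_rate, n, S)
    g[mask] <- NA_integer_
  }
  snp_meta <- data.frame(
    snp_id = colnames(g),
    gene = paste0("gene", sprintf("%03d", ((seq_len(S) - 1L) %/% 8L) + 1L)),
    chrom = as.character(((seq_len(S) - 1L) %% 22L) + 1L),
    pos = seq_len(S) * 10000L,
    freq_pop_a = p_a, freq_pop_b = p_b, maf_target = p,
    stringsAsFactors = FALSE
  )
  theta <- theta_s[pedigree$sibship_id]
  names(theta) <- pedigree$individual_id
  structure(list(genotypes = g, complete = complete, theta = theta,
                 snp_meta = snp_meta),
            class = "sim_genotypes")
}

# covariate names of the standard 15-covariate risk-factor panel
covariate_panel <- function() {
  c("age", "sex", "sbp", "dbp", "height", "weight", "diabetes",
    "hypertension", "antihtn", "htn_duration", "smoker", "mi",
    "chol", "ldl", "trig")
}

#' Simulate the 15-covariate risk-factor panel
#'
#' Generates the standard covariate panel used in the association scans: age,
#' sex, systolic and diastolic blood pressure, height, weight, diabetes,
#' hypertension and anti-hypertensive-medication status, duration of
#' hypertension, smoking, history of myocardial infarction, total cholesterol,
#' LDL and triglycerides. Marginal distributions mimic an older hypertensive
#' cohort (mean age ~63, ~79% hypertensive); continuous covariates are
#' Gaussian or log-normal, status covariates Bernoulli 0/1.
#'
#' @param pedigree data.frame from [simulate_pedigree()].
#' @param seed integer seed.
#' @return data.frame with `individual_id`, `sibship_id` and the 15 covariates.
#' @export
simulate_covariates <- function(pedigree, seed = 1L) {
  if (nrow(pedigree) == 0L) stop("pedigree is empty")
  set.seed(as.integer(seed) + 2L)
  n <- nrow(pedigree)
  hypertension <- stats::rbinom(n, 1, 0.79)
  out <- data.frame(
    individual_id = pedigree$individual_id,
    sibship_id = pedigree$sibship_id,
    age = stats::rnorm(n, 63, 9.5),
    sex = stats::rbinom(n, 1, 0.30),
    sbp = stats::rnorm(n, 138, 21),
    dbp = stats::rnorm(n, 80, 11),
    height = stats::rnorm(n, 168, 8.8),
    weight = stats::rlnorm(n, log(88), 0.21),
    diabetes = stats::rbinom(n, 1, 0.29),
    hypertension = hypertension,
    antihtn = stats::rbinom(n, 1, ifelse(hypertension == 1, 0.85, 0.1)),
    htn_duration = hypertension * stats::rgamma(n, shape = 1.7, scale = 9.7),
    smoker = stats::rbinom(n, 1, 0.14),
    mi = stats::rbinom(n, 1, 0.08),
    chol = stats::rnorm(n, 200, 40),
    ldl = stats::rnorm(n, 122, 36),
    trig = stats::rlnorm(n, log(115), 0.45),
    stringsAsFactors = FALSE
  )
  out
}

#' Effect specification for trait simulation
#'
#' Describes how the log-scale trait is assembled: dummy-coded SNP main
#' effects, dummy-product epistatic effects for SNP pairs, per-unit covariate
#' effects, an effect of the ancestry proportion theta (confounding), a
#' sibship random intercept and residual Gaussian noise. All genetic and
#' covariate effects act on the natural-log scale of the trait, which is
#' exponentiated so the released trait is strictly positive (log-normal, like
#' left-ventricular mass in grams).
#'
#' @param main_effects list of `list(snp =, beta = c(het, hom))` entries:
#'   per-dummy effects of heterozygote and rare-homozygote classes.
#' @param epistatic_pairs list of `list(snp1 =, snp2 =, gamma = 2x2 matrix)`
#'   entries; `gamma[j, k]` multiplies `I(g1 == j) * I(g2 == k)`.
#' @param covariate_effects named numeric, per-unit log-scale effects.
#' @param ancestry_effect log-scale effect of theta.
#' @param family_sd standard deviation of the sibship random intercept (>= 0).
#' @param noise_sd residual standard deviation (>= 0).
#' @param intercept log-scale intercept; default `log(160)` puts the trait on
#'   a ~160-gram scale.
#' @return object of class `effects_spec`.
#' @export
effects_spec <- function(main_effects = list(),
                         epistatic_pairs = list(),
                         covariate_effects = c(age = 0.003, sex = 0.12,
                                               sbp = 0.002, height = 0.004,
                                               weight = 0.004),
                         ancestry_effect = 0,
                         family_sd = 0.10,
                         noise_sd = 0.25,
                         intercept = log(160)) {
  if (family_sd < 0 || noise_sd < 0) stop("family_sd and noise_sd must be >= 0")
  for (m in main_effects)
    if (is.null(m$snp) || length(m$beta) != 2L)
      stop("each main effect needs a snp and beta = c(het, hom)")
  for (e in epistatic_pairs)
    if (is.null(e$snp1) || is.null(e$snp2) ||
        !all(dim(as.matrix(e$gamma)) == c(2L, 2L)))
      stop("each epistatic pair needs snp1, snp2 and a 2x2 gamma matrix")
  structure(list(main_effects = main_effects,
                 epistatic_pairs = epistatic_pairs,
                 covariate_effects = covariate_effects,
                 ancestry_effect = ancestry_effect,
                 family_sd = family_sd, noise_sd = noise_sd,
                 intercept = intercept),
            class = "effects_spec")
}

resolve_snp <- function(snp, g) {
  if (is.character(snp)) {
    j <- match(snp, colnames(g))
    if (is.na(j)) stop("effect references unknown SNP: ", snp)
    j
  } else {
    j <- as.integer(snp)
    if (j < 1L || j > ncol(g)) stop("effect references SNP index out of range: ", snp)
    j
  }
}

#' Simulate a positive trait from genotypes, covariates and effects
#'
#' The natural log of the trait is the sum of the intercept, covariate
#' effects, dummy-coded SNP main effects, dummy-product epistatic effects,
#' the ancestry effect, a per-sibship Gaussian random intercept and Gaussian
#' noise; the released trait is its exponential. Effects are evaluated on the
#' complete (pre-missingness) genotypes so injected signals are defined for
#' every individual.
#'
#' @param genotypes a `sim_genotypes` object or a complete genotype matrix.
#' @param covariates data.frame from [simulate_covariates()] (must carry
#'   `individual_id` and `sibship_id`).
#' @param effects an [effects_spec()].
#' @param seed integer seed for family effects and noise.
#' @return list with `trait` (named positive numeric) and `truth` (data.frame
#'   with per-individual theta, genetic value, family effect and linear
#'   predictor; the effects spec is attached as attribute `effects`).
#' @export
simulate_trait <- function(genotypes, covariates, effects, seed = 1L) {
  stopifnot(inherits(effects, "effects_spec"))
  if (inherits(genotypes, "sim_genotypes")) {
    g <- genotypes$complete
    theta <- genotypes$theta[covariates$individual_id]
  } else {
    g <- as.matrix(genotypes)
    theta <- rep(0, nrow(covariates))
  }
  g <- g[covariates$individual_id, , drop = FALSE]
  theta[is.na(theta)] <- 0
  set.seed(as.integer(seed) + 3L)
  n <- nrow(covariates)
  lp <- rep(effects$intercept, n)
  for (nm in names(effects$covariate_effects)) {
    if (!nm %in% names(covariates)) stop("covariate effect references unknown column: ", nm)
    lp <- lp + effects$covariate_effects[[nm]] * covariates[[nm]]
  }
  genetic <- rep(0, n)
  for (m in effects$main_effects) {
    j <- resolve_snp(m$snp, g)
    genetic <- genetic + m$beta[1] * (g[, j] == 1L) + m$beta[2] * (g[, j] == 2L)
  }
  for (e in effects$epistatic_pairs) {
    j1 <- resolve_snp(e$snp1, g); j2 <- resolve_snp(e$snp2, g)
    gam <- as.matrix(e$gamma)
    for (a in 1:2) for (b in 1:2)
      genetic <- genetic + gam[a, b] * (g[, j1] == a) * (g[, j2] == b)
  }
  lp <- lp + genetic + effects$ancestry_effect * theta
  fids <- unique(covariates$sibship_id)
  fam <- stats::rnorm(length(fids), 0, effects$family_sd)
  names(fam) <- fids
  fam_i <- fam[covariates$sibship_id]
  eps <- stats::rnorm(n, 0, effects$noise_sd)
  log_trait <- lp + fam_i + eps
  trait <- exp(log_trait)
  names(trait) <- covariates$individual_id
  truth <- data.frame(individual_id = covariates$individual_id,
                      sibship_id = covariates$sibship_id,
                      theta = as.numeric(theta),
                      genetic_value = genetic,
                      family_effect = as.numeric(fam_i),
                      linear_predictor = lp,
                      log_trait = log_trait,
                      stringsAsFactors = FALSE)
  attr(truth, "effects") <- effects
  list(trait = trait, truth = truth)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_genotypes()],
#' [simulate_covariates()] and [simulate_trait()] under one seed and bundling
#' the result as a `cohort` object consumed by the pipeline stages.
#'
#' @param config a [sim_config()].
#' @param effects an [effects_spec()]; defaults to covariate effects only
#'   (no genetic signal).
#' @param trait_name name of the trait column added to the covariate table.
#' @return object of class `cohort`: list with `genotypes` (matrix with NA),
#'   `covariates` (including the trait column), `pedigree`, `snp_meta` and
#'   `truth` (theta, complete genotypes, per-individual truth table).
#' @export
simulate_cohort <- function(config = sim_config(), effects = effects_spec(),
                            trait_name = "lvm") {
  ped <- simulate_pedigree(config)
  sg <- simulate_genotypes(ped, config)
  cov <- simulate_covariates(ped, seed = config$seed)
  tr <- simulate_trait(sg, cov, effects, seed = config$seed)
  cov[[trait_name]] <- as.numeric(tr$trait)
  structure(list(genotypes = sg$genotypes,
                 covariates = cov,
                 pedigree = ped,
                 snp_meta = sg$snp_meta,
                 trait_name = trait_name,
                 truth = list(theta = sg$theta,
                              complete_genotypes = sg$complete,
                              individuals = tr$truth,
                              effects = effects)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$covariates), "individuals in",
      length(unique(x$pedigree$sibship_id)), "sibships;",
      ncol(x$genotypes), "SNPs; trait:", x$trait_name, "\n")
  invisible(x)
}

#' Construct a pure-epistasis effects specification
#'
#' Builds an [effects_spec()] in which one SNP pair carries an interaction
#' effect while each SNP's marginal genotype-class means are equalized:
#' a single dummy-product effect `gamma * I(g1==1) * I(g2==1)` is combined
#' with compensating main-effect dummies equal to minus the least-squares
#' projection of the product indicator on the main-effect dummies, computed
#' from the realized genotypes. The resulting genetic term is orthogonal to
#' both SNPs' dummy codings, so single-SNP scans see null signal while the
#' interaction test sees the full effect. `gamma` is calibrated so that the
#' incremental variance explained by the interaction term (beyond main
#' effects) is `r2` of the residual trait variance:
#' `gamma^2 = r2 * noise_var / ((1 - r2) * var(orthogonalized product))`.
#'
#' @param g complete genotype matrix (no missing values for the two SNPs).
#' @param snp1,snp2 column indices or names of the interacting pair.
#' @param r2 target incremental interaction R-squared (against the trait
#'   variance left after covariates/family effects).
#' @param noise_sd residual standard deviation of the trait model.
#' @param family_sd sibship random-intercept standard deviation; counted as
#'   part of the unexplained variance when calibrating `r2`.
#' @param ... further arguments passed to [effects_spec()].
#' @return an [effects_spec()] with the calibrated epistatic pair and
#'   compensating main effects; the realized `gamma` is attached as attribute
#'   `gamma`.
#' @export
pure_epistasis_effects <- function(g, snp1, snp2, r2 = 0.03,
                                   noise_sd = 0.25, family_sd = 0.10, ...) {
  if (inherits(g, "sim_genotypes")) g <- g$complete
  if (inherits(g, "cohort")) g <- g$truth$complete_genotypes
  j1 <- resolve_snp(snp1, g); j2 <- resolve_snp(snp2, g)
  g1 <- g[, j1]; g2 <- g[, j2]
  prod11 <- as.numeric(g1 == 1L & g2 == 1L)
  X <- cbind(1, g1 == 1L, g1 == 2L, g2 == 1L, g2 == 2L)
  fit <- stats::lm.fit(X, prod11)
  v <- mean(fit$residuals^2)
  if (v <= 0) stop("product indicator has no variation beyond main effects")
  unexplained <- noise_sd^2 + family_sd^2
  gamma <- sqrt(r2 * unexplained / ((1 - r2) * v))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  eff <- effects_spec(
    main_effects = list(
      list(snp = j1, beta = c(-gamma * cf[2], -gamma * cf[3])),
      list(snp = j2, beta = c(-gamma * cf[4], -gamma * cf[5]))
    ),
    epistatic_pairs = list(
      list(snp1 = j1, snp2 = j2,
           gamma = matrix(c(gamma, 0, 0, 0), 2, 2))
    ),
    family_sd = family_sd, noise_sd = noise_sd, ...
  )
  attr(eff, "gamma") <- gamma
  eff
}
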