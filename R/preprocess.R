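#' Allele and genotype frequencies by gene counting
#'
#' @param g vector of minor-allele counts (0/1/2, NA allowed).
#' @return list with `counts` (n0, n1, n2), `n` (non-missing total),
#'   `allele_freq` (frequency of the counted allele) and `maf`
#'   (min(allele_freq, 1 - allele_freq)).
#' @export
genotype_frequencies <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("all genotypes missing")
  if (!all(g %in% 0:2)) stop("genotypes must be 0, 1, 2 or NA")
  counts <- c(n0 = sum(g == 0L), n1 = sum(g == 1L), n2 = sum(g == 2L))
  n <- length(g)
  freq <- (2 * counts[["n2"]] + counts[["n1"]]) / (2 * n)
  list(counts = counts, n = n, allele_freq = freq, maf = min(freq, 1 - freq))
}

#' Hardy-Weinberg equilibrium test
#'
#' Chi-square goodness-of-fit test (1 df) on the three genotype classes
#' against expected Hardy-Weinberg proportions, switching to the exact HWE
#' test (enumeration over heterozygote counts conditional on the allele
#' counts) whenever any observed genotype class has fewer than five
#' individuals.
#'
#' @param counts integer vector (n0, n1, n2) of genotype class counts.
#' @return list with `method` ("chisq" or "exact"), `statistic` (chi-square
#'   value, NA for the exact branch) and `p.value`.
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L) stop("counts must be (n0, n1, n2)")
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 3) stop("need at least 3 genotyped individuals")
  if (min(counts) < 5) {
    return(list(method = "exact", statistic = NA_real_,
                p.value = hwe_exact_p(counts)))
  }
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((counts - expected)^2 / expected)
  list(method = "chisq", statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Exact HWE p-value: enumerate all heterozygote counts compatible with the
# observed allele counts; p = sum of probabilities of configurations no more
# probable than the observed one (two-sided, probability ordering).
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_minor <- 2 * counts[3] + counts[2]        # copies of the rarer allele
  if (n_minor > n) {                          # orient so n_minor <= n copies
    counts <- rev(counts)
    n_minor <- 2 * counts[3] + counts[2]
  }
  het_obs <- counts[2]
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log-probability (up to a constant in h) of each heterozygote count given
  # the allele counts: P(h) proportional to 2^h / (n_AA! h! n_aa!)
  log_p <- vapply(hets, function(h) {
    hom_rare <- (n_minor - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) - lgamma(hom_common + 1) - lgamma(h + 1) - lgamma(hom_rare + 1)
  }, numeric(1))
  # normalize in log space (h-independent terms cancel)
  log_p <- log_p - max(log_p)
  prob <- exp(log_p) / sum(exp(log_p))
  p_obs <- prob[match(het_obs, hets)]
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

#' Principal components of a marker matrix
#'
#' Column-standardized PCA for admixture adjustment: missing entries are
#' mean-imputed (for PCA only), constant columns are dropped with a warning,
#' and scores are projections on the top right-singular vectors. Component
#' signs follow the convention that each component's largest-magnitude
#' loading is positive.
#'
#' @param x individuals x markers numeric matrix (NA allowed).
#' @param n_components number of components to retain (default 20).
#' @return object of class `pc_scores`: list with `scores` (individuals x
#'   components, columns PC1..), `varfrac` (non-increasing variance-explained
#'   fractions) and `dropped` (names of constant columns removed).
#' @export
compute_pcs <- function(x, n_components = 20L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, stats::sd)
  constant <- !is.finite(sds) | sds == 0
  dropped <- colnames(x)[constant]
  if (any(constant)) {
    warning(sum(constant), " constant column(s) dropped before PCA")
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) < n_components)
    stop("n_components (", n_components, ") exceeds the number of informative columns (",
         ncol(x), ")")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  if (n_components > sum(pc$sdev > OLS_TOL))
    stop("n_components exceeds the rank of the standardized matrix")
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {       # sign convention
    jmax <- which.max(abs(rot[, k]))
    if (rot[jmax, k] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- rownames(x)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, varfrac = varfrac[seq_len(n_components)],
                 dropped = dropped),
            class = "pc_scores")
}

#' Adjust the log trait to residuals
#'
#' Fits least-squares regression of the natural-log trait on the adjustment
#' covariates (default: age, sex, SBP, height, weight) and the leading
#' principal components, and returns the residuals used as the dependent
#' variable of all association tests. Covariates named in `exclude` are left
#' out of the adjustment (the SNP-covariate interaction pathway: the excluded
#' covariate is instead modeled in the interaction test itself). Individuals
#' with any missing required field are dropped (complete case) and reported.
#'
#' @param covariates data.frame with `individual_id`, the trait column and
#'   the adjustment covariates.
#' @param pcs a `pc_scores` object, or NULL to adjust without components.
#' @param exclude character vector of covariate names to leave out; must be a
#'   subset of `covariate_set`.
#' @param trait name of the trait column (positive values required).
#' @param covariate_set adjustment covariates (default age, sex, sbp, height,
#'   weight).
#' @return object of class `adjusted_trait`: list with `residuals` (named,
#'   mean zero), `used`, `excluded`, `n_components` and `dropped_ids`.
#' @export
adjust_trait <- function(covariates, pcs = NULL, exclude = character(),
                         trait = "lvm",
                         covariate_set = c("age", "sex", "sbp", "height", "weight")) {
  stopifnot(trait %in% names(covariates))
  if (!all(exclude %in% covariate_set))
    stop("exclude must be a subset of the adjustment covariate set")
  use <- setdiff(covariate_set, exclude)
  ids <- covariates$individual_id
  y_raw <- covariates[[trait]]
  bad <- !is.na(y_raw) & y_raw <= 0
  if (any(bad))
    stop("non-positive trait value for individual(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  X <- as.matrix(covariates[, use, drop = FALSE])
  if (!is.null(pcs)) {
    sc <- pcs$scores[match(ids, rownames(pcs$scores)), , drop = FALSE]
    X <- cbind(X, sc)
  }
  keep <- !is.na(y_raw) & stats::complete.cases(X)
  dropped_ids <- ids[!keep]
  y <- log(y_raw[keep])
  Xk <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
  fit <- fit_ols(Xk, y)
  res <- fit$residuals
  names(res) <- ids[keep]
  structure(list(residuals = res,
                 used = colnames(Xk)[-1],
                 excluded = exclude,
                 n_components = if (is.null(pcs)) 0L else ncol(pcs$scores),
                 dropped_ids = dropped_ids,
                 trait = trait),
            class = "adjusted_trait")
}

#' Residual sets for all scan pathways
#'
#' The SNP main-effect and SNP-SNP scans use residuals adjusted for the full
#' covariate set; each SNP-covariate interaction scan whose covariate belongs
#' to the adjustment set needs residuals built with that covariate excluded.
#' This helper computes the default residuals plus one exclusion set per
#' adjustment covariate.
#'
#' @param cohort a `cohort` object (or list with `covariates`, `genotypes`).
#' @param pcs optional `pc_scores` (e.g. from a background marker panel);
#'   computed from the cohort's own SNPs (default 20 components) when NULL.
#' @param n_components passed to [compute_pcs()] when `pcs` is NULL; 0 skips
#'   the admixture adjustment entirely (unstructured cohorts).
#' @inheritParams adjust_trait
#' @return named list of `adjusted_trait` objects: `default` plus one entry
#'   per adjustment covariate; the `pc_scores` used are attached as attribute
#'   `pcs`.
#' @export
adjusted_residual_sets <- function(cohort, pcs = NULL, n_components = 20L,
                                   covariate_set = c("age", "sex", "sbp",
                                                     "height", "weight")) {
  trait <- if (!is.null(cohort$trait_name)) cohort$trait_name else "lvm"
  if (is.null(pcs) && n_components > 0L)
    pcs <- compute_pcs(cohort$genotypes, n_components = n_components)
  sets <- list(default = adjust_trait(cohort$covariates, pcs,
                                      trait = trait,
                                      covariate_set = covariate_set))
  for (cv in covariate_set)
    sets[[cv]] <- adjust_trait(cohort$covariates, pcs, exclude = cv,
                               trait = trait, covariate_set = covariate_set)
  attr(sets, "pcs") <- pcs
  sets
}
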