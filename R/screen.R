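#' Configuration of the three false-positive reduction criteria
#'
#' Thresholds and settings of the Stage II screen: FDR q-value threshold
#' (default 0.30), incremental cross-validated R-squared threshold (default
#' 0.005, i.e. 0.5% of variance, a level calibrated so that the chance
#' exceedance probability under a permuted-residual null is below 5%),
#' replication alpha (default 0.10 in each sibling subset), the CV layout
#' (4 folds, 10 repeats) and the permutation count.
#'
#' @param q_threshold FDR q-value threshold in (0,1).
#' @param cv_threshold incremental CV R-squared threshold in (0,1).
#' @param replication_alpha per-subset replication significance level.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param cv_repeats number of repeated random partitions averaged (>= 1).
#' @param n_permutations permutations for [permutation_calibrate()].
#' @param seed integer seed for CV partitions, splits and permutations.
#' @param storey_pi0 if TRUE, rescale BH q-values by a Storey-type null
#'   proportion estimate.
#' @return object of class `criteria_config`.
#' @export
criteria_config <- function(q_threshold = 0.30, cv_threshold = 0.005,
                            replication_alpha = 0.10, cv_folds = 4L,
                            cv_repeats = 10L, n_permutations = 200L,
                            seed = 1L, storey_pi0 = FALSE) {
  stopifnot(q_threshold > 0, q_threshold < 1,
            cv_threshold > 0, cv_threshold < 1,
            replication_alpha > 0, replication_alpha < 1,
            cv_folds >= 2L, cv_repeats >= 1L)
  structure(list(q_threshold = q_threshold, cv_threshold = cv_threshold,
                 replication_alpha = replication_alpha,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), storey_pi0 = storey_pi0),
            class = "criteria_config")
}

#' FDR q-values
#'
#' Benjamini-Hochberg step-up q-values: `q_(i) = min_{j >= i} m p_(j) / j`,
#' clipped to [0,1] and returned in input order. With `storey_pi0 = TRUE`
#' the q-values are rescaled by a Storey-type estimate of the null
#' proportion, `pi0 = min(1, mean(p > lambda) / (1 - lambda))` at
#' `lambda = 0.5`.
#'
#' @param p vector of p-values in [0,1].
#' @param storey_pi0 rescale by the estimated null proportion.
#' @param lambda tuning parameter of the pi0 estimate.
#' @return q-value vector aligned with `p`.
#' @export
qvalues <- function(p, storey_pi0 = FALSE, lambda = 0.5) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  q <- stats::p.adjust(p, method = "BH")
  if (storey_pi0) {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    q <- pmin(q * pi0, 1)
  }
  q
}

# fold assignments: repeats x n matrix of fold labels, near-equal sizes
cv_partitions <- function(n, folds, repeats, seed) {
  set.seed(seed)
  base <- rep(seq_len(folds), length.out = n)
  t(vapply(seq_len(repeats), function(r) sample(base), integer(n)))
}

#' Repeated k-fold cross-validated prediction R-squared
#'
#' For each repeat the sample is randomly divided into near-equal folds; each
#' fold is predicted from a least-squares fit on its complement, and the
#' pooled prediction R-squared is `1 - SSE/SST` over all held-out
#' predictions, with SST taken about the full-sample mean. The result is the
#' mean over repeats. Negative values are not truncated: a model with no
#' predictive information scores slightly below zero. Genotype classes absent
#' from a training fold yield aliased coefficients, which are treated as zero
#' (intercept-plus-available-terms prediction) and counted in the attached
#' `events` attribute.
#'
#' @param y response vector (adjusted residuals).
#' @param X design matrix including the intercept column.
#' @param folds,repeats CV layout.
#' @param seed partition seed.
#' @param partitions optional precomputed [cv_partitions()] matrix (used to
#'   share partitions between nested models).
#' @return mean CV R-squared (numeric scalar) with attributes `per_repeat`
#'   and `events` (count of aliased-coefficient training fits).
#' @export
cv_r2 <- function(y, X, folds = 4L, repeats = 10L, seed = 1L,
                  partitions = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < folds * (ncol(X) + 2L))
    stop("sample too small for ", folds, "-fold CV of a ", ncol(X), "-column model")
  if (is.null(partitions)) partitions <- cv_partitions(n, folds, repeats, seed)
  sst <- sum((y - mean(y))^2)
  events <- 0L
  r2 <- numeric(nrow(partitions))
  for (r in seq_len(nrow(partitions))) {
    lab <- partitions[r, ]
    sse <- 0
    for (k in sort(unique(lab))) {
      test <- lab == k
      fit <- fit_ols(X[!test, , drop = FALSE], y[!test])
      if (anyNA(fit$coefficients)) events <- events + 1L
      pred <- predict_ols(fit, X[test, , drop = FALSE])
      sse <- sse + sum((y[test] - pred)^2)
    }
    r2[r] <- 1 - sse / sst
  }
  structure(mean(r2), per_repeat = r2, events = events)
}

#' Incremental cross-validated R-squared of nested models
#'
#' Difference in repeated k-fold CV prediction R-squared between a full model
#' (with interaction terms) and its reduced model (main effects only),
#' computed on identical partitions so the difference isolates the
#' interaction terms' out-of-sample contribution.
#'
#' @param y response vector.
#' @param X_full,X_reduced nested design matrices (reduced columns must be a
#'   subset of the full model's column span).
#' @inheritParams cv_r2
#' @return delta CV R-squared (full minus reduced) with attributes
#'   `cv_r2_full` and `cv_r2_reduced`.
#' @export
cv_delta <- function(y, X_full, X_reduced, folds = 4L, repeats = 10L,
                     seed = 1L, partitions = NULL) {
  if (is.null(partitions))
    partitions <- cv_partitions(length(y), folds, repeats, seed)
  full <- cv_r2(y, X_full, folds, repeats, seed, partitions = partitions)
  red <- cv_r2(y, X_reduced, folds, repeats, seed, partitions = partitions)
  structure(as.numeric(full) - as.numeric(red),
            cv_r2_full = as.numeric(full), cv_r2_reduced = as.numeric(red))
}

#' Internal replication split
#'
#' Randomly samples one sibling per sibship (without replacement) into the
#' first replication subset, then one of the remaining siblings per sibship
#' into the second. Singleton sibships contribute to the first subset only,
#' so the two subsets are disjoint with at most one member per sibship each.
#'
#' @param pedigree data.frame with `individual_id` and `sibship_id` covering
#'   all analyzed individuals.
#' @param seed integer seed.
#' @return object of class `replication_split`: list with `subset1`,
#'   `subset2` (individual id vectors) and `seed`.
#' @export
split_replication <- function(pedigree, seed = 1L) {
  if (is.null(pedigree) || nrow(pedigree) == 0L) stop("empty sibship map")
  set.seed(as.integer(seed))
  fam <- split(pedigree$individual_id, pedigree$sibship_id)
  s1 <- vapply(fam, function(m) m[sample.int(length(m), 1L)], character(1))
  rest <- Map(setdiff, fam, s1)
  rest <- rest[lengths(rest) > 0L]
  s2 <- vapply(rest, function(m) m[sample.int(length(m), 1L)], character(1))
  structure(list(subset1 = unname(s1), subset2 = unname(s2),
                 seed = as.integer(seed)),
            class = "replication_split")
}

# Per-subset pipeline: recompute PCs and adjusted residual sets within a
# replication subset (the subset re-analysis mirrors the full pipeline,
# including its admixture-adjustment dimensionality, capped by subset size).
subset_residual_sets <- function(cohort, ids, n_components = NULL,
                                 covariate_set = c("age", "sex", "sbp",
                                                   "height", "weight")) {
  sub <- cohort
  sub$covariates <- cohort$covariates[cohort$covariates$individual_id %in% ids, ,
                                      drop = FALSE]
  sub$genotypes <- cohort$genotypes[sub$covariates$individual_id, , drop = FALSE]
  sub$pedigree <- cohort$pedigree[cohort$pedigree$individual_id %in% ids, ,
                                  drop = FALSE]
  if (is.null(n_components))
    n_components <- 20L
  n_components <- min(n_components, nrow(sub$covariates) %/% 10L,
                      ncol(sub$genotypes) - 2L)
  adjusted_residual_sets(sub, n_components = max(0L, n_components),
                         covariate_set = covariate_set)
}

# Re-run a single Stage I test (one row of a scan table) on a residual set.
rerun_test <- function(row, residual_sets, genotypes, covariates) {
  g1 <- genotypes[, row$snp1]
  names(g1) <- rownames(genotypes)
  c1 <- code_snp(g1)
  if (row$test_kind == "snp_main") {
    snp_main_test(residual_sets$default, c1, row$snp1)
  } else if (row$test_kind == "snp_covariate") {
    res <- if (row$covariate %in% residual_sets$default$used)
      residual_sets[[row$covariate]] else residual_sets$default
    v <- covariates[[row$covariate]]
    names(v) <- covariates$individual_id
    snp_covariate_test(res, c1, v, row$snp1, row$covariate)
  } else {
    g2 <- genotypes[, row$snp2]
    names(g2) <- rownames(genotypes)
    snp_snp_test(residual_sets$default, c1, code_snp(g2), row$snp1, row$snp2)
  }
}

#' Replicate a Stage I test in the two sibling subsets
#'
#' Re-derives the adjustment residuals within each replication subset (a full
#' per-subset pipeline, including within-subset principal components) and
#' re-runs the identical Stage I test in each. The association replicates
#' when both subset p-values fall below `alpha`.
#'
#' @param row one-row data.frame from a [run_scan()] table (fields
#'   `test_kind`, `snp1`, `snp2`, `covariate`).
#' @param cohort the `cohort` object.
#' @param split a [split_replication()] result.
#' @param alpha per-subset significance level (default 0.10).
#' @param residual_sets1,residual_sets2 optional precomputed per-subset
#'   residual sets (reused across many tests).
#' @param n_components admixture-adjustment dimensionality for the subset
#'   pipelines (defaults to the full-sample choice of 20, capped by subset
#'   size; 0 skips PC adjustment).
#' @return list with `p1`, `p2`, `pass`, and the two subset `assoc_result`s.
#' @export
replication_test <- function(row, cohort, split, alpha = 0.10,
                             residual_sets1 = NULL, residual_sets2 = NULL,
                             n_components = NULL) {
  if (is.null(residual_sets1))
    residual_sets1 <- subset_residual_sets(cohort, split$subset1,
                                           n_components = n_components)
  if (is.null(residual_sets2))
    residual_sets2 <- subset_residual_sets(cohort, split$subset2,
                                           n_components = n_components)
  run1 <- tryCatch(rerun_test(row, residual_sets1, cohort$genotypes,
                              cohort$covariates),
                   error = function(e) e)
  run2 <- tryCatch(rerun_test(row, residual_sets2, cohort$genotypes,
                              cohort$covariates),
                   error = function(e) e)
  p1 <- if (inherits(run1, "assoc_result")) run1$p.value else NA_real_
  p2 <- if (inherits(run2, "assoc_result")) run2$p.value else NA_real_
  pass <- isTRUE(p1 < alpha) && isTRUE(p2 < alpha)
  reason <- NULL
  if (inherits(run1, "error")) reason <- c(reason, paste("subset1:", conditionMessage(run1)))
  if (inherits(run2, "error")) reason <- c(reason, paste("subset2:", conditionMessage(run2)))
  list(p1 = p1, p2 = p2, pass = pass, fit1 = run1, fit2 = run2,
       reason = reason)
}

#' Homogeneity of effects across the two replication subsets
#'
#' Checks that shared estimable interaction coefficients agree across the two
#' subset fits in direction (concordant signs) and magnitude (two-sample
#' z-test `z = (b1 - b2) / sqrt(se1^2 + se2^2)` non-significant at
#' `alpha` for every shared term).
#'
#' @param coef1,coef2 coefficient tables (`term`, `estimate`, `se`) from the
#'   two subset fits; interaction terms are identified by a ":" in the name
#'   unless `terms` is supplied.
#' @param alpha significance level of the per-term magnitude z-test.
#' @param terms optional explicit term names to compare.
#' @return list with `verdict` ("homogeneous", "heterogeneous" or
#'   "not assessable"), `direction_ok`, `magnitude_ok` and the per-term
#'   comparison table.
#' @export
homogeneity_test <- function(coef1, coef2, alpha = 0.05, terms = NULL) {
  if (is.null(terms)) {
    terms <- intersect(grep(":", coef1$term, value = TRUE),
                       grep(":", coef2$term, value = TRUE))
  }
  i1 <- match(terms, coef1$term); i2 <- match(terms, coef2$term)
  ok <- !is.na(i1) & !is.na(i2) &
    is.finite(coef1$estimate[i1]) & is.finite(coef2$estimate[i2]) &
    is.finite(coef1$se[i1]) & is.finite(coef2$se[i2])
  if (!any(ok))
    return(list(verdict = "not assessable", direction_ok = NA,
                magnitude_ok = NA, table = NULL))
  b1 <- coef1$estimate[i1][ok]; b2 <- coef2$estimate[i2][ok]
  s1 <- coef1$se[i1][ok]; s2 <- coef2$se[i2][ok]
  z <- (b1 - b2) / sqrt(s1^2 + s2^2)
  pz <- 2 * stats::pnorm(-abs(z))
  direction_ok <- all(sign(b1) == sign(b2) | (b1 == 0 & b2 == 0))
  magnitude_ok <- all(pz > alpha)
  list(verdict = if (direction_ok && magnitude_ok) "homogeneous" else "heterogeneous",
       direction_ok = direction_ok, magnitude_ok = magnitude_ok,
       table = data.frame(term = terms[ok], b1 = b1, b2 = b2, z = z,
                          p = pz, stringsAsFactors = FALSE))
}

# Build full/reduced design matrices for one scan row (shared by the CV and
# permutation machinery). Returns y, X_full, X_reduced on complete cases.
test_designs <- function(row, residual_sets, genotypes, covariates) {
  g1 <- genotypes[, row$snp1]; names(g1) <- rownames(genotypes)
  c1 <- code_snp(g1)
  if (row$test_kind == "snp_main") {
    ac <- align_cases(residual_sets$default, list(c1))
    X_full <- cbind(`(Intercept)` = 1, ac$mats[[1]])
    X_red <- X_full[, 1, drop = FALSE]
  } else if (row$test_kind == "snp_covariate") {
    res <- if (row$covariate %in% residual_sets$default$used)
      residual_sets[[row$covariate]] else residual_sets$default
    v <- covariates[[row$covariate]]; names(v) <- covariates$individual_id
    ac <- align_cases(res, list(c1), covariate = v)
    d <- ac$mats[[1]]
    prods <- d * ac$covariate
    colnames(prods) <- paste0(colnames(d), ":", row$covariate)
    X_red <- cbind(`(Intercept)` = 1, d, cv = ac$covariate)
    X_full <- cbind(X_red, prods)
  } else {
    g2 <- genotypes[, row$snp2]; names(g2) <- rownames(genotypes)
    c2 <- code_snp(g2)
    ac <- align_cases(residual_sets$default, list(c1, c2))
    d1 <- ac$mats[[1]]; d2 <- ac$mats[[2]]
    prods <- matrix(0, length(ac$y), ncol(d1) * ncol(d2))
    k <- 0L; pn <- character(ncol(prods))
    for (a in seq_len(ncol(d1))) for (b in seq_len(ncol(d2))) {
      k <- k + 1L
      prods[, k] <- d1[, a] * d2[, b]
      pn[k] <- paste0(colnames(d1)[a], ":", colnames(d2)[b])
    }
    colnames(prods) <- pn
    X_red <- cbind(`(Intercept)` = 1, d1, d2)
    X_full <- cbind(X_red, prods)
  }
  list(y = ac$y, X_full = X_full, X_reduced = X_red)
}

#' Permutation calibration of the CV threshold
#'
#' Estimates the probability that the incremental CV R-squared of an
#' interaction model exceeds a threshold by chance: the residual vector is
#' permuted uniformly, the repeated k-fold incremental CV R-squared of the
#' full (interaction) vs reduced (main effects) model is recomputed for each
#' permutation, and the exceedance fraction is returned with a binomial
#' confidence interval.
#'
#' @param y residual vector.
#' @param X_full,X_reduced nested designs of the interaction model.
#' @param threshold incremental CV R-squared threshold (default 0.005).
#' @param n_permutations number of permutations (>= 100).
#' @param folds,repeats CV layout.
#' @param seed integer seed.
#' @return list with `exceedance` (fraction), `n_exceed`, `n_permutations`,
#'   `conf_int` (95% Clopper-Pearson) and the permuted `deltas`.
#' @export
permutation_calibrate <- function(y, X_full, X_reduced, threshold = 0.005,
                                  n_permutations = 200L, folds = 4L,
                                  repeats = 10L, seed = 1L) {
  if (n_permutations < 100L) stop("use at least 100 permutations")
  set.seed(as.integer(seed))
  n <- length(y)
  deltas <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    yp <- y[sample.int(n)]
    part_seed <- sample.int(.Machine$integer.max, 1L)
    deltas[b] <- as.numeric(cv_delta(yp, X_full, X_reduced, folds, repeats,
                                     seed = part_seed))
  }
  k <- sum(deltas > threshold)
  ci <- as.numeric(stats::binom.test(k, n_permutations)$conf.int)
  list(exceedance = k / n_permutations, n_exceed = k,
       n_permutations = n_permutations, conf_int = ci, deltas = deltas,
       threshold = threshold)
}

#' Apply the three Stage II criteria to a scan table
#'
#' Annotates each Stage I result with its FDR q-value (computed per test
#' family, as the p-value vectors of the main-effect, SNP-covariate and
#' SNP-SNP families are separate), the incremental cross-validated R-squared
#' of its interaction terms (for main effects, the model CV R-squared
#' itself), and the two replication-subset p-values; sets per-criterion pass
#' flags and the overall pass (all three). Homogeneity of direction and
#' magnitude across the subsets is evaluated only for tests passing all
#' three criteria.
#'
#' @param results data.frame from [run_scan()].
#' @param cohort the `cohort` object.
#' @param config a [criteria_config()].
#' @param split optional [split_replication()]; drawn from `config$seed`
#'   when NULL.
#' @param residual_sets optional precomputed [adjusted_residual_sets()].
#' @param evaluate "all" computes CV and replication for every test
#'   (Table-style counting of each criterion); "passing" computes them only
#'   for tests that pass the q-value gate, short-circuiting the overall
#'   verdict for large null scans. Overall pass flags are identical.
#' @return `screened` data.frame: the scan columns plus `q_value`,
#'   `cv_r2_full`, `cv_r2_reduced`, `cv_delta`, `rep_p1`, `rep_p2`,
#'   `pass_q`, `pass_cv`, `pass_rep`, `pass_all`, `homogeneity`.
#' @export
apply_criteria <- function(results, cohort, config = criteria_config(),
                           split = NULL, residual_sets = NULL,
                           evaluate = c("all", "passing")) {
  evaluate <- match.arg(evaluate)
  if (nrow(results) == 0L) stop("empty result table")
  if (is.null(split)) split <- split_replication(cohort$pedigree, config$seed)
  if (is.null(residual_sets)) residual_sets <- adjusted_residual_sets(cohort)
  out <- results
  out$q_value <- NA_real_
  for (fam in unique(out$test_kind)) {
    i <- out$test_kind == fam
    # main effects screened on model p-values, interactions on partial-F
    pv <- if (fam == "snp_main") out$model_p[i] else out$p_value[i]
    out$q_value[i] <- qvalues(pv, storey_pi0 = config$storey_pi0)
  }
  out$pass_q <- out$q_value < config$q_threshold
  out$cv_r2_full <- NA_real_; out$cv_r2_reduced <- NA_real_
  out$cv_delta <- NA_real_
  out$rep_p1 <- NA_real_; out$rep_p2 <- NA_real_
  out$pass_cv <- NA; out$pass_rep <- NA
  todo <- if (evaluate == "all") seq_len(nrow(out)) else which(out$pass_q)
  ncomp <- residual_sets$default$n_components
  rs1 <- subset_residual_sets(cohort, split$subset1, n_components = ncomp)
  rs2 <- subset_residual_sets(cohort, split$subset2, n_components = ncomp)
  if (length(todo)) {
    for (i in todo) {
      row <- out[i, , drop = FALSE]
      des <- tryCatch(test_designs(row, residual_sets, cohort$genotypes,
                                   cohort$covariates),
                      error = function(e) NULL)
      if (!is.null(des)) {
        if (row$test_kind == "snp_main") {
          cv <- cv_r2(des$y, des$X_full, config$cv_folds, config$cv_repeats,
                      seed = config$seed)
          out$cv_r2_full[i] <- as.numeric(cv)
          out$cv_delta[i] <- as.numeric(cv)   # main effects gated on CV R2 itself
        } else {
          dl <- cv_delta(des$y, des$X_full, des$X_reduced, config$cv_folds,
                         config$cv_repeats, seed = config$seed)
          out$cv_r2_full[i] <- attr(dl, "cv_r2_full")
          out$cv_r2_reduced[i] <- attr(dl, "cv_r2_reduced")
          out$cv_delta[i] <- as.numeric(dl)
        }
      }
      rep_ <- replication_test(row, cohort, split, config$replication_alpha,
                               residual_sets1 = rs1, residual_sets2 = rs2)
      out$rep_p1[i] <- rep_$p1; out$rep_p2[i] <- rep_$p2
      out$pass_rep[i] <- rep_$pass
    }
    out$pass_cv[todo] <- !is.na(out$cv_delta[todo]) &
      out$cv_delta[todo] > config$cv_threshold
  }
  out$pass_all <- out$pass_q & isTRUE_vec(out$pass_cv) & isTRUE_vec(out$pass_rep)
  out$homogeneity <- NA_character_
  for (i in which(out$pass_all)) {
    rep_ <- replication_test(out[i, , drop = FALSE], cohort, split,
                             config$replication_alpha,
                             residual_sets1 = rs1, residual_sets2 = rs2)
    if (inherits(rep_$fit1, "assoc_result") && inherits(rep_$fit2, "assoc_result"))
      out$homogeneity[i] <- homogeneity_test(rep_$fit1$coefficients,
                                             rep_$fit2$coefficients)$verdict
  }
  attr(out, "split") <- split
  attr(out, "config") <- config
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Three-criterion gate logic
#'
#' Evaluates the per-criterion pass flags and the overall verdict for given
#' q-value, incremental CV R-squared and replication p-values. An
#' association is positive only when it passes all three pre-determined
#' thresholds.
#'
#' @param q FDR q-value.
#' @param cv_delta incremental CV R-squared (for main effects, the model CV
#'   R-squared itself).
#' @param p1,p2 replication p-values in the two sibling subsets.
#' @param config a [criteria_config()].
#' @return list with logical `pass_q`, `pass_cv`, `pass_rep`, `pass_all`.
#' @export
criteria_pass <- function(q, cv_delta, p1, p2, config = criteria_config()) {
  pass_q <- isTRUE(q < config$q_threshold)
  pass_cv <- isTRUE(cv_delta > config$cv_threshold)
  pass_rep <- isTRUE(p1 < config$replication_alpha) &&
    isTRUE(p2 < config$replication_alpha)
  list(pass_q = pass_q, pass_cv = pass_cv, pass_rep = pass_rep,
       pass_all = pass_q && pass_cv && pass_rep)
}

#' Criteria summary counts
#'
#' Tabulates, per test family, the total number of tests and the number
#' passing each criterion individually and all three jointly.
#'
#' @param screened output of [apply_criteria()].
#' @param p_threshold nominal p-value threshold for the first row.
#' @return data.frame with one row per criterion and one column per family.
#' @export
criteria_summary <- function(screened, p_threshold = 0.10) {
  fams <- unique(screened$test_kind)
  rows <- c("total_tests", sprintf("p_value_lt_%g", p_threshold),
            "fdr_q_lt_threshold", "cv_r2_gt_threshold",
            "replication_both_lt_alpha", "all_three")
  out <- data.frame(criterion = rows, stringsAsFactors = FALSE)
  for (fam in fams) {
    i <- screened$test_kind == fam
    pv <- if (fam == "snp_main") screened$model_p[i] else screened$p_value[i]
    out[[fam]] <- c(sum(i), sum(pv < p_threshold, na.rm = TRUE),
                    sum(screened$pass_q[i], na.rm = TRUE),
                    sum(isTRUE_vec(screened$pass_cv[i])),
                    sum(isTRUE_vec(screened$pass_rep[i])),
                    sum(screened$pass_all[i], na.rm = TRUE))
  }
  out
}
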