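#' Dummy-code a SNP genotype vector
#'
#' Codes a three-class genotype with up to two indicator columns
#' (heterozygote, rare homozygote) against the common-homozygote reference,
#' making no assumption about the underlying genetic model. Unobserved
#' classes are dropped, so the effective degrees of freedom equal the number
#' of retained indicator columns (1 or 2).
#'
#' @param g vector of minor-allele counts (0/1/2, NA allowed); names are
#'   carried to the indicator rows.
#' @return object of class `snp_coding`: list with `columns` (n x df 0/1
#'   matrix with NA rows for missing genotypes), `df`, `reference` (the
#'   reference genotype class) and `dropped_classes`.
#' @export
code_snp <- function(g) {
  obs <- g[!is.na(g)]
  if (!all(obs %in% 0:2)) stop("genotypes must be 0, 1, 2 or NA")
  classes <- sort(unique(obs))
  if (length(classes) < 2L)
    stop("monomorphic: genotype column has a single observed class")
  homs <- c(sum(obs == 0L), sum(obs == 2L))
  # reference = most frequent homozygote class, ties toward genotype 0
  reference <- if (0L %in% classes && 2L %in% classes) {
    if (homs[2] > homs[1]) 2L else 0L
  } else if (0L %in% classes) 0L else if (2L %in% classes) 2L else 1L
  keep <- setdiff(classes, reference)
  cols <- vapply(keep, function(k) as.numeric(g == k), numeric(length(g)))
  cols <- matrix(cols, nrow = length(g),
                 dimnames = list(names(g), paste0("g", keep)))
  structure(list(columns = cols, df = length(keep), reference = reference,
                 dropped_classes = setdiff(0:2, classes)),
            class = "snp_coding")
}

# Align an adjusted_trait (or named residual vector) with coding rows and
# optional covariate values; returns complete-case y, matrices and ids.
align_cases <- function(residuals, codings, covariate = NULL) {
  y <- if (inherits(residuals, "adjusted_trait")) residuals$residuals else residuals
  ids <- names(y)
  mats <- lapply(codings, function(cd) {
    m <- cd$columns
    if (!is.null(rownames(m)) && !is.null(ids)) m[match(ids, rownames(m)), , drop = FALSE]
    else m
  })
  keep <- rep(TRUE, length(y))
  for (m in mats) keep <- keep & stats::complete.cases(m)
  cv <- NULL
  if (!is.null(covariate)) {
    cv <- if (!is.null(names(covariate)) && !is.null(ids)) covariate[ids] else covariate
    keep <- keep & !is.na(cv)
  }
  list(y = y[keep],
       mats = lapply(mats, function(m) m[keep, , drop = FALSE]),
       covariate = if (is.null(cv)) NULL else as.numeric(cv[keep]),
       ids = ids[keep])
}

assoc_result <- function(test_kind, snp1, snp2 = NA_character_,
                         covariate = NA_character_, n, df, statistic, p.value,
                         model_p, coefficients) {
  structure(list(test_kind = test_kind, snp1 = snp1, snp2 = snp2,
                 covariate = covariate, n = n, df = df,
                 statistic = statistic, p.value = p.value,
                 model_p = model_p, coefficients = coefficients),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  lab <- switch(x$test_kind,
                snp_main = x$snp1,
                snp_covariate = paste(x$snp1, "x", x$covariate),
                snp_snp = paste(x$snp1, "x", x$snp2))
  cat(sprintf("%s test %s: F = %.4g on (%d, %d), p = %.3g (n = %d)\n",
              x$test_kind, lab, x$statistic, x$df, x$n - length(x$coefficients$term),
              x$p.value, x$n))
  invisible(x)
}

#' Single-SNP main-effect test
#'
#' Partial F-test of the model with the SNP's dummy indicators against the
#' intercept-only model on the adjusted residuals; equivalent to one-way
#' ANOVA across genotype classes, with up to 2 degrees of freedom.
#'
#' @param residuals an `adjusted_trait` or named residual vector.
#' @param coding a [code_snp()] result.
#' @param snp_id label for the result.
#' @return an `assoc_result` with statistic, df, p-value and the coefficient
#'   table of the full model.
#' @export
snp_main_test <- function(residuals, coding, snp_id = "snp") {
  ac <- align_cases(residuals, list(coding))
  d <- ac$mats[[1]]
  if (length(ac$y) < ncol(d) + 2L)
    stop("insufficient complete cases for the main-effect test")
  X_full <- cbind(`(Intercept)` = 1, d)
  X_red <- matrix(1, length(ac$y), 1, dimnames = list(NULL, "(Intercept)"))
  pf_ <- partial_f(X_full, X_red, ac$y)
  assoc_result("snp_main", snp_id, n = length(ac$y), df = pf_$df1,
               statistic = pf_$statistic, p.value = pf_$p.value,
               model_p = pf_$p.value, coefficients = coef_table(pf_$fit_full))
}

#' SNP-covariate interaction test
#'
#' Partial F-test comparing the full model (SNP dummies, covariate main
#' effect and SNP x covariate products) against the reduced model with only
#' the SNP and covariate main effects. If the covariate belongs to the trait
#' adjustment set, the residuals must have been built with it excluded. The
#' interaction degrees of freedom equal the number of estimable product
#' columns (rank difference).
#'
#' @param residuals `adjusted_trait` built excluding the covariate when
#'   applicable, or a named residual vector.
#' @param coding a [code_snp()] result.
#' @param covariate named numeric covariate vector.
#' @param snp_id,covariate_name labels for the result.
#' @return an `assoc_result`.
#' @export
snp_covariate_test <- function(residuals, coding, covariate,
                               snp_id = "snp", covariate_name = "covariate") {
  if (inherits(residuals, "adjusted_trait") &&
      covariate_name %in% residuals$used)
    stop("residuals were adjusted for '", covariate_name,
         "'; rebuild them with exclude = '", covariate_name, "'")
  ac <- align_cases(residuals, list(coding), covariate = covariate)
  d <- ac$mats[[1]]
  cv <- ac$covariate
  if (length(unique(cv)) < 2L)
    stop("covariate constant in complete cases")
  if (length(ac$y) < ncol(d) + 3L)
    stop("insufficient complete cases for the interaction test")
  prods <- d * cv
  colnames(prods) <- paste0(colnames(d), ":", covariate_name)
  X_red <- cbind(`(Intercept)` = 1, d, cov = cv)
  colnames(X_red)[ncol(X_red)] <- covariate_name
  X_full <- cbind(X_red, prods)
  pf_ <- partial_f(X_full, X_red, ac$y)
  if (pf_$df1 < 1L || !is.finite(pf_$statistic))
    stop("no estimable interaction term")
  assoc_result("snp_covariate", snp_id, covariate = covariate_name,
               n = length(ac$y), df = pf_$df1,
               statistic = pf_$statistic, p.value = pf_$p.value,
               model_p = omnibus_p(pf_$fit_full, ac$y),
               coefficients = coef_table(pf_$fit_full))
}

#' SNP-SNP (epistasis) interaction test
#'
#' Partial F-test comparing the full model with both SNPs' dummies plus all
#' pairwise dummy products against the reduced model with main-effect
#' dummies only. The interaction degrees of freedom are the design rank
#' difference, up to 4 depending on which joint genotype classes are
#' observed. The omnibus p-value of the full model against the intercept is
#' also reported.
#'
#' @param residuals an `adjusted_trait` or named residual vector.
#' @param coding1,coding2 [code_snp()] results for the two SNPs.
#' @param snp1_id,snp2_id labels for the result.
#' @return an `assoc_result` with the interaction statistic/df/p-value,
#'   `model_p` (omnibus full-model F p-value) and the coefficient table.
#' @export
snp_snp_test <- function(residuals, coding1, coding2,
                         snp1_id = "snp1", snp2_id = "snp2") {
  ac <- align_cases(residuals, list(coding1, coding2))
  d1 <- ac$mats[[1]]; d2 <- ac$mats[[2]]
  n <- length(ac$y)
  prods <- matrix(0, n, ncol(d1) * ncol(d2))
  pn <- character(ncol(prods))
  k <- 0L
  for (a in seq_len(ncol(d1))) for (b in seq_len(ncol(d2))) {
    k <- k + 1L
    prods[, k] <- d1[, a] * d2[, b]
    pn[k] <- paste0(snp1_id, ".", colnames(d1)[a], ":",
                    snp2_id, ".", colnames(d2)[b])
  }
  colnames(prods) <- pn
  colnames(d1) <- paste0(snp1_id, ".", colnames(d1))
  colnames(d2) <- paste0(snp2_id, ".", colnames(d2))
  X_red <- cbind(`(Intercept)` = 1, d1, d2)
  if (n < ncol(X_red) + ncol(prods) + 2L)
    stop("insufficient complete cases for the SNP-SNP test")
  X_full <- cbind(X_red, prods)
  pf_ <- partial_f(X_full, X_red, ac$y)
  if (pf_$df1 < 1L)
    stop("no observed joint variation: interaction terms not estimable")
  assoc_result("snp_snp", snp1_id, snp2 = snp2_id, n = n, df = pf_$df1,
               statistic = pf_$statistic, p.value = pf_$p.value,
               model_p = omnibus_p(pf_$fit_full, ac$y),
               coefficients = coef_table(pf_$fit_full))
}

#' Exhaustive Stage I association scan
#'
#' Runs the requested test families over every SNP (main effects), every
#' SNP x covariate combination, and every SNP pair, on the appropriate
#' adjusted-residual set. Complete cases are taken per test; monomorphic or
#' otherwise untestable combinations are skipped and logged. Ordering is
#' deterministic (SNP index, then pair index).
#'
#' @param cohort a `cohort` object.
#' @param residual_sets result of [adjusted_residual_sets()]; the `default`
#'   entry serves the main-effect and SNP-SNP scans, per-covariate entries
#'   serve the matching SNP-covariate scans.
#' @param kinds subset of `c("snp_main", "snp_covariate", "snp_snp")`.
#' @param covariates covariate names for the SNP-covariate family (default:
#'   the full 15-covariate panel).
#' @param pairs either "all" or a 2-column matrix/data.frame of SNP index or
#'   name pairs to test.
#' @param keep_coefs if TRUE, attach each test's coefficient table as a list
#'   column (memory-heavy for all-pairs scans).
#' @return data.frame with one row per performed test (`test_kind`, `snp1`,
#'   `snp2`, `covariate`, `n`, `df`, `statistic`, `p_value`, `model_p`);
#'   skipped tests with reasons are attached as attribute `skips`.
#' @export
run_scan <- function(cohort, residual_sets,
                     kinds = c("snp_main", "snp_covariate", "snp_snp"),
                     covariates = covariate_panel(),
                     pairs = "all", keep_coefs = FALSE) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  g <- cohort$genotypes
  snps <- colnames(g)
  adj_set <- residual_sets$default$used
  codings <- vector("list", length(snps))
  skip <- list()
  for (j in seq_along(snps)) {
    codings[[j]] <- tryCatch(code_snp(g[, j]), error = function(e) e$message)
    if (is.character(codings[[j]]))
      skip[[length(skip) + 1L]] <- data.frame(test_kind = "coding",
                                              snp1 = snps[j], snp2 = NA,
                                              covariate = NA,
                                              reason = codings[[j]])
  }
  ok <- vapply(codings, inherits, logical(1), "snp_coding")
  rows <- list(); coefs <- list()
  add <- function(r) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test_kind = r$test_kind, snp1 = r$snp1, snp2 = r$snp2,
      covariate = r$covariate, n = r$n, df = r$df,
      statistic = r$statistic, p_value = r$p.value, model_p = r$model_p,
      stringsAsFactors = FALSE)
    if (keep_coefs) coefs[[length(coefs) + 1L]] <<- r$coefficients
  }
  note_skip <- function(kind, s1, s2, cv, e) {
    skip[[length(skip) + 1L]] <<- data.frame(test_kind = kind, snp1 = s1,
                                             snp2 = s2, covariate = cv,
                                             reason = conditionMessage(e))
  }
  if ("snp_main" %in% kinds) {
    for (j in which(ok)) {
      tryCatch(add(snp_main_test(residual_sets$default, codings[[j]], snps[j])),
               error = function(e) note_skip("snp_main", snps[j], NA, NA, e))
    }
  }
  if ("snp_covariate" %in% kinds) {
    for (cv in covariates) {
      res <- if (cv %in% adj_set) residual_sets[[cv]] else residual_sets$default
      if (is.null(res))
        stop("no residual set excluding adjustment covariate '", cv, "'")
      v <- cohort$covariates[[cv]]
      names(v) <- cohort$covariates$individual_id
      for (j in which(ok)) {
        tryCatch(add(snp_covariate_test(res, codings[[j]], v, snps[j], cv)),
                 error = function(e) note_skip("snp_covariate", snps[j], NA, cv, e))
      }
    }
  }
  if ("snp_snp" %in% kinds) {
    if (identical(pairs, "all")) {
      idx <- which(ok)
      pair_idx <- if (length(idx) >= 2L) t(utils::combn(idx, 2L)) else
        matrix(integer(0), 0, 2)
    } else {
      pair_idx <- as.matrix(pairs)
      if (is.character(pair_idx))
        pair_idx <- matrix(match(pair_idx, snps), ncol = 2)
      storage.mode(pair_idx) <- "integer"
    }
    for (r in seq_len(nrow(pair_idx))) {
      j1 <- pair_idx[r, 1]; j2 <- pair_idx[r, 2]
      if (!ok[j1] || !ok[j2]) {
        skip[[length(skip) + 1L]] <- data.frame(
          test_kind = "snp_snp", snp1 = snps[j1], snp2 = snps[j2],
          covariate = NA, reason = "monomorphic member")
        next
      }
      tryCatch(add(snp_snp_test(residual_sets$default, codings[[j1]],
                                codings[[j2]], snps[j1], snps[j2])),
               error = function(e) note_skip("snp_snp", snps[j1], snps[j2], NA, e))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test_kind = character(), snp1 = character(), snp2 = character(),
               covariate = character(), n = integer(), df = integer(),
               statistic = numeric(), p_value = numeric(), model_p = numeric())
  rownames(out) <- NULL
  if (keep_coefs) out$coefficients <- I(coefs)
  attr(out, "skips") <- if (length(skip)) do.call(rbind, skip) else NULL
  out
}
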