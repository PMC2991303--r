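# Multivariable modeling of screened SNP-SNP interactions: forward
# selection of interaction blocks, per-step variance accounting, and a
# mixed-model sensitivity check for familial correlation.

# Build the combined design for a list of interaction blocks.
# Each block contributes its two SNPs' main-effect dummies (a SNP's dummies
# enter at most once across blocks) and all pairwise dummy products.
# Complete cases are taken over the residuals and every involved SNP.
# Returns y, X (with intercept), and per-block lists of all / product-only
# column names newly added by that block.
build_model_design <- function(blocks, residuals, genotypes) {
  y <- if (inherits(residuals, "adjusted_trait")) residuals$residuals else residuals
  ids <- names(y)
  snps <- unique(unlist(lapply(blocks, function(b) c(b$snp1, b$snp2))))
  gsub_ <- genotypes[match(ids, rownames(genotypes)), snps, drop = FALSE]
  keep <- stats::complete.cases(gsub_)
  y <- y[keep]; gsub_ <- gsub_[keep, , drop = FALSE]
  codings <- lapply(snps, function(s) code_snp(gsub_[, s]))
  names(codings) <- snps
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  seen <- character(0)
  block_cols <- list(); block_prod_cols <- list()
  for (b in blocks) {
    added <- character(0)
    for (s in c(b$snp1, b$snp2)) {
      if (!s %in% seen) {
        d <- codings[[s]]$columns
        colnames(d) <- paste0(s, ".", colnames(d))
        X <- cbind(X, d)
        added <- c(added, colnames(d))
        seen <- c(seen, s)
      }
    }
    d1 <- codings[[b$snp1]]$columns; d2 <- codings[[b$snp2]]$columns
    prods <- matrix(0, length(y), ncol(d1) * ncol(d2))
    pn <- character(ncol(prods)); k <- 0L
    for (a in seq_len(ncol(d1))) for (bb in seq_len(ncol(d2))) {
      k <- k + 1L
      prods[, k] <- d1[, a] * d2[, bb]
      pn[k] <- paste0(b$snp1, ".", colnames(d1)[a], ":",
                      b$snp2, ".", colnames(d2)[bb])
    }
    colnames(prods) <- pn
    new_prods <- setdiff(pn, colnames(X))
    X <- cbind(X, prods[, new_prods, drop = FALSE])
    block_cols[[length(block_cols) + 1L]] <- c(added, new_prods)
    block_prod_cols[[length(block_prod_cols) + 1L]] <- new_prods
  }
  list(y = y, X = X, block_cols = block_cols,
       block_prod_cols = block_prod_cols, snps = snps)
}

#' Forward selection of screened SNP-SNP interactions
#'
#' Builds a multivariable model over interaction blocks (a SNP pair's
#' main-effect dummies plus all dummy products). The candidate pool is the
#' `pool_size` screened results with the smallest full-model p-values. The
#' first block is the candidate with the smallest full-model p-value; each
#' subsequent step adds the remaining candidate whose added block (new main
#' and interaction columns) yields the smallest partial F-test p-value
#' against the current model. Selection stops at `max_blocks` or when the
#' best added-block p-value exceeds `p_cap`.
#'
#' @param candidates data.frame of screened results (rows with `snp1`,
#'   `snp2`, `model_p`), typically `pass_all` rows of [apply_criteria()].
#' @param residuals `adjusted_trait` or named residual vector.
#' @param genotypes genotype matrix.
#' @param max_blocks maximum number of interaction blocks (default 4).
#' @param pool_size size of the candidate pool ranked by full-model p-value
#'   (default 10).
#' @param p_cap stop when the best added-block p-value exceeds this.
#' @return object of class `model_spec`: list with `blocks` (each `snp1`,
#'   `snp2`), `step_p` (added-block p-values, NA for the first), and
#'   `pool` (the candidate pool used). Empty candidates give an
#'   intercept-only spec with zero blocks.
#' @export
forward_select <- function(candidates, residuals, genotypes,
                           max_blocks = 4L, pool_size = 10L, p_cap = 0.05) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(structure(list(blocks = list(), step_p = numeric(0),
                          pool = NULL), class = "model_spec"))
  stopifnot(all(candidates$test_kind == "snp_snp"))
  pool <- candidates[order(candidates$model_p), , drop = FALSE]
  pool <- utils::head(pool, pool_size)
  blocks <- list(list(snp1 = pool$snp1[1], snp2 = pool$snp2[1]))
  step_p <- NA_real_
  remaining <- seq_len(nrow(pool))[-1]
  while (length(blocks) < max_blocks && length(remaining) > 0L) {
    best_p <- Inf; best_i <- NA_integer_
    for (i in remaining) {
      cand <- list(snp1 = pool$snp1[i], snp2 = pool$snp2[i])
      des <- build_model_design(c(blocks, list(cand)), residuals, genotypes)
      new_cols <- des$block_cols[[length(des$block_cols)]]
      X_red <- des$X[, setdiff(colnames(des$X), new_cols), drop = FALSE]
      pf_ <- partial_f(des$X, X_red, des$y)
      if (is.finite(pf_$p.value) && pf_$p.value < best_p) {
        best_p <- pf_$p.value; best_i <- i
      }
    }
    if (is.na(best_i) || best_p > p_cap) break
    blocks[[length(blocks) + 1L]] <- list(snp1 = pool$snp1[best_i],
                                          snp2 = pool$snp2[best_i])
    step_p <- c(step_p, best_p)
    remaining <- setdiff(remaining, best_i)
  }
  structure(list(blocks = blocks, step_p = step_p, pool = pool),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  if (length(x$blocks) == 0L) {
    cat("model_spec: intercept only (no blocks)\n")
    return(invisible(x))
  }
  cat("model_spec with", length(x$blocks), "interaction block(s):\n")
  for (i in seq_along(x$blocks))
    cat(sprintf("  %d. %s * %s  (added-block p = %s)\n", i,
                x$blocks[[i]]$snp1, x$blocks[[i]]$snp2,
                ifelse(is.na(x$step_p[i]), "-", format(x$step_p[i], digits = 3))))
  invisible(x)
}

#' Per-step summary of the forward-selected model
#'
#' For each prefix of the selected blocks reports the total number of model
#' terms (matching the design rank; shared SNP dummies are counted once),
#' in-sample R-squared and adjusted R-squared, the partial F-test p-value
#' and degrees of freedom of the newly added block, and the full-model
#' repeated k-fold CV R-squared.
#'
#' @param spec a [forward_select()] result.
#' @param residuals `adjusted_trait` or named residual vector.
#' @param genotypes genotype matrix.
#' @param config a [criteria_config()] supplying the CV layout and seed.
#' @return data.frame with one row per step.
#' @export
model_summary <- function(spec, residuals, genotypes,
                          config = criteria_config()) {
  if (length(spec$blocks) == 0L)
    return(data.frame(step = integer(0), interaction = character(0),
                      n_terms = integer(0), r2 = numeric(0),
                      adj_r2 = numeric(0), added_p = numeric(0),
                      added_df = integer(0), cv_r2 = numeric(0)))
  out <- vector("list", length(spec$blocks))
  for (k in seq_along(spec$blocks)) {
    des <- build_model_design(spec$blocks[seq_len(k)], residuals, genotypes)
    fit <- fit_ols(des$X, des$y)
    sst <- sum((des$y - mean(des$y))^2)
    r2 <- 1 - fit$sse / sst
    n <- length(des$y); pterms <- fit$rank
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - pterms)
    if (k == 1L) {
      added_p <- NA_real_; added_df <- NA_integer_
    } else {
      new_cols <- des$block_cols[[k]]
      X_red <- des$X[, setdiff(colnames(des$X), new_cols), drop = FALSE]
      pf_ <- partial_f(des$X, X_red, des$y)
      added_p <- pf_$p.value; added_df <- pf_$df1
    }
    cv <- cv_r2(des$y, des$X, config$cv_folds, config$cv_repeats,
                seed = config$seed)
    out[[k]] <- data.frame(
      step = k,
      interaction = paste(spec$blocks[[k]]$snp1, "*", spec$blocks[[k]]$snp2),
      n_terms = fit$rank, r2 = r2, adj_r2 = adj_r2,
      added_p = added_p, added_df = added_df, cv_r2 = as.numeric(cv),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mixed-model sensitivity check for familial correlation
#'
#' Refits the multivariable model with a sibship random intercept
#' (REML via lme4) and tests each block's interaction terms jointly with a
#' Satterthwaite-approximated F-test, alongside the fixed-model partial
#' F-test of the same terms. Reports per-block p-value pairs, the Pearson
#' correlation between the fixed and mixed p-value vectors, and the
#' estimated random-intercept standard deviation.
#'
#' @param spec a [forward_select()] result with at least one block.
#' @param residuals `adjusted_trait` or named residual vector.
#' @param genotypes genotype matrix.
#' @param pedigree data.frame mapping `individual_id` to `sibship_id`.
#' @return data.frame with `block`, `interaction`, `fixed_p`, `mixed_p`;
#'   attributes `p_correlation`, `family_sd_hat` and `convergence`.
#' @export
mixed_check <- function(spec, residuals, genotypes, pedigree) {
  if (length(spec$blocks) == 0L) stop("model_spec has no blocks")
  des <- build_model_design(spec$blocks, residuals, genotypes)
  # drop aliased columns so fixed and mixed designs match term-for-term
  fit0 <- fit_ols(des$X, des$y)
  keep_cols <- colnames(des$X)[!is.na(fit0$coefficients)]
  X <- des$X[, keep_cols, drop = FALSE]
  sib <- pedigree$sibship_id[match(names(des$y), pedigree$individual_id)]
  if (anyNA(sib)) stop("sibship map does not cover all modeled individuals")
  dat <- as.data.frame(X[, -1, drop = FALSE])
  safe <- paste0("V", seq_len(ncol(dat)))
  col_map <- stats::setNames(safe, colnames(dat))
  names(dat) <- safe
  dat$.y <- des$y
  dat$.sib <- factor(sib)
  form <- stats::as.formula(paste(".y ~", paste(safe, collapse = " + "),
                                  "+ (1 | .sib)"))
  mm <- tryCatch(
    lmerTest::lmer(form, data = dat,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore")),
    error = function(e) e)
  converged <- inherits(mm, "merMod")
  rows <- vector("list", length(spec$blocks))
  for (k in seq_along(spec$blocks)) {
    prod_cols <- intersect(des$block_prod_cols[[k]], keep_cols)
    if (length(prod_cols) == 0L) {
      rows[[k]] <- data.frame(block = k,
                              interaction = paste(spec$blocks[[k]]$snp1, "*",
                                                  spec$blocks[[k]]$snp2),
                              fixed_p = NA_real_, mixed_p = NA_real_)
      next
    }
    X_red <- X[, setdiff(colnames(X), prod_cols), drop = FALSE]
    pf_ <- partial_f(X, X_red, des$y)
    mixed_p <- NA_real_
    if (converged) {
      cf_names <- names(lme4::fixef(mm))
      L <- matrix(0, length(prod_cols), length(cf_names))
      for (j in seq_along(prod_cols)) {
        pos <- match(col_map[[prod_cols[j]]], cf_names)
        L[j, pos] <- 1
      }
      ct <- tryCatch(lmerTest::contest(mm, L, joint = TRUE),
                     error = function(e) NULL)
      if (!is.null(ct)) mixed_p <- ct[["Pr(>F)"]]
    }
    rows[[k]] <- data.frame(block = k,
                            interaction = paste(spec$blocks[[k]]$snp1, "*",
                                                spec$blocks[[k]]$snp2),
                            fixed_p = pf_$p.value, mixed_p = mixed_p)
  }
  out <- do.call(rbind, rows)
  cc <- stats::complete.cases(out[, c("fixed_p", "mixed_p")])
  attr(out, "p_correlation") <- if (sum(cc) >= 2L)
    stats::cor(out$fixed_p[cc], out$mixed_p[cc]) else NA_real_
  attr(out, "family_sd_hat") <- if (converged)
    sqrt(unname(lme4::VarCorr(mm)$.sib[1])) else NA_real_
  attr(out, "convergence") <- if (converged) "ok" else conditionMessage(mm)
  out
}
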