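# Internal least-squares helpers shared by the scan, screen and model stages.
# Rank handling is explicit (QR with a fixed tolerance) because interaction
# designs are routinely rank-deficient when joint genotype classes are absent.

OLS_TOL <- 1e-8

# QR fit of y on X; aliased columns get NA coefficients.
# Returns rank, residuals, SSE, coefficient table with standard errors.
fit_ols <- function(X, y, tol = OLS_TOL) {
  X <- as.matrix(X)
  qx <- qr(X, tol = tol)
  rank <- qx$rank
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  sse <- sum(res^2)
  n <- length(y)
  df_resid <- n - rank
  sigma2 <- if (df_resid > 0) sse / df_resid else NA_real_
  se <- rep(NA_real_, ncol(X))
  if (rank > 0 && df_resid > 0) {
    used <- qx$pivot[seq_len(rank)]
    R <- qr.R(qx)[seq_len(rank), seq_len(rank), drop = FALSE]
    xtx_inv <- chol2inv(R)
    se[used] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  }
  names(coef) <- colnames(X)
  names(se) <- colnames(X)
  list(rank = rank, coefficients = coef, se = se, residuals = res,
       fitted = y - res, sse = sse, n = n, df_resid = df_resid)
}

# Partial F-test of nested least-squares models (the finite-sample-exact
# monotone transform of the Gaussian likelihood-ratio test).
# df1 = rank(full) - rank(reduced); df2 = n - rank(full).
partial_f <- function(X_full, X_reduced, y, tol = OLS_TOL) {
  ff <- fit_ols(X_full, y, tol)
  fr <- fit_ols(X_reduced, y, tol)
  df1 <- ff$rank - fr$rank
  df2 <- ff$n - ff$rank
  if (df1 <= 0 || df2 <= 0) {
    return(list(statistic = NA_real_, df1 = df1, df2 = df2,
                p.value = NA_real_, fit_full = ff, fit_reduced = fr))
  }
  f <- ((fr$sse - ff$sse) / df1) / (ff$sse / df2)
  f <- max(f, 0)
  list(statistic = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE),
       fit_full = ff, fit_reduced = fr)
}

# Predict from a fit_ols result treating aliased (NA) coefficients as zero,
# i.e. intercept-plus-available-terms prediction.
predict_ols <- function(fit, X_new) {
  cf <- fit$coefficients
  aliased <- is.na(cf)
  cf[aliased] <- 0
  drop(as.matrix(X_new) %*% cf)
}

# Omnibus F p-value of a fitted model against the intercept-only model,
# computed from the fit itself (no refit).
omnibus_p <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  df1 <- fit$rank - 1L
  df2 <- fit$n - fit$rank
  if (df1 < 1L || df2 < 1L) return(NA_real_)
  f <- ((sst - fit$sse) / df1) / (fit$sse / df2)
  stats::pf(max(f, 0), df1, df2, lower.tail = FALSE)
}

coef_table <- function(fit) {
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se),
             stringsAsFactors = FALSE)
}
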