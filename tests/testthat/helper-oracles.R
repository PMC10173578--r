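# Independent oracles and fixture builders used across the suite. The
# oracles deliberately use different computational routes (dense grid
# search, explicit normal equations via solve(), exhaustive greedy
# re-implementation) than the package's estimators.

toy_table <- function(df, id, type = "continuous", ...) {
  defaults <- data.frame(chr = "1", pos = seq_len(nrow(df)) * 2.1e7,
                         eaf = 0.3, n = 1e5, stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  summaryStats(df, trait_id = id, trait_type = type, ...)
}

# Exposure table with n strong SNPs at fixed betas.
toy_exposure <- function(beta, se = 0.005, snp = sprintf("rs%03d", seq_along(beta))) {
  toy_table(data.frame(snp = snp, ea = "A", oa = "G", beta = beta, se = se,
                       pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
                       stringsAsFactors = FALSE), "expo")
}

# Weighted least squares (with intercept when icpt=TRUE) by explicit
# normal equations through solve(); the unscaled coefficient SEs.
wls_oracle <- function(x, y, w, icpt = FALSE) {
  X <- if (icpt) cbind(1, x) else cbind(x)
  A <- solve(t(X) %*% (X * w))
  coef <- drop(A %*% t(X) %*% (y * w))
  list(coef = coef, se = sqrt(diag(A)),
       rss = sum(w * (y - drop(X %*% coef))^2))
}

# Multi-exposure weighted least squares (zero intercept) by explicit
# normal equations.
wls_oracle_mv <- function(X, y, w) {
  A <- solve(t(X) %*% (X * w))
  coef <- drop(A %*% t(X) %*% (y * w))
  list(coef = coef, se = sqrt(diag(A)),
       rss = sum(w * (y - drop(X %*% coef))^2))
}

# Dense grid search of the ML profile likelihood.
ml_grid_oracle <- function(x, y, sx, sy, lo, hi, step = 1e-5) {
  grid <- seq(lo, hi, by = step)
  nll <- vapply(grid, function(th)
    0.5 * sum((y - th * x)^2 / (sy^2 + th^2 * sx^2)), numeric(1))
  grid[which.min(nll)]
}

# Dense grid search for the sign change of the RAPS l2 profile score.
raps_grid_oracle <- function(x, y, sx, sy, lo, hi, step = 1e-5) {
  score <- function(th) {
    v <- sy^2 + th^2 * sx^2
    t <- (y - th * x) / sqrt(v)
    sum(t * (x / sqrt(v) + t * th * sx^2 / v))
  }
  grid <- seq(lo, hi, by = step)
  s <- vapply(grid, score, numeric(1))
  i <- which(diff(sign(s)) != 0)[1]
  mean(grid[c(i, i + 1)])
}

# Greedy clumping re-implemented independently: explicit loop over the
# canonically sorted list, checking every previously kept SNP.
clump_oracle <- function(records, ld, params) {
  rec <- records[order(records$pval, records$pos, records$snp), ]
  kept <- character()
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    for (k in kept) {
      krow <- rec[rec$snp == k, ]
      same_chr <- krow$chr == rec$chr[i]
      close <- abs(krow$pos - rec$pos[i]) <= params$window_bp
      r2 <- if (is.null(ld)) 1 else ld[k, rec$snp[i]]
      if (same_chr && close && r2 >= params$r2_threshold) ok <- FALSE
    }
    if (ok) kept <- c(kept, rec$snp[i])
  }
  kept
}

# Simple homogeneous null study on the summary scale: fixed exposure
# betas (no measurement error), outcome = theta * x + N(0, sy).
null_set <- function(n, theta = 0.2, seed = NULL, sy = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- runif(n, 0.05, 0.2)
  sy <- sy %||% runif(n, 0.008, 0.02)
  y <- theta * x + rnorm(n, 0, sy)
  instrumentSet(x, rep(1e-6, n), y, sy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
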