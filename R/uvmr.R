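## Univariable two-sample MR estimators. All effects are computed and
## stored on the linear scale of the outcome (log-odds when binary); the
## odds-ratio scale is presentation only (orScale()).

.mr_result <- function(method, beta, se, pval, n_snp, set,
                       ci = beta + c(-1, 1) * stats::qnorm(0.975) * se,
                       extras = list()) {
  new("MRResult", method = method,
      exposure = set@exposureId, outcome = set@outcomeId,
      beta = beta, se = se, ciLow = ci[1], ciHigh = ci[2],
      pval = pval, nSnp = as.integer(n_snp),
      binaryOutcome = identical(set@outcomeType, "binary"),
      extras = extras)
}

.xysw <- function(set) {
  p <- set@pairs
  list(x = p$beta_exp, y = p$beta_out, sx = p$se_exp, sy = p$se_out,
       w = 1 / p$se_out^2, n = nrow(p))
}

#' Wald ratio estimate from a single instrument
#'
#' beta = beta_out / beta_exp with the first-order (delta-method) standard
#' error se_out / |beta_exp|, normal CI and p-value.
#'
#' @param set an [InstrumentSet-class] or [HarmonizedSet-class] with
#'   exactly one SNP, or `NULL` when `beta_exp` etc. are given directly.
#' @param beta_exp,se_exp,beta_out,se_out scalar associations (alternative
#'   interface to `set`).
#' @return an [MRResult-class]
#' @export
waldRatio <- function(set = NULL, beta_exp, se_exp, beta_out, se_out) {
  if (!is.null(set)) {
    .assert(nSnps(set) == 1L, "waldRatio needs exactly one SNP")
    d <- .xysw(set)
    beta_exp <- d$x; se_exp <- d$sx; beta_out <- d$y; se_out <- d$sy
  } else {
    set <- .instrument_set(beta_exp, se_exp, beta_out, se_out)
  }
  if (beta_exp == 0)
    stop("undefined ratio: exposure effect is zero", call. = FALSE)
  beta <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  .mr_result("Wald ratio", beta, se, .pval_z(beta / se), 1L, set)
}

## Closed-form IVW pieces shared with the sensitivity module so that the
## Q used for multiplicative-random scaling and the reported Cochran Q are
## provably the same quantity.
.ivw_fit <- function(x, y, w) {
  sxx <- sum(w * x^2)
  beta <- sum(w * x * y) / sxx
  Q <- sum(w * (y - beta * x)^2)
  list(beta = beta, se_fixed = 1 / sqrt(sxx), Q = Q)
}

#' Inverse-variance-weighted estimate
#'
#' Zero-intercept weighted regression of outcome on exposure associations
#' with weights `se_out^-2`. Under the default multiplicative random-effects
#' model the fixed-effect SE is inflated by `max(1, sqrt(Q / (n - 1)))`
#' where Q is Cochran's Q at the estimate; the scaling never deflates.
#' With a single SNP the estimate reduces to [waldRatio()] exactly.
#'
#' @param set an [InstrumentSet-class] (or [HarmonizedSet-class])
#' @param model `"multiplicative_random"` (default) or `"fixed"`
#' @return an [MRResult-class]; `extras` carries `Q`, `Q_df` and the
#'   applied scale factor.
#' @export
mrIVW <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  d <- .xysw(set)
  if (d$n == 1L) return(waldRatio(set))
  if (all(d$x == 0)) stop("all exposure effects are zero", call. = FALSE)
  fit <- .ivw_fit(d$x, d$y, d$w)
  scale <- if (model == "multiplicative_random")
    max(1, sqrt(fit$Q / (d$n - 1))) else 1
  se <- fit$se_fixed * scale
  .mr_result(paste0("IVW (", sub("_", " ", model), ")"),
             fit$beta, se, .pval_z(fit$beta / se), d$n, set,
             extras = list(Q = fit$Q, Q_df = d$n - 1, scale = scale,
                           model = model))
}

## Weighted least squares with intercept via normal equations; returns
## coefficients, their unscaled SEs, and the weighted RSS.
.wls_intercept <- function(x, y, w) {
  X <- cbind(1, x)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  inv <- solve(XtWX)
  coefs <- unname(drop(inv %*% (XtW %*% y)))
  rss <- sum(w * (y - drop(X %*% coefs))^2)
  list(coef = coefs, se_unscaled = unname(sqrt(diag(inv))), rss = rss)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations with a free
#' intercept (weights `se_out^-2`), after orienting every pair so the
#' exposure effect is non-negative (required for the intercept to be
#' interpretable as average directional pleiotropy). Slope and intercept
#' inference uses the estimated residual scale and the t distribution
#' with `n_snp - 2` df, i.e. standard weighted-regression inference,
#' which keeps the intercept test exactly calibrated under the null.
#'
#' @param set an [InstrumentSet-class] with at least 3 SNPs
#' @return an [MRResult-class]; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_pval`, `Q` (Egger framework) and `Q_df`.
#' @export
mrEgger <- function(set) {
  d <- .xysw(set)
  if (d$n < 3L) stop("MR-Egger needs at least 3 SNPs", call. = FALSE)
  flip <- sign(d$x)
  flip[flip == 0] <- 1
  x <- d$x * flip
  y <- d$y * flip
  fit <- .wls_intercept(x, y, d$w)
  df <- d$n - 2
  scale <- sqrt(fit$rss / df)
  se <- fit$se_unscaled * scale
  slope <- fit$coef[2]; icpt <- fit$coef[1]
  tstat <- function(b, s) if (s > 0) b / s else if (b == 0) 0 else
    Inf * sign(b)
  ci <- slope + c(-1, 1) * stats::qt(0.975, df) * se[2]
  .mr_result("MR-Egger", slope, se[2], .pval_t(tstat(slope, se[2]), df),
             d$n, set, ci = ci,
             extras = list(intercept = icpt, intercept_se = se[1],
                           intercept_pval = .pval_t(tstat(icpt, se[1]), df),
                           Q = fit$rss, Q_df = df, scale = scale))
}

## Profile log-likelihood of the bivariate normal measurement model with
## the per-SNP true exposure effects profiled out:
##   -2 logLik(theta) = sum (y - theta x)^2 / (sy^2 + theta^2 sx^2) + const
.ml_negloglik <- function(theta, x, y, sx, sy)
  0.5 * sum((y - theta * x)^2 / (sy^2 + theta^2 * sx^2))

#' Maximum-likelihood estimate
#'
#' Models each SNP's observed exposure and outcome associations as
#' independent normals centred at (gamma_j, theta * gamma_j) with known
#' SEs, profiles out the gamma_j, and maximizes the resulting profile
#' likelihood in theta. The SE comes from the observed information
#' (numerical second derivative at the optimum); CI and p are normal.
#'
#' @param set an [InstrumentSet-class] with at least 2 SNPs
#' @return an [MRResult-class]
#' @export
mrMaxLik <- function(set) {
  d <- .xysw(set)
  if (d$n < 2L) stop("maximum likelihood needs at least 2 SNPs",
                     call. = FALSE)
  ivw <- .ivw_fit(d$x, d$y, d$w)
  width <- max(10 * ivw$se_fixed * max(1, sqrt(ivw$Q / (d$n - 1))), 1)
  opt <- stats::optimize(.ml_negloglik, ivw$beta + c(-1, 1) * width,
                         x = d$x, y = d$y, sx = d$sx, sy = d$sy,
                         tol = 1e-10)
  theta <- opt$minimum
  h <- max(1e-5, abs(theta) * 1e-5)
  info <- (.ml_negloglik(theta + h, d$x, d$y, d$sx, d$sy) -
             2 * opt$objective +
             .ml_negloglik(theta - h, d$x, d$y, d$sx, d$sy)) / h^2
  if (!is.finite(info) || info <= 0)
    stop("maximum-likelihood information not positive at the optimum",
         call. = FALSE)
  se <- 1 / sqrt(info)
  .mr_result("Maximum likelihood", theta, se, .pval_z(theta / se),
             d$n, set, extras = list(negloglik = opt$objective))
}

.huber_psi <- function(t, k) pmin(pmax(t, -k), k)

## Standardized residuals and the dispersion target E[psi(Z) Z] for Z ~
## N(0,1): 1 for the identity score, 2*Phi(k) - 1 for the Huber score.
.raps_t <- function(theta, d, tau2) {
  v <- d$sy^2 + theta^2 * d$sx^2 + tau2
  list(t = (d$y - theta * d$x) / sqrt(v), v = v)
}

.raps_score <- function(theta, d, tau2, psi) {
  r <- .raps_t(theta, d, tau2)
  ## dt/dtheta = -x/sqrt(v) - t * theta * sx^2 / v; score = -sum psi(t) dt/dtheta
  sum(psi(r$t) * (d$x / sqrt(r$v) + r$t * theta * d$sx^2 / r$v))
}

#' Robust adjusted profile score estimate
#'
#' Solves the profile-score estimating equation in theta built on the
#' standardized residuals t_j = (beta_out - theta beta_exp) /
#' sqrt(se_out^2 + theta^2 se_exp^2 + tau^2), with the identity score
#' (`loss = "l2"`) or a Huber score (constant `k_huber`, default 1.345).
#' With `overdispersion = TRUE`, tau^2 >= 0 is estimated jointly so the
#' average of `psi(t) t` matches its standard-normal expectation. The
#' standard error is the sandwich estimate; the root is bracketed around
#' the IVW estimate and the bracket widened once before failing.
#'
#' @param set an [InstrumentSet-class] with at least 3 SNPs
#' @param loss `"l2"` or `"huber"`
#' @param overdispersion estimate the pleiotropy variance tau^2?
#' @param k_huber Huber threshold on the standardized-residual scale.
#' @return an [MRResult-class]; `extras` carries `tau2`.
#' @export
mrRAPS <- function(set, loss = c("l2", "huber"), overdispersion = FALSE,
                   k_huber = 1.345) {
  loss <- match.arg(loss)
  d <- .xysw(set)
  if (d$n < 3L) stop("RAPS needs at least 3 SNPs", call. = FALSE)
  psi <- if (loss == "l2") identity else function(t) .huber_psi(t, k_huber)
  delta <- if (loss == "l2") 1 else 2 * stats::pnorm(k_huber) - 1

  ivw <- .ivw_fit(d$x, d$y, d$w)
  width0 <- max(10 * ivw$se_fixed * max(1, sqrt(ivw$Q / (d$n - 1))),
                0.5 * abs(ivw$beta) + 0.1)

  solve_theta <- function(tau2) {
    width <- width0
    for (attempt in 1:2) {
      lo <- ivw$beta - width; hi <- ivw$beta + width
      flo <- .raps_score(lo, d, tau2, psi)
      fhi <- .raps_score(hi, d, tau2, psi)
      if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi))
        return(stats::uniroot(.raps_score, c(lo, hi), d = d, tau2 = tau2,
                              psi = psi, tol = 1e-10)$root)
      width <- width * 4
    }
    stop("RAPS score has no sign change in the widened bracket",
         call. = FALSE)
  }

  tau2 <- 0
  theta <- solve_theta(tau2)
  if (overdispersion) {
    for (iter in 1:100) {
      disp <- function(t2) {
        r <- .raps_t(theta, d, t2)
        mean(psi(r$t) * r$t) - delta
      }
      tau2_new <- if (disp(0) <= 0) 0 else {
        hi <- max(d$sy^2)
        while (disp(hi) > 0) hi <- hi * 4
        stats::uniroot(disp, c(0, hi), tol = 1e-12)$root
      }
      theta_new <- solve_theta(tau2_new)
      done <- abs(theta_new - theta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
      theta <- theta_new; tau2 <- tau2_new
      if (done) break
    }
  }

  ## Sandwich variance: A = dS/dtheta (numeric), B = sum of squared
  ## per-SNP score contributions.
  r <- .raps_t(theta, d, tau2)
  contrib <- psi(r$t) * (d$x / sqrt(r$v) + r$t * theta * d$sx^2 / r$v)
  h <- max(1e-6, abs(theta) * 1e-6)
  A <- (.raps_score(theta + h, d, tau2, psi) -
          .raps_score(theta - h, d, tau2, psi)) / (2 * h)
  B <- sum(contrib^2)
  se <- sqrt(B / A^2)
  .mr_result(paste0("MR-RAPS (", loss,
                    if (overdispersion) ", overdispersed" else "", ")"),
             theta, se, .pval_z(theta / se), d$n, set,
             extras = list(tau2 = tau2, loss = loss))
}

#' Run the standard estimator panel on one instrument set
#'
#' IVW (primary), MR-Egger, maximum likelihood and MR-RAPS, in the
#' configuration used throughout the package's pipeline.
#'
#' @param set an [InstrumentSet-class]
#' @param raps_overdispersion passed to [mrRAPS()]
#' @return named list of [MRResult-class] objects
#' @export
mrAllMethods <- function(set, raps_overdispersion = TRUE) {
  out <- list(ivw = mrIVW(set))
  if (nSnps(set) >= 3L) {
    out$egger <- mrEgger(set)
    out$raps <- mrRAPS(set, overdispersion = raps_overdispersion)
  }
  if (nSnps(set) >= 2L) out$max_lik <- mrMaxLik(set)
  out
}

#' Tidy table of MR results
#'
#' One row per result, mirroring a forest-plot table: method, number of
#' SNPs, log-scale estimate with CI and p, and the OR scale when the
#' outcome is binary.
#'
#' @param results a list of [MRResult-class] objects (possibly nested one
#'   level, e.g. the output of [mrAllMethods()] across contrasts).
#' @return data.frame
#' @export
mrTable <- function(results) {
  if (is(results, "MRResult")) results <- list(results)
  flat <- list()
  for (r in results)
    if (is(r, "MRResult")) flat <- c(flat, list(r)) else flat <- c(flat, r)
  do.call(rbind, lapply(flat, function(r) {
    df <- data.frame(exposure = r@exposure, outcome = r@outcome,
                     method = r@method, n_snp = r@nSnp, beta = r@beta,
                     se = r@se, ci_low = r@ciLow, ci_high = r@ciHigh,
                     pval = r@pval, stringsAsFactors = FALSE)
    if (r@binaryOutcome) {
      or <- orScale(r)
      df$or <- or[["or"]]; df$or_low <- or[["ci_low"]]
      df$or_high <- or[["ci_high"]]
    } else {
      df$or <- df$or_low <- df$or_high <- NA_real_
    }
    df
  }))
}
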