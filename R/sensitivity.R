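## Heterogeneity, pleiotropy, outlier, directionality, influence and power
## diagnostics for a fitted instrument set.

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_j (beta_out_j - fitted_j)^2 with weights `se_out^-2`, where the
#' fitted values come from the zero-intercept IVW fit (df = n - 1) or the
#' free-intercept Egger fit (df = n - 2). The IVW-framework Q is computed
#' by the same code path as the residual sum used for the
#' multiplicative-random SE scaling in [mrIVW()], so the two are identical
#' by construction. The p-value is the chi-square upper tail.
#'
#' @param set an [InstrumentSet-class]
#' @param framework `"IVW"` (default) or `"Egger"`
#' @return a [QResult-class]
#' @export
cochranQ <- function(set, framework = c("IVW", "Egger")) {
  framework <- match.arg(framework)
  d <- .xysw(set)
  if (framework == "IVW") {
    if (d$n < 2L) stop("Q (IVW) needs at least 2 SNPs", call. = FALSE)
    Q <- .ivw_fit(d$x, d$y, d$w)$Q
    df <- d$n - 1
  } else {
    if (d$n < 3L) stop("Q (Egger) needs at least 3 SNPs", call. = FALSE)
    flip <- sign(d$x); flip[flip == 0] <- 1
    Q <- .wls_intercept(d$x * flip, d$y * flip, d$w)$rss
    df <- d$n - 2
  }
  new("QResult", Q = Q, df = as.numeric(df),
      pval = stats::pchisq(Q, df, lower.tail = FALSE),
      framework = framework)
}

#' Leave-one-out influence analysis
#'
#' Refits the IVW estimator with each instrument omitted in turn and flags
#' omissions whose refit CI excludes the full-set point estimate or whose
#' refit flips the sign of the effect.
#'
#' @param set an [InstrumentSet-class] with at least 3 SNPs
#' @param model IVW model, as in [mrIVW()]
#' @return data.frame with one row per omitted SNP: the refit estimate,
#'   SE, CI, p-value and an `influential` flag. The full-set estimate is
#'   attached as attribute `"full"`.
#' @export
leaveOneOut <- function(set, model = "multiplicative_random") {
  .assert(nSnps(set) >= 3L, "leave-one-out needs at least 3 SNPs")
  full <- mrIVW(set, model = model)
  p <- set@pairs
  rows <- lapply(seq_len(nrow(p)), function(j) {
    sub <- set
    sub@pairs <- p[-j, , drop = FALSE]
    sub@fstat <- set@fstat[-j]
    r <- mrIVW(sub, model = model)
    data.frame(snp = p$snp[j], beta = r@beta, se = r@se,
               ci_low = r@ciLow, ci_high = r@ciHigh, pval = r@pval,
               influential = (full@beta < r@ciLow | full@beta > r@ciHigh |
                                sign(r@beta) * sign(full@beta) < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

#' Residual-sum-of-squares outlier analysis (MR-PRESSO style)
#'
#' The observed global statistic is the weighted leave-one-out residual sum
#' of squares `sum_j w_j (beta_out_j - theta_hat_{-j} beta_exp_j)^2`, with
#' `theta_hat_{-j}` the IVW estimate excluding SNP j. Its null distribution
#' is generated by parametric simulation: `n_sim` draws of
#' `beta_exp* ~ N(beta_exp, se_exp)` and
#' `beta_out* ~ N(theta_hat_{-j} beta_exp, se_out)` from a seeded
#' generator. The global p-value is the empirical upper-tail proportion;
#' per-SNP outlier p-values compare each SNP's observed residual to its
#' simulated residual distribution with Bonferroni adjustment, and are only
#' acted on when the global test is significant. The distortion p-value
#' compares the observed raw-vs-corrected shift to shifts obtained by
#' removing random subsets of the same size. Identical seeds and inputs
#' give bit-identical results.
#'
#' @param set an [InstrumentSet-class] with at least 4 SNPs
#' @param n_sim number of parametric simulations (>= 100; default 1000)
#' @param seed mandatory RNG seed
#' @param alpha_outlier per-SNP significance level applied to the
#'   Bonferroni-adjusted empirical p-values (default 0.05)
#' @param alpha_global significance level for the global test (default 0.05)
#' @return a [PressoResult-class]
#' @export
mrPresso <- function(set, n_sim = 1000L, seed, alpha_outlier = 0.05,
                     alpha_global = 0.05) {
  .assert(nSnps(set) >= 4L, "PRESSO needs at least 4 SNPs")
  .assert(n_sim >= 100L, "n_sim must be at least 100")
  .assert(!missing(seed), "seed is mandatory for mrPresso")
  d <- .xysw(set)
  n <- d$n

  loo_theta <- function(x, y, w) {
    sxy <- sum(w * x * y); sxx <- sum(w * x^2)
    (sxy - w * x * y) / (sxx - w * x^2)
  }
  th_loo <- loo_theta(d$x, d$y, d$w)
  res_obs <- d$w * (d$y - th_loo * d$x)^2
  rss_obs <- sum(res_obs)

  with_seed(seed, {
    ## n_sim x n matrices; rows are simulated studies.
    Xs <- matrix(rep(d$x, each = n_sim), n_sim) +
      matrix(stats::rnorm(n_sim * n), n_sim) *
        matrix(rep(d$sx, each = n_sim), n_sim)
    Ys <- matrix(rep(th_loo * d$x, each = n_sim), n_sim) +
      matrix(stats::rnorm(n_sim * n), n_sim) *
        matrix(rep(d$sy, each = n_sim), n_sim)
    W <- matrix(rep(d$w, each = n_sim), n_sim)
    sxy <- rowSums(W * Xs * Ys); sxx <- rowSums(W * Xs^2)
    Th <- (sxy - W * Xs * Ys) / (sxx - W * Xs^2)
    Res <- W * (Ys - Th * Xs)^2
    rss_sim <- rowSums(Res)
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
    psnp <- vapply(seq_len(n), function(j)
      (1 + sum(Res[, j] >= res_obs[j])) / (1 + n_sim), numeric(1))
    psnp_adj <- pmin(1, psnp * n)

    raw <- mrIVW(set)
    outliers <- integer()
    distortion_pval <- NA_real_
    corrected <- raw
    if (global_pval < alpha_global)
      outliers <- which(psnp_adj < alpha_outlier)
    if (length(outliers) && length(outliers) < n - 1L) {
      sub <- set
      sub@pairs <- set@pairs[-outliers, , drop = FALSE]
      sub@fstat <- set@fstat[-outliers]
      corrected <- mrIVW(sub)
      d_obs <- corrected@beta - raw@beta
      d_null <- vapply(seq_len(n_sim), function(b) {
        drop_idx <- sample.int(n, length(outliers))
        .ivw_fit(d$x[-drop_idx], d$y[-drop_idx],
                 d$w[-drop_idx])$beta - raw@beta
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
    }
    new("PressoResult", globalRSS = rss_obs, globalPval = global_pval,
        outlierIndices = as.integer(outliers),
        outlierSnps = set@pairs$snp[outliers],
        outlierPvals = psnp_adj[outliers],
        distortionPval = distortion_pval,
        betaRaw = raw, betaCorrected = corrected,
        nSim = as.integer(n_sim), seed = as.integer(seed))
  })
}

## Per-SNP variance explained from the squared-correlation approximation
## r2 = z^2 / (z^2 + n); binary traits use the effective sample size
## n_eff = 4 / (1/ncase + 1/ncontrol).
.r2_from_z <- function(beta, se, n, trait_type, ncase = NULL,
                       ncontrol = NULL) {
  z <- beta / se
  neff <- if (trait_type == "binary") {
    .assert(!is.null(ncase) && !is.null(ncontrol),
            "binary trait needs ncase and ncontrol for Steiger r2")
    4 / (1 / ncase + 1 / ncontrol)
  } else n
  z^2 / (z^2 + neff)
}

#' Steiger directionality test
#'
#' Compares the total instrument variance explained in the exposure versus
#' the outcome. Per-SNP variance explained uses r2 = z^2/(z^2 + n) with
#' z = beta/se; binary traits substitute the effective sample size
#' 4/(1/ncase + 1/ncontrol). The p-value is the two-sided normal test on
#' the difference of Fisher-transformed |r| across the two independent
#' samples. The causal direction is confirmed when the instruments explain
#' strictly more variance in the exposure.
#'
#' @param set an [InstrumentSet-class]
#' @param n_exp,n_out GWAS sample sizes for exposure and outcome.
#' @param exposure_type,outcome_type trait types; default taken from the set.
#' @param ncase_exp,ncontrol_exp,ncase_out,ncontrol_out case/control counts,
#'   required for binary traits.
#' @return a [SteigerResult-class]
#' @export
mrSteiger <- function(set, n_exp, n_out,
                      exposure_type = set@exposureType,
                      outcome_type = set@outcomeType,
                      ncase_exp = NULL, ncontrol_exp = NULL,
                      ncase_out = NULL, ncontrol_out = NULL) {
  .assert(n_exp > 0 && n_out > 0, "sample sizes must be positive")
  p <- set@pairs
  r2x <- sum(.r2_from_z(p$beta_exp, p$se_exp, n_exp, exposure_type,
                        ncase_exp, ncontrol_exp))
  r2y <- sum(.r2_from_z(p$beta_out, p$se_out, n_out, outcome_type,
                        ncase_out, ncontrol_out))
  r2x <- min(r2x, 1); r2y <- min(r2y, 1)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  new("SteigerResult", r2Exposure = r2x, r2Outcome = r2y,
      directionCorrect = r2x > r2y, pval = .pval_z(z))
}

#' Analytic power for MR with a binary outcome
#'
#' Two-sided power of the IVW test at level `alpha` under the linearized
#' logistic approximation, where the estimate's standard error is
#' `1 / sqrt(n K (1-K) r2)` on the log-odds scale: the non-centrality is
#' `ln(OR) * sqrt(n K (1-K) r2)`. At `true_or = 1` the power equals
#' `alpha` exactly, and it increases to 1 with n, r2 and |ln OR|. The
#' formula is validated in the package tests against a Monte-Carlo oracle
#' that simulates summary statistics and runs the IVW test.
#'
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction case fraction K in (0, 1).
#' @param r2_instruments variance in the exposure explained by the
#'   instruments, in (0, 1).
#' @param true_or assumed true odds ratio per exposure unit.
#' @param alpha type-I error rate (default 0.05).
#' @return power in \[0, 1\]
#' @export
powerBinary <- function(n_outcome, case_fraction, r2_instruments, true_or,
                        alpha = 0.05) {
  .assert(case_fraction > 0 && case_fraction < 1,
          "case_fraction must be in (0,1)")
  .assert(r2_instruments > 0 && r2_instruments < 1,
          "r2_instruments must be in (0,1)")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  .assert(n_outcome > 0 && true_or > 0, "n_outcome and true_or must be > 0")
  ncp <- log(true_or) *
    sqrt(n_outcome * case_fraction * (1 - case_fraction) * r2_instruments)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Consolidated diagnostics for one exposure-outcome contrast
#'
#' The column set of a forest-plot annotation row: Q and its p in both
#' frameworks, the Egger intercept and its p, the Steiger p and direction,
#' mean instrument F, and (for binary outcomes with known design) power.
#'
#' @param set an [InstrumentSet-class]
#' @param n_exp,n_out sample sizes for [mrSteiger()] (optional; Steiger
#'   columns are NA when absent).
#' @param presso_seed seed for [mrPresso()]; PRESSO columns are NA when
#'   absent or when fewer than 4 SNPs.
#' @param n_sim PRESSO simulation count.
#' @param power_args optional list with `case_fraction`, `true_or` (and
#'   optionally `alpha`) for [powerBinary()]; `r2_instruments` is computed
#'   from the set and `n_exp`.
#' @param ... further arguments passed to [mrSteiger()] (case/control
#'   counts for binary traits).
#' @return one-row data.frame of diagnostics
#' @export
sensitivitySuite <- function(set, n_exp = NULL, n_out = NULL,
                             presso_seed = NULL, n_sim = 1000L,
                             power_args = NULL, ...) {
  n <- nSnps(set)
  q_ivw <- cochranQ(set, "IVW")
  egg <- if (n >= 3L) mrEgger(set) else NULL
  q_egger <- if (n >= 3L) cochranQ(set, "Egger") else NULL
  steig <- if (!is.null(n_exp) && !is.null(n_out))
    mrSteiger(set, n_exp, n_out, ...) else NULL
  presso <- if (!is.null(presso_seed) && n >= 4L)
    mrPresso(set, n_sim = n_sim, seed = presso_seed) else NULL
  power <- NA_real_
  if (!is.null(power_args) && !is.null(n_exp) && !is.null(n_out)) {
    p <- set@pairs
    dots <- list(...)
    r2 <- min(1, sum(.r2_from_z(p$beta_exp, p$se_exp, n_exp,
                                set@exposureType,
                                ncase = dots$ncase_exp,
                                ncontrol = dots$ncontrol_exp)))
    power <- powerBinary(n_out, power_args$case_fraction, r2,
                         power_args$true_or,
                         alpha = power_args$alpha %||% 0.05)
  }
  data.frame(
    exposure = set@exposureId, outcome = set@outcomeId, n_snp = n,
    mean_F = meanF(set),
    Q_ivw = q_ivw@Q, Q_ivw_df = q_ivw@df, P_het_ivw = q_ivw@pval,
    Q_egger = if (is.null(q_egger)) NA_real_ else q_egger@Q,
    P_het_egger = if (is.null(q_egger)) NA_real_ else q_egger@pval,
    egger_intercept = if (is.null(egg)) NA_real_ else
      egg@extras$intercept,
    P_intercept = if (is.null(egg)) NA_real_ else
      egg@extras$intercept_pval,
    P_steiger = if (is.null(steig)) NA_real_ else steig@pval,
    steiger_correct = if (is.null(steig)) NA else steig@directionCorrect,
    P_presso_global = if (is.null(presso)) NA_real_ else
      presso@globalPval,
    n_presso_outliers = if (is.null(presso)) NA_integer_ else
      length(presso@outlierIndices),
    power = power,
    stringsAsFactors = FALSE)
}
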