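## Multivariable IVW and the network mediation decomposition: total,
## direct and indirect effects and proportions mediated, for single and
## combined mediators.

#' Construct an MVInstrumentSet from aligned matrices
#'
#' @param snp SNP ids.
#' @param beta_exp,se_exp SNP-by-exposure matrices of genetic associations
#'   (columns named by exposure, or names given via `exposure_ids`).
#' @param beta_out,se_out outcome associations aligned to the same effect
#'   alleles.
#' @param exposure_ids exposure identifiers (defaults to the column names).
#' @param outcome_id,outcome_type outcome metadata.
#' @param chr,pos optional coordinates.
#' @return an [MVInstrumentSet-class]
#' @export
mvInstrumentSet <- function(snp, beta_exp, se_exp, beta_out, se_out,
                            exposure_ids = colnames(beta_exp),
                            outcome_id = "outcome",
                            outcome_type = "binary",
                            chr = NULL, pos = NULL) {
  beta_exp <- as.matrix(beta_exp); se_exp <- as.matrix(se_exp)
  if (is.null(exposure_ids))
    exposure_ids <- paste0("exposure", seq_len(ncol(beta_exp)))
  colnames(beta_exp) <- colnames(se_exp) <- exposure_ids
  n <- length(snp)
  new("MVInstrumentSet", snp = as.character(snp),
      chr = as.character(chr %||% rep("1", n)),
      pos = as.numeric(pos %||% seq_len(n) * 2.1e7),
      betaExp = beta_exp, seExp = se_exp,
      betaOut = as.numeric(beta_out), seOut = as.numeric(se_out),
      exposureIds = exposure_ids, outcomeId = outcome_id,
      outcomeType = outcome_type)
}

#' Multivariable IVW regression
#'
#' Weighted multiple regression (zero intercept, weights `se_out^-2`) of
#' the outcome associations on the SNP-by-exposure association matrix.
#' Each coefficient is the conditional (direct) effect of that exposure
#' given the other columns. Coefficient SEs come from the weighted normal
#' equations, inflated by the multiplicative residual scale
#' `max(1, sqrt(Q / (n - k)))` — with a single exposure this reproduces
#' univariable [mrIVW()] exactly.
#'
#' @param set an [MVInstrumentSet-class]
#' @return an [MVMRResult-class]
#' @export
mvmrIVW <- function(set) {
  .assert(is(set, "MVInstrumentSet"), "set must be an MVInstrumentSet")
  X <- set@betaExp
  y <- set@betaOut
  w <- 1 / set@seOut^2
  n <- nrow(X); k <- ncol(X)
  if (n <= k)
    stop("need more SNPs than exposures (", n, " <= ", k, ")",
         call. = FALSE)
  if (qr(X)$rank < k)
    stop("exposure-beta matrix is rank deficient", call. = FALSE)
  XtW <- t(X * w)
  inv <- solve(XtW %*% X)
  coefs <- drop(inv %*% (XtW %*% y))
  rss <- sum(w * (y - drop(X %*% coefs))^2)
  scale <- max(1, sqrt(rss / (n - k)))
  se <- sqrt(diag(inv)) * scale
  zcrit <- stats::qnorm(0.975)
  names(coefs) <- names(se) <- set@exposureIds
  new("MVMRResult", exposures = set@exposureIds,
      beta = coefs, se = se,
      ciLow = coefs - zcrit * se, ciHigh = coefs + zcrit * se,
      pval = .pval_z(coefs / se), nSnp = as.integer(n),
      binaryOutcome = identical(set@outcomeType, "binary"),
      extras = list(Q = rss, Q_df = n - k, scale = scale))
}

.coef_of <- function(x, exposure = NULL) {
  if (is(x, "MRResult")) return(c(beta = x@beta, se = x@se))
  if (is(x, "MVMRResult")) {
    exposure <- exposure %||% x@exposures[1L]
    .assert(exposure %in% x@exposures,
            paste0("exposure '", exposure, "' not in MVMR result"))
    return(c(beta = unname(x@beta[exposure]), se = unname(x@se[exposure])))
  }
  stop("expected an MRResult or MVMRResult", call. = FALSE)
}

.mediation_new <- function(mediator, total, total_se, direct, direct_se,
                           indirect, indirect_se, method) {
  if (total == 0) stop("undefined PM: total effect is zero", call. = FALSE)
  ratio <- indirect / total
  pm <- 100 * ratio
  ## Delta method for indirect/total treating the two as uncorrelated
  ## normals (documented approximation; bootstrap alternative available).
  if (method == "difference") {
    ## pm/100 = 1 - d/t: gradient (-1/t, d/t^2) on (d, t)
    var_ratio <- (direct_se / total)^2 + (direct * total_se / total^2)^2
  } else {
    var_ratio <- (indirect_se / total)^2 +
      (indirect * total_se / total^2)^2
  }
  pm_se <- 100 * sqrt(var_ratio)
  zcrit <- stats::qnorm(0.975)
  note <- if (pm < 0 || pm > 100)
    "PM outside [0, 100]: interpret with caution" else ""
  new("MediationResult", mediator = mediator,
      total = total, totalSE = total_se,
      direct = direct, directSE = direct_se,
      indirect = indirect, indirectSE = indirect_se,
      pm = pm, pmSE = pm_se, pmCI = pm + c(-1, 1) * zcrit * pm_se,
      method = method, note = note)
}

#' Mediation by the difference method
#'
#' Decomposes a total effect into direct and indirect components using a
#' univariable (total) and a mediator-adjusted multivariable (direct)
#' estimate on the same log-odds scale: indirect = total - direct, and the
#' proportion mediated is PM = 100 * indirect / total. The PM standard
#' error is a delta-method approximation treating total and direct as
#' uncorrelated (they share instruments, so this is approximate; see
#' [pmBootstrap()] for a resampling alternative). PM is reported
#' unbounded, with a note when it falls outside \[0, 100\].
#'
#' @param total an [MRResult-class] for the unadjusted exposure-outcome
#'   effect.
#' @param direct an [MRResult-class] or [MVMRResult-class] holding the
#'   mediator-adjusted direct effect (for an `MVMRResult`, the coefficient
#'   chosen by `exposure`).
#' @param mediator label for the mediator (set) being adjusted for.
#' @param exposure which MVMR coefficient is the exposure of interest.
#' @return a [MediationResult-class]
#' @export
mediationDifference <- function(total, direct, mediator = "mediator",
                                exposure = NULL) {
  tt <- .coef_of(total)
  dd <- .coef_of(direct, exposure)
  indirect <- tt["beta"] - dd["beta"]
  indirect_se <- sqrt(tt["se"]^2 + dd["se"]^2)
  .mediation_new(mediator, unname(tt["beta"]), unname(tt["se"]),
                 unname(dd["beta"]), unname(dd["se"]),
                 unname(indirect), unname(indirect_se), "difference")
}

#' Mediation by the product method
#'
#' indirect = a * b where `a` is the exposure-to-mediator effect and `b`
#' the mediator-to-outcome effect conditional on the exposure; the SE is
#' the product delta method sqrt(a^2 se_b^2 + b^2 se_a^2). The proportion
#' mediated is computed against the supplied `total` effect.
#'
#' @param a an [MRResult-class] for exposure -> mediator.
#' @param b an [MRResult-class] or [MVMRResult-class] for
#'   mediator -> outcome conditional on the exposure (coefficient chosen
#'   by `mediator_id` when an MVMR result).
#' @param total an [MRResult-class] total effect (required for PM).
#' @param mediator label; `mediator_id` selects the MVMR coefficient.
#' @param mediator_id column of `b` holding the mediator's effect.
#' @return a [MediationResult-class]
#' @export
mediationProduct <- function(a, b, total, mediator = "mediator",
                             mediator_id = NULL) {
  .assert(!missing(total), "total effect is required to compute PM")
  aa <- .coef_of(a)
  bb <- .coef_of(b, mediator_id)
  tt <- .coef_of(total)
  indirect <- unname(aa["beta"] * bb["beta"])
  indirect_se <- sqrt(aa["beta"]^2 * bb["se"]^2 +
                        bb["beta"]^2 * aa["se"]^2)
  direct <- unname(tt["beta"]) - indirect
  direct_se <- sqrt(unname(tt["se"])^2 + indirect_se^2)
  .mediation_new(mediator, unname(tt["beta"]), unname(tt["se"]),
                 direct, unname(direct_se),
                 indirect, unname(indirect_se), "product")
}

#' Network mediation decomposition
#'
#' One difference-method [MediationResult-class] per mediator (each from
#' the multivariable model adjusting for that mediator alone) plus the
#' combined result from the model adjusting for all mediators jointly.
#'
#' @param total an [MRResult-class] total effect.
#' @param direct_single named list of [MVMRResult-class] (or
#'   [MRResult-class]) objects, one per mediator.
#' @param direct_all the all-mediator [MVMRResult-class].
#' @param exposure which MVMR coefficient is the exposure of interest.
#' @return named list of [MediationResult-class] objects; the joint entry
#'   is named `"combined"`.
#' @export
networkDecomposition <- function(total, direct_single, direct_all,
                                 exposure = NULL) {
  .assert(is.list(direct_single) && length(names(direct_single)) ==
            length(direct_single),
          "direct_single must be a named list")
  out <- lapply(names(direct_single), function(m)
    mediationDifference(total, direct_single[[m]], mediator = m,
                        exposure = exposure))
  names(out) <- names(direct_single)
  out$combined <- mediationDifference(total, direct_all,
                                      mediator = "combined",
                                      exposure = exposure)
  out
}

#' Tidy table of mediation results
#'
#' @param decomp list of [MediationResult-class] objects (e.g. from
#'   [networkDecomposition()]).
#' @return data.frame with one row per mediator, mirroring a forest-style
#'   total/direct/PM report.
#' @export
mediationTable <- function(decomp) {
  if (is(decomp, "MediationResult")) decomp <- list(decomp)
  do.call(rbind, lapply(decomp, function(m)
    data.frame(mediator = m@mediator, method = m@method,
               total = m@total, total_se = m@totalSE,
               direct = m@direct, direct_se = m@directSE,
               indirect = m@indirect, indirect_se = m@indirectSE,
               or_total = exp(m@total), or_direct = exp(m@direct),
               pm = m@pm, pm_se = m@pmSE,
               pm_ci_low = m@pmCI[1], pm_ci_high = m@pmCI[2],
               note = m@note, stringsAsFactors = FALSE)))
}

#' Bootstrap-over-instruments PM uncertainty
#'
#' Resamples the univariable instrument set (for the total effect) and the
#' multivariable instrument rows (for the direct effect) with replacement,
#' recomputing the difference-method PM each time. The two sets are
#' resampled independently, matching the delta-method independence
#' approximation rather than correcting it; the percentile interval is
#' still typically more honest than the delta interval when PM is near 0
#' or the total effect is weak.
#'
#' @param uv_set [InstrumentSet-class] behind the total effect.
#' @param mv_set [MVInstrumentSet-class] behind the direct effect.
#' @param exposure exposure coefficient of interest in the MVMR model.
#' @param reps bootstrap replicates (default 500).
#' @param seed mandatory RNG seed.
#' @return list with `pm_se` and percentile `pm_ci` (both percent), plus
#'   the vector of bootstrap PMs.
#' @export
pmBootstrap <- function(uv_set, mv_set, exposure = NULL, reps = 500L,
                        seed) {
  .assert(!missing(seed), "seed is mandatory for pmBootstrap")
  exposure <- exposure %||% mv_set@exposureIds[1L]
  n_uv <- nSnps(uv_set); n_mv <- nSnps(mv_set)
  with_seed(seed, {
    pms <- vapply(seq_len(reps), function(b) {
      iu <- sample.int(n_uv, replace = TRUE)
      im <- sample.int(n_mv, replace = TRUE)
      su <- uv_set
      su@pairs <- uv_set@pairs[iu, , drop = FALSE]
      su@pairs$snp <- sprintf("bs%05d", seq_along(iu))
      su@fstat <- uv_set@fstat[iu]
      total_b <- mrIVW(su)
      sm <- mvInstrumentSet(sprintf("bs%05d", seq_along(im)),
                            mv_set@betaExp[im, , drop = FALSE],
                            mv_set@seExp[im, , drop = FALSE],
                            mv_set@betaOut[im], mv_set@seOut[im],
                            exposure_ids = mv_set@exposureIds,
                            outcome_id = mv_set@outcomeId,
                            outcome_type = mv_set@outcomeType)
      direct_b <- tryCatch(mvmrIVW(sm), error = function(e) NULL)
      if (is.null(direct_b) || total_b@beta == 0) return(NA_real_)
      100 * (total_b@beta - direct_b@beta[exposure]) / total_b@beta
    }, numeric(1))
    pms <- pms[is.finite(pms)]
    list(pm_se = stats::sd(pms),
         pm_ci = unname(stats::quantile(pms, c(0.025, 0.975))),
         pm_boot = pms)
  })
}
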