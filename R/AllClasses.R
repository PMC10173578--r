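## Central S4 data objects. All user-visible containers get a validity
## method; construction goes through the exported constructor functions,
## never through new() in user code.

#' SummaryStats: one trait's GWAS summary statistics
#'
#' Holds per-SNP association records for a single trait. The `stats` slot is
#' a data.frame with the canonical columns `snp`, `chr`, `pos` (1-based),
#' `ea` (effect allele), `oa` (other allele), `eaf` (effect-allele frequency,
#' may be `NA`), `beta`, `se`, `pval`, `n`, and for binary traits optionally
#' `ncase`, `ncontrol`. Rows rejected at construction are retained, with a
#' reason, in `rejected`.
#'
#' @slot traitId single character trait identifier.
#' @slot traitType `"continuous"` or `"binary"`.
#' @slot stats data.frame of validated records, one row per SNP.
#' @slot rejected data.frame of rejected rows with a `reason` column.
#' @slot meta list of trait-level metadata (e.g. default `n`, `ncase`,
#'   `ncontrol`).
#' @exportClass SummaryStats
setClass("SummaryStats",
  slots = c(traitId = "character", traitType = "character",
            stats = "data.frame", rejected = "data.frame", meta = "list"))

.SUMSTAT_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf",
                   "beta", "se", "pval", "n", "ncase", "ncontrol")

setValidity("SummaryStats", function(object) {
  msg <- character()
  if (length(object@traitId) != 1L || !nzchar(object@traitId))
    msg <- c(msg, "traitId must be a single non-empty string")
  if (!object@traitType %in% c("continuous", "binary"))
    msg <- c(msg, "traitType must be 'continuous' or 'binary'")
  st <- object@stats
  if (!all(.SUMSTAT_COLS %in% names(st)))
    msg <- c(msg, paste("stats must contain columns:",
                        paste(.SUMSTAT_COLS, collapse = ", ")))
  if (nrow(st)) {
    if (anyDuplicated(st$snp)) msg <- c(msg, "snp ids must be unique")
    if (any(st$se <= 0)) msg <- c(msg, "all se must be > 0")
    if (any(!is.na(st$eaf) & (st$eaf < 0 | st$eaf > 1)))
      msg <- c(msg, "eaf must lie in [0, 1] when present")
    if (any(st$ea == st$oa)) msg <- c(msg, "effect and other allele must differ")
    if (any(st$pval <= 0 | st$pval > 1)) msg <- c(msg, "pval must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: exposure/outcome effects aligned to a common effect allele
#'
#' The unit of all downstream estimation. `pairs` has one row per retained
#' SNP with columns `snp`, `chr`, `pos`, `ea`, `oa`, `beta_exp`, `se_exp`,
#' `pval_exp`, `eaf_exp`, `beta_out`, `se_out`, `pval_out`, `eaf_out`,
#' `status` (one of `kept`, `flipped`, `strand_flipped`). Dropped SNPs are
#' accounted for in `dropped` (`status` `dropped_palindromic` or
#' `dropped_incompatible`).
#'
#' @slot exposureId,outcomeId trait identifiers.
#' @slot exposureType,outcomeType trait types (`"continuous"`/`"binary"`).
#' @slot pairs data.frame of retained, aligned SNP pairs.
#' @slot dropped data.frame of dropped SNPs with status and reason.
#' @slot params list recording the harmonization thresholds used.
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  slots = c(exposureId = "character", outcomeId = "character",
            exposureType = "character", outcomeType = "character",
            pairs = "data.frame", dropped = "data.frame", params = "list"))

setValidity("HarmonizedSet", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out", "status")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("pairs must contain:", paste(need, collapse = ", ")))
  else if (nrow(p)) {
    if (anyDuplicated(p$snp)) msg <- c(msg, "snp ids must be unique")
    if (any(p$se_exp <= 0) || any(p$se_out <= 0))
      msg <- c(msg, "kept pairs must have positive SEs")
    if (any(!p$status %in% c("kept", "flipped", "strand_flipped")))
      msg <- c(msg, "retained pairs may only be kept/flipped/strand_flipped")
  }
  if (identical(object@exposureId, object@outcomeId))
    msg <- c(msg, "exposure and outcome must be different traits")
  if (length(msg)) msg else TRUE
})

#' InstrumentSet: a HarmonizedSet restricted to selected instruments
#'
#' Extends [HarmonizedSet-class] with per-SNP F statistics, the clumping
#' parameters used, and the record of confounder-based exclusions applied.
#'
#' @slot fstat numeric vector of per-SNP F statistics, parallel to `pairs`.
#' @slot clumpParams list with `p_threshold`, `r2_threshold`, `window_bp`.
#' @slot exclusions data.frame of removed SNPs (`snp`, `reason`).
#' @exportClass InstrumentSet
setClass("InstrumentSet", contains = "HarmonizedSet",
  slots = c(fstat = "numeric", clumpParams = "list",
            exclusions = "data.frame"))

setValidity("InstrumentSet", function(object) {
  msg <- character()
  if (length(object@fstat) != nrow(object@pairs))
    msg <- c(msg, "fstat must be parallel to pairs")
  if (nrow(object@pairs) == 0L)
    msg <- c(msg, "instrument set must be non-empty")
  if (length(msg)) msg else TRUE
})

#' MRResult: one causal estimate
#'
#' Effect estimates are always stored on the linear scale of the outcome
#' (log-odds when the outcome is binary); the odds-ratio scale is a
#' presentation transform available via [orScale()].
#'
#' @slot method estimator name.
#' @slot exposure,outcome trait identifiers.
#' @slot beta,se point estimate and standard error.
#' @slot ciLow,ciHigh 95% confidence limits.
#' @slot pval two-sided p-value.
#' @slot nSnp number of instruments used.
#' @slot binaryOutcome whether the outcome is binary (enables OR scale).
#' @slot extras list of method-specific diagnostics (e.g. Egger intercept,
#'   Cochran's Q at the estimate, RAPS overdispersion).
#' @exportClass MRResult
setClass("MRResult",
  slots = c(method = "character", exposure = "character", outcome = "character",
            beta = "numeric", se = "numeric", ciLow = "numeric",
            ciHigh = "numeric", pval = "numeric", nSnp = "integer",
            binaryOutcome = "logical", extras = "list"))

setValidity("MRResult", function(object) {
  msg <- character()
  tol <- 1e-8
  if (object@se < 0) msg <- c(msg, "se must be >= 0")
  if (object@ciLow > object@beta + tol || object@ciHigh < object@beta - tol)
    msg <- c(msg, "confidence interval must bracket the point estimate")
  if (object@pval < 0 || object@pval > 1) msg <- c(msg, "pval must be in [0,1]")
  if (object@nSnp < 1L) msg <- c(msg, "nSnp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' QResult: Cochran's Q heterogeneity statistic
#'
#' @slot Q statistic value.
#' @slot df degrees of freedom (`n_snp - 1` in the IVW framework,
#'   `n_snp - 2` in the Egger framework).
#' @slot pval chi-square upper-tail p-value.
#' @slot framework `"IVW"` or `"Egger"`.
#' @exportClass QResult
setClass("QResult",
  slots = c(Q = "numeric", df = "numeric", pval = "numeric",
            framework = "character"))

setValidity("QResult", function(object) {
  msg <- character()
  if (object@Q < 0) msg <- c(msg, "Q must be >= 0")
  if (!object@framework %in% c("IVW", "Egger"))
    msg <- c(msg, "framework must be IVW or Egger")
  if (length(msg)) msg else TRUE
})

#' PressoResult: residual-sum-of-squares outlier analysis
#'
#' @slot globalRSS observed leave-one-out weighted residual sum of squares.
#' @slot globalPval empirical global pleiotropy p-value.
#' @slot outlierIndices indices (into the instrument set) of flagged SNPs;
#'   empty when the global test is not significant.
#' @slot outlierSnps SNP ids of the flagged instruments.
#' @slot outlierPvals Bonferroni-adjusted per-SNP empirical p-values.
#' @slot distortionPval p-value comparing raw and outlier-corrected estimates
#'   against the simulated distortion null (`NA` when no outliers).
#' @slot betaRaw,betaCorrected IVW estimates before/after outlier removal.
#' @slot nSim,seed simulation size and seed (reproducibility contract).
#' @exportClass PressoResult
setClass("PressoResult",
  slots = c(globalRSS = "numeric", globalPval = "numeric",
            outlierIndices = "integer", outlierSnps = "character",
            outlierPvals = "numeric", distortionPval = "numeric",
            betaRaw = "MRResult", betaCorrected = "MRResult",
            nSim = "integer", seed = "integer"))

#' SteigerResult: directionality diagnostic
#'
#' @slot r2Exposure,r2Outcome summed instrument variance explained.
#' @slot directionCorrect TRUE when the instruments explain strictly more
#'   variance in the exposure than in the outcome.
#' @slot pval two-sided p-value from the Fisher z comparison of |r|.
#' @exportClass SteigerResult
setClass("SteigerResult",
  slots = c(r2Exposure = "numeric", r2Outcome = "numeric",
            directionCorrect = "logical", pval = "numeric"))

setValidity("SteigerResult", function(object) {
  msg <- character()
  if (object@r2Exposure < 0 || object@r2Exposure > 1 ||
      object@r2Outcome < 0 || object@r2Outcome > 1)
    msg <- c(msg, "r2 values must lie in [0, 1]")
  if (!identical(object@directionCorrect,
                 object@r2Exposure > object@r2Outcome))
    msg <- c(msg, "directionCorrect must equal r2Exposure > r2Outcome")
  if (length(msg)) msg else TRUE
})

#' MVInstrumentSet: instruments for multivariable MR
#'
#' SNP-by-exposure matrices of genetic associations together with outcome
#' associations, all aligned to a common effect allele per SNP.
#'
#' @slot snp SNP ids (rows).
#' @slot chr,pos genomic coordinates.
#' @slot betaExp,seExp numeric matrices, one column per exposure.
#' @slot betaOut,seOut outcome association vectors.
#' @slot exposureIds column (exposure) identifiers.
#' @slot outcomeId,outcomeType outcome identifier and type.
#' @exportClass MVInstrumentSet
setClass("MVInstrumentSet",
  slots = c(snp = "character", chr = "character", pos = "numeric",
            betaExp = "matrix", seExp = "matrix",
            betaOut = "numeric", seOut = "numeric",
            exposureIds = "character", outcomeId = "character",
            outcomeType = "character"))

setValidity("MVInstrumentSet", function(object) {
  msg <- character()
  n <- length(object@snp)
  if (anyDuplicated(object@snp)) msg <- c(msg, "duplicated SNP rows")
  if (nrow(object@betaExp) != n || nrow(object@seExp) != n ||
      length(object@betaOut) != n || length(object@seOut) != n)
    msg <- c(msg, "row dimensions must agree")
  if (ncol(object@betaExp) != length(object@exposureIds))
    msg <- c(msg, "one exposure id per beta column")
  if (n && (any(object@seOut <= 0) || any(object@seExp <= 0)))
    msg <- c(msg, "standard errors must be positive")
  if (length(msg)) msg else TRUE
})

#' MVMRResult: conditional (direct) effects from multivariable MR
#'
#' @slot exposures exposure identifiers, in column order.
#' @slot beta,se,ciLow,ciHigh,pval named per-exposure estimates.
#' @slot nSnp number of instruments.
#' @slot binaryOutcome whether the outcome is binary.
#' @slot extras diagnostics (Q at the fit, residual scale).
#' @exportClass MVMRResult
setClass("MVMRResult",
  slots = c(exposures = "character", beta = "numeric", se = "numeric",
            ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
            nSnp = "integer", binaryOutcome = "logical", extras = "list"))

setValidity("MVMRResult", function(object) {
  msg <- character()
  k <- length(object@exposures)
  if (any(vapply(list(object@beta, object@se, object@ciLow, object@ciHigh,
                      object@pval), length, 1L) != k))
    msg <- c(msg, "per-exposure vectors must have one entry per exposure")
  if (any(object@ciLow > object@beta + 1e-8) ||
      any(object@ciHigh < object@beta - 1e-8))
    msg <- c(msg, "confidence intervals must bracket estimates")
  if (length(msg)) msg else TRUE
})

#' MediationResult: total/direct/indirect decomposition for one mediator set
#'
#' All effects are on the linear (log-odds for a binary outcome) scale.
#' By the difference method `indirect = total - direct` exactly, and the
#' proportion mediated is `pm = 100 * indirect / total`. PM is reported
#' unbounded; `note` flags values outside [0, 100].
#'
#' @slot mediator label of the mediator (or `"combined"` for joint sets).
#' @slot total,totalSE,direct,directSE,indirect,indirectSE effect components.
#' @slot pm proportion mediated, percent.
#' @slot pmSE delta-method (or bootstrap) standard error of PM, percent.
#' @slot pmCI length-2 95% interval for PM, percent.
#' @slot method `"difference"` or `"product"`.
#' @slot note quality flags (e.g. PM outside [0,100]).
#' @exportClass MediationResult
setClass("MediationResult",
  slots = c(mediator = "character", total = "numeric", totalSE = "numeric",
            direct = "numeric", directSE = "numeric",
            indirect = "numeric", indirectSE = "numeric",
            pm = "numeric", pmSE = "numeric", pmCI = "numeric",
            method = "character", note = "character"))

setValidity("MediationResult", function(object) {
  msg <- character()
  if (!object@method %in% c("difference", "product"))
    msg <- c(msg, "method must be 'difference' or 'product'")
  if (object@method == "difference" &&
      abs(object@indirect - (object@total - object@direct)) > 1e-8)
    msg <- c(msg, "difference method requires indirect = total - direct")
  if (length(object@pmCI) != 2L) msg <- c(msg, "pmCI must have length 2")
  if (length(msg)) msg else TRUE
})

#' DagSpec: simulation design for the synthetic summary-stat generator
#'
#' Encodes the causal diagram exposure -> mediators -> outcome (with a
#' direct exposure -> outcome edge), the per-trait GWAS designs, and the
#' nuisance processes (pleiotropy, overdispersion, palindromic SNPs). The
#' true estimands are closed-form functions of the edge coefficients:
#' total = c + sum(a_i b_i), indirect_i = a_i b_i, PM_i = a_i b_i / total.
#'
#' @slot nMediators number of mediators k.
#' @slot a exposure -> mediator coefficients (length k).
#' @slot b mediator -> outcome coefficients, log-odds scale (length k).
#' @slot cDirect direct exposure -> outcome coefficient.
#' @slot nSnps instruments per trait (exposure, then mediators).
#' @slot h2 total variance explained by each trait's instruments.
#' @slot nSample GWAS sample sizes: exposure, mediators, outcome.
#' @slot outcomeType `"binary"` or `"continuous"`.
#' @slot caseFraction outcome case fraction K (binary outcome).
#' @slot pleioFrac fraction of exposure instruments with a direct
#'   (pleiotropic) outcome effect.
#' @slot pleioMean,pleioSD offset distribution on the exposure-increasing
#'   allele direction; a nonzero mean makes the pleiotropy directional.
#' @slot tau2 overdispersion added to outcome effects (variance).
#' @slot palinFrac fraction of palindromic (A/T or C/G) SNPs generated.
#' @slot seed mandatory RNG seed.
#' @exportClass DagSpec
setClass("DagSpec",
  slots = c(nMediators = "integer", a = "numeric", b = "numeric",
            cDirect = "numeric", nSnps = "integer", h2 = "numeric",
            nSample = "numeric", outcomeType = "character",
            caseFraction = "numeric", pleioFrac = "numeric",
            pleioMean = "numeric", pleioSD = "numeric", tau2 = "numeric",
            palinFrac = "numeric", seed = "integer"))

setValidity("DagSpec", function(object) {
  msg <- character()
  k <- object@nMediators
  if (length(object@a) != k || length(object@b) != k)
    msg <- c(msg, "a and b must have one entry per mediator")
  if (length(object@nSnps) != k + 1L || length(object@h2) != k + 1L)
    msg <- c(msg, "nSnps and h2 must cover exposure plus each mediator")
  if (length(object@nSample) != k + 2L)
    msg <- c(msg, "nSample must cover exposure, mediators and outcome")
  if (any(object@h2 <= 0 | object@h2 >= 1))
    msg <- c(msg, "h2 must lie in (0, 1)")
  if (object@outcomeType == "binary" &&
      (object@caseFraction <= 0 || object@caseFraction >= 1))
    msg <- c(msg, "caseFraction must lie in (0, 1)")
  if (object@pleioFrac < 0 || object@pleioFrac > 1)
    msg <- c(msg, "pleioFrac must lie in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' SimulatedStudy: generated summary statistics plus ground truth
#'
#' @slot tables named list of [SummaryStats-class] objects: `exposure`,
#'   `M1` ... `Mk`, `outcome`.
#' @slot truth list of true estimands (see [trueEffects()]).
#' @slot spec the generating [DagSpec-class].
#' @slot version generator version string.
#' @exportClass SimulatedStudy
setClass("SimulatedStudy",
  slots = c(tables = "list", truth = "list", spec = "DagSpec",
            version = "character"))
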