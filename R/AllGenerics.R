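## Generics and accessors. Slot access in user code goes through these.

#' @describeIn SummaryStats-class trait identifier
#' @param x a netMR object
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
setMethod("traitId", "SummaryStats", function(x) x@traitId)

#' @describeIn SummaryStats-class trait type ("continuous"/"binary")
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
setMethod("traitType", "SummaryStats", function(x) x@traitType)

#' @describeIn SummaryStats-class validated per-SNP records as a data.frame
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
setMethod("statsTable", "SummaryStats", function(x) x@stats)

#' @describeIn SummaryStats-class rows rejected at validation, with reasons
#' @export
setGeneric("rejectedRows", function(x) standardGeneric("rejectedRows"))
setMethod("rejectedRows", "SummaryStats", function(x) x@rejected)

#' Number of SNPs in an object
#' @param x a netMR object
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
setMethod("nSnps", "SummaryStats", function(x) nrow(x@stats))
setMethod("nSnps", "HarmonizedSet", function(x) nrow(x@pairs))
setMethod("nSnps", "MRResult", function(x) x@nSnp)
setMethod("nSnps", "MVInstrumentSet", function(x) length(x@snp))
setMethod("nSnps", "MVMRResult", function(x) x@nSnp)

#' @describeIn HarmonizedSet-class retained aligned pairs as a data.frame
#' @param x a `HarmonizedSet`
#' @export
setGeneric("harmonizedPairs", function(x) standardGeneric("harmonizedPairs"))
setMethod("harmonizedPairs", "HarmonizedSet", function(x) x@pairs)

#' @describeIn HarmonizedSet-class dropped SNPs with status and reason
#' @export
setGeneric("droppedSnps", function(x) standardGeneric("droppedSnps"))
setMethod("droppedSnps", "HarmonizedSet", function(x) x@dropped)

#' @describeIn HarmonizedSet-class exposure trait identifier
#' @export
setGeneric("exposureId", function(x) standardGeneric("exposureId"))
setMethod("exposureId", "HarmonizedSet", function(x) x@exposureId)

#' @describeIn HarmonizedSet-class outcome trait identifier
#' @export
setGeneric("outcomeId", function(x) standardGeneric("outcomeId"))
setMethod("outcomeId", "HarmonizedSet", function(x) x@outcomeId)
setMethod("outcomeId", "MVInstrumentSet", function(x) x@outcomeId)

#' @describeIn InstrumentSet-class per-SNP F statistics
#' @param x an `InstrumentSet`
#' @export
setGeneric("fStats", function(x) standardGeneric("fStats"))
setMethod("fStats", "InstrumentSet", function(x) x@fstat)

#' @describeIn InstrumentSet-class mean F statistic over the instruments
#' @export
setGeneric("meanF", function(x) standardGeneric("meanF"))
setMethod("meanF", "InstrumentSet", function(x) mean(x@fstat))

#' Point estimate of a result object
#'
#' For `MRResult` the single causal estimate; for `MVMRResult` the named
#' vector of conditional (direct) effects.
#' @param x a result object
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
setMethod("estimate", "MRResult", function(x) x@beta)
setMethod("estimate", "MVMRResult", function(x) x@beta)

#' Standard error of a result object
#' @param x a result object
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
setMethod("stdError", "MRResult", function(x) x@se)
setMethod("stdError", "MVMRResult", function(x) x@se)

#' Two-sided p-value of a result object
#' @param x a result object
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
setMethod("pValue", "MRResult", function(x) x@pval)
setMethod("pValue", "MVMRResult", function(x) x@pval)
setMethod("pValue", "QResult", function(x) x@pval)
setMethod("pValue", "SteigerResult", function(x) x@pval)

#' 95% confidence limits of a result object
#' @param x a result object
#' @return numeric of length 2 (or a 2-column matrix for `MVMRResult`)
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
setMethod("confInt", "MRResult", function(x) c(x@ciLow, x@ciHigh))
setMethod("confInt", "MVMRResult",
          function(x) cbind(low = x@ciLow, high = x@ciHigh))

#' Method-specific diagnostics stored with a result
#' @param x a result object
#' @export
setGeneric("mrExtras", function(x) standardGeneric("mrExtras"))
setMethod("mrExtras", "MRResult", function(x) x@extras)
setMethod("mrExtras", "MVMRResult", function(x) x@extras)

#' Odds-ratio scale presentation of a log-odds estimate
#'
#' Exponentiates the estimate and confidence limits of a result whose
#' outcome is binary. The stored estimate itself always stays on the
#' log-odds scale.
#'
#' @param x an `MRResult` (binary outcome)
#' @return named numeric: `or`, `ci_low`, `ci_high`
#' @export
setGeneric("orScale", function(x) standardGeneric("orScale"))
setMethod("orScale", "MRResult", function(x) {
  if (!x@binaryOutcome)
    stop("orScale is only defined for binary outcomes", call. = FALSE)
  c(or = exp(x@beta), ci_low = exp(x@ciLow), ci_high = exp(x@ciHigh))
})

#' @describeIn MediationResult-class proportion mediated, percent
#' @param x a `MediationResult`
#' @export
setGeneric("proportionMediated", function(x) standardGeneric("proportionMediated"))
setMethod("proportionMediated", "MediationResult", function(x) x@pm)

## ---- show methods -------------------------------------------------------

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats '%s' (%s): %d SNPs (%d rejected)\n",
              object@traitId, object@traitType, nrow(object@stats),
              nrow(object@rejected)))
  if (nrow(object@stats))
    print(utils::head(object@stats[, c("snp", "chr", "pos", "ea", "oa",
                                       "beta", "se", "pval")], 3L))
})

setMethod("show", "HarmonizedSet", function(object) {
  tab <- table(factor(c(object@pairs$status, object@dropped$status)))
  cat(sprintf("HarmonizedSet %s -> %s: %d SNPs retained, %d dropped\n",
              object@exposureId, object@outcomeId, nrow(object@pairs),
              nrow(object@dropped)))
  if (length(tab))
    cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "), "\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf(
    "InstrumentSet %s -> %s: %d instruments, mean F = %.1f%s\n",
    object@exposureId, object@outcomeId, nrow(object@pairs),
    mean(object@fstat),
    if (mean(object@fstat) <= 10) " (WEAK)" else ""))
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s] %s -> %s (%d SNPs)\n", object@method,
              object@exposure, object@outcome, object@nSnp))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pval))
  if (object@binaryOutcome) {
    or <- orScale(object)
    cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f]\n",
                or["or"], or["ci_low"], or["ci_high"]))
  }
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran's Q (%s): Q = %.3f, df = %d, p = %.3g\n",
              object@framework, object@Q, as.integer(object@df),
              object@pval))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("PRESSO: global p = %.3g (RSS = %.3f, %d sims, seed %d)\n",
              object@globalPval, object@globalRSS, object@nSim, object@seed))
  if (length(object@outlierIndices))
    cat("  outliers:", paste(object@outlierSnps, collapse = ", "),
        sprintf(" distortion p = %.3g\n", object@distortionPval))
  else cat("  no outliers flagged\n")
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf(
    "Steiger: r2(exposure) = %.4g, r2(outcome) = %.4g, direction %s, p = %.3g\n",
    object@r2Exposure, object@r2Outcome,
    if (object@directionCorrect) "correct" else "NOT confirmed",
    object@pval))
})

setMethod("show", "MVMRResult", function(object) {
  cat(sprintf("MVMRResult (%d SNPs), conditional effects:\n", object@nSnp))
  df <- data.frame(exposure = object@exposures, beta = object@beta,
                   se = object@se, ci_low = object@ciLow,
                   ci_high = object@ciHigh, pval = object@pval,
                   row.names = NULL)
  print(df, digits = 4)
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("Mediation [%s] via %s:\n", object@method, object@mediator))
  cat(sprintf("  total = %.4f, direct = %.4f, indirect = %.4f\n",
              object@total, object@direct, object@indirect))
  cat(sprintf("  PM = %.2f%% (SE %.2f), 95%% CI [%.2f, %.2f]\n",
              object@pm, object@pmSE, object@pmCI[1], object@pmCI[2]))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "DagSpec", function(object) {
  cat(sprintf(
    "DagSpec: 1 exposure, %d mediator(s), %s outcome; seed %d\n",
    object@nMediators, object@outcomeType, object@seed))
  te <- trueEffects(object)
  cat(sprintf("  true total = %.4f, combined PM = %.2f%%\n",
              te$total, te$pm_combined))
})

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy (generator %s, seed %d): %d tables\n",
              object@version, object@spec@seed, length(object@tables)))
  for (nm in names(object@tables))
    cat(sprintf("  %-10s %5d SNPs (%s)\n", nm, nSnps(object@tables[[nm]]),
                traitType(object@tables[[nm]])))
})
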