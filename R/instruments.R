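## Instrument selection: significance filtering, greedy LD clumping,
## instrument-strength screening and confounder-based exclusion.

#' Clumping parameters
#'
#' Defaults follow the standard two-sample practice for strongly
#' independent instruments: genome-wide significance p < 5e-8, pairwise
#' r^2 < 0.001 within a 10 Mb window.
#'
#' @param p_threshold significance cutoff for instrument inclusion.
#' @param r2_threshold LD cutoff; SNP pairs at or above it are pruned.
#' @param window_bp clump window in base pairs (inclusive, same chromosome).
#' @return a validated list of class `clump_params`
#' @export
clumpParams <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                        window_bp = 1e7) {
  .assert(p_threshold > 0 && p_threshold < 1, "p_threshold must be in (0,1)")
  .assert(r2_threshold >= 0 && r2_threshold <= 1,
          "r2_threshold must be in [0,1]")
  .assert(window_bp > 0, "window_bp must be > 0")
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_bp = window_bp), class = "clump_params")
}

#' Read a square LD (r-squared) matrix from a TSV file
#'
#' Expects a square matrix with SNP ids as both header row and first
#' column, values in \[0,1\] with unit diagonal.
#'
#' @param path TSV file path
#' @return symmetric numeric matrix with SNP-id dimnames
#' @export
readLDMatrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  .assert(nrow(m) == ncol(m), "LD matrix must be square")
  .assert(all(m >= 0 & m <= 1), "r2 values must lie in [0,1]")
  .assert(all(abs(diag(m) - 1) < 1e-8), "LD matrix diagonal must be 1")
  m
}

#' Greedy LD clumping
#'
#' Sorts SNPs by ascending p-value (ties broken by ascending position then
#' SNP id, making the result independent of input row order), then
#' repeatedly keeps the best remaining SNP and removes every remaining SNP
#' on the same chromosome within `window_bp` whose r-squared with it is at
#' or above `r2_threshold`. When no LD matrix is supplied the fall-back is
#' distance-only: any same-chromosome SNP inside the window is treated as
#' correlated and removed. This conservative fall-back preserves the
#' independence guarantee when no reference panel is available.
#'
#' @param records data.frame with columns `snp`, `chr`, `pos`, `pval`.
#' @param ld optional symmetric r-squared matrix with SNP-id dimnames.
#' @param params a [clumpParams()] list.
#' @return character vector of kept SNP ids, in selection order
#' @export
ldClump <- function(records, ld = NULL, params = clumpParams()) {
  .assert(all(c("snp", "chr", "pos", "pval") %in% names(records)),
          "records needs columns snp, chr, pos, pval")
  if (!nrow(records)) return(character())
  if (!is.null(ld)) {
    absent <- setdiff(records$snp, rownames(ld))
    if (length(absent))
      stop("LD matrix is missing SNP(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  ord <- order(records$pval, records$pos, records$snp)
  rec <- records[ord, ]
  kept <- character()
  while (nrow(rec)) {
    top <- rec[1L, ]
    kept <- c(kept, top$snp)
    in_window <- rec$chr == top$chr &
      abs(rec$pos - top$pos) <= params$window_bp
    if (is.null(ld)) {
      remove <- in_window
    } else {
      r2 <- ld[top$snp, rec$snp]
      remove <- in_window & r2 >= params$r2_threshold
      remove[1L] <- TRUE
    }
    rec <- rec[!remove, , drop = FALSE]
  }
  kept
}

#' Per-SNP instrument-strength F statistic
#'
#' Uses the squared-t approximation F = (beta/se)^2 on the exposure
#' association. (An alternative formulation based on the variance explained
#' and sample size, F = r2 (n-2) / (1 - r2), is essentially equivalent for
#' single SNPs at GWAS scale; the squared-t form needs no sample size.)
#' An instrument set is conventionally flagged weak when the mean F is at
#' or below 10.
#'
#' @param beta_exp,se_exp exposure association and its standard error
#'   (vectors accepted).
#' @return numeric vector of F statistics
#' @export
fStatistic <- function(beta_exp, se_exp) {
  .assert(all(se_exp > 0), "se_exp must be > 0")
  (beta_exp / se_exp)^2
}

#' Select instruments from a harmonized set
#'
#' Applies the genome-wide significance filter on the exposure p-value,
#' greedy LD clumping ([ldClump()]), the instrument-strength screen, and
#' an optional confounder-based exclusion list, yielding an
#' [InstrumentSet-class].
#'
#' @param hset a [HarmonizedSet-class]
#' @param params a [clumpParams()] list
#' @param ld optional r-squared matrix (see [ldClump()])
#' @param exclusions optional data.frame (`snp`, `reason`) of SNPs to
#'   remove, e.g. confounder-associated SNPs identified externally.
#' @return an [InstrumentSet-class]
#' @export
selectInstruments <- function(hset, params = clumpParams(), ld = NULL,
                              exclusions = NULL) {
  .assert(is(hset, "HarmonizedSet"), "hset must be a HarmonizedSet")
  p <- hset@pairs
  p <- p[p$pval_exp < params$p_threshold, , drop = FALSE]
  if (!nrow(p))
    stop("no SNP passes the significance threshold", call. = FALSE)
  kept <- ldClump(p[, c("snp", "chr", "pos")] |>
                    cbind(pval = p$pval_exp), ld = ld, params = params)
  p <- p[match(kept, p$snp), , drop = FALSE]
  rownames(p) <- NULL
  iset <- new("InstrumentSet",
              exposureId = hset@exposureId, outcomeId = hset@outcomeId,
              exposureType = hset@exposureType,
              outcomeType = hset@outcomeType,
              pairs = p, dropped = hset@dropped, params = hset@params,
              fstat = fStatistic(p$beta_exp, p$se_exp),
              clumpParams = unclass(params),
              exclusions = data.frame(snp = character(),
                                      reason = character()))
  if (!is.null(exclusions) && nrow(exclusions))
    iset <- applyExclusions(iset, exclusions)
  iset
}

#' Read a confounder-exclusion list
#'
#' Two-column TSV (`snp`, `reason`) naming SNPs to exclude from instrument
#' sets, typically because they associate with confounders of the
#' exposure-outcome relation.
#'
#' @param path TSV file path
#' @return data.frame with columns `snp`, `reason`
#' @export
readExclusions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  .assert(all(c("snp", "reason") %in% names(df)),
          "exclusion list needs columns snp, reason")
  df[, c("snp", "reason")]
}

#' Remove listed SNPs from an instrument set
#'
#' Listed SNPs not present in the set are ignored with a warning. Removing
#' every instrument is an error.
#'
#' @param iset an [InstrumentSet-class]
#' @param exclusions data.frame (`snp`, `reason`)
#' @return the reduced [InstrumentSet-class]; removals are appended to the
#'   set's exclusion provenance.
#' @export
applyExclusions <- function(iset, exclusions) {
  .assert(is(iset, "InstrumentSet"), "iset must be an InstrumentSet")
  if (is.null(exclusions) || !nrow(exclusions)) return(iset)
  .assert(all(c("snp", "reason") %in% names(exclusions)),
          "exclusions needs columns snp, reason")
  hit <- exclusions$snp %in% iset@pairs$snp
  if (any(!hit))
    warning("exclusion list names SNP(s) not in the set: ",
            paste(exclusions$snp[!hit], collapse = ", "), call. = FALSE)
  if (!any(hit)) return(iset)
  if (all(iset@pairs$snp %in% exclusions$snp))
    stop("empty instrument set after exclusions", call. = FALSE)
  keep <- !iset@pairs$snp %in% exclusions$snp
  iset@exclusions <- rbind(iset@exclusions,
                           exclusions[hit, c("snp", "reason")])
  rownames(iset@exclusions) <- NULL
  iset@pairs <- iset@pairs[keep, , drop = FALSE]
  rownames(iset@pairs) <- NULL
  iset@fstat <- iset@fstat[keep]
  validObject(iset)
  iset
}

## Internal: build an InstrumentSet directly from aligned vectors (used by
## tests and simulations where clumping/thresholding is not under study).
.instrument_set <- function(beta_exp, se_exp, beta_out, se_out,
                            snp = NULL, chr = NULL, pos = NULL,
                            pval_exp = NULL, pval_out = NULL,
                            exposure_id = "exposure",
                            outcome_id = "outcome",
                            outcome_type = "binary",
                            exposure_type = "continuous") {
  n <- length(beta_exp)
  snp <- snp %||% sprintf("rs%04d", seq_len(n))
  pairs <- data.frame(
    snp = snp,
    chr = chr %||% rep("1", n),
    pos = pos %||% seq_len(n) * 2.1e7,
    ea = rep("A", n), oa = rep("G", n),
    beta_exp = beta_exp, se_exp = se_exp,
    pval_exp = pval_exp %||% .pval_z(beta_exp / se_exp),
    eaf_exp = rep(0.3, n),
    beta_out = beta_out, se_out = se_out,
    pval_out = pval_out %||% .pval_z(beta_out / se_out),
    eaf_out = rep(0.3, n),
    status = rep("kept", n), stringsAsFactors = FALSE)
  new("InstrumentSet", exposureId = exposure_id, outcomeId = outcome_id,
      exposureType = exposure_type, outcomeType = outcome_type,
      pairs = pairs, dropped = data.frame(), params = list(),
      fstat = fStatistic(beta_exp, se_exp),
      clumpParams = unclass(clumpParams()),
      exclusions = data.frame(snp = character(), reason = character()))
}

#' Build an instrument set from aligned effect vectors
#'
#' Convenience constructor for already-harmonized, already-selected
#' instruments (e.g. published instrument tables): supplies the aligned
#' exposure/outcome betas and SEs directly.
#'
#' @param beta_exp,se_exp,beta_out,se_out aligned per-SNP associations.
#' @param snp optional SNP ids.
#' @param exposure_id,outcome_id trait labels.
#' @param outcome_type `"binary"` or `"continuous"` (controls OR display).
#' @return an [InstrumentSet-class]
#' @export
instrumentSet <- function(beta_exp, se_exp, beta_out, se_out, snp = NULL,
                          exposure_id = "exposure", outcome_id = "outcome",
                          outcome_type = "binary") {
  .assert(length(unique(c(length(beta_exp), length(se_exp),
                          length(beta_out), length(se_out)))) == 1L,
          "effect vectors must have equal length")
  .instrument_set(beta_exp, se_exp, beta_out, se_out, snp = snp,
                  exposure_id = exposure_id, outcome_id = outcome_id,
                  outcome_type = outcome_type)
}
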