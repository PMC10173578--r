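## Reading, validating and harmonizing GWAS summary statistics.

.CANONICAL_MAP <- c(snp = "snp", chr = "chr", pos = "pos", ea = "ea",
                    oa = "oa", eaf = "eaf", beta = "beta", se = "se",
                    pval = "pval", n = "n", ncase = "ncase",
                    ncontrol = "ncontrol")

#' Construct a SummaryStats object from a data.frame
#'
#' Validates each row against the record invariants (positive SE, alleles
#' differ and are A/C/G/T, frequency in \[0,1\] when present, p in (0,1\]).
#' Rows that violate an invariant are moved to the `rejected` slot with a
#' reason rather than aborting the whole table; alleles are upper-cased
#' before validation. Positions are 1-based throughout the package.
#'
#' @param df data.frame with the canonical columns (`snp`, `chr`, `pos`,
#'   `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`, optionally `ncase`,
#'   `ncontrol`); missing optional columns are added as `NA`.
#' @param trait_id single character identifier.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n,ncase,ncontrol trait-level defaults used to fill missing
#'   per-row sample sizes.
#' @return a [SummaryStats-class] object
#' @export
summaryStats <- function(df, trait_id, trait_type = c("continuous", "binary"),
                         n = NULL, ncase = NULL, ncontrol = NULL) {
  trait_type <- match.arg(trait_type)
  .assert(is.data.frame(df), "df must be a data.frame")
  for (col in c("eaf", "ncase", "ncontrol"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_real_
  missing_req <- setdiff(setdiff(.SUMSTAT_COLS, c("eaf", "n", "ncase",
                                                  "ncontrol")), names(df))
  if (length(missing_req))
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  df <- df[, .SUMSTAT_COLS]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "ncase", "ncontrol"))
    df[[col]] <- as.numeric(df[[col]])
  if (!is.null(n)) df$n[is.na(df$n)] <- n
  if (!is.null(ncase)) df$ncase[is.na(df$ncase)] <- ncase
  if (!is.null(ncontrol)) df$ncontrol[is.na(df$ncontrol)] <- ncontrol

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(df$snp) | !nzchar(df$snp), "missing snp id")
  flag(is.na(df$beta), "missing beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive SE")
  flag(!df$ea %in% c("A", "C", "G", "T") |
         !df$oa %in% c("A", "C", "G", "T"), "invalid allele")
  flag(df$ea == df$oa, "identical alleles")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0,1]")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  flag(duplicated(df$snp), "duplicate snp id")
  if (trait_type == "binary")
    flag(!is.na(df$ncase) & !is.na(df$ncontrol) & !is.na(df$n) &
           abs(df$ncase + df$ncontrol - df$n) > 0.5,
         "ncase + ncontrol != n")

  rejected <- df[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  kept <- df[is.na(reason), , drop = FALSE]
  rownames(kept) <- rownames(rejected) <- NULL
  if (nrow(kept) == 0L)
    stop("zero valid rows for trait '", trait_id, "'", call. = FALSE)
  new("SummaryStats", traitId = trait_id, traitType = trait_type,
      stats = kept, rejected = rejected,
      meta = list(n = n, ncase = ncase, ncontrol = ncontrol))
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited table with a header (the delimiter is
#' sniffed from the header line), renames columns to the canonical schema
#' through `column_map`, and validates rows via [summaryStats()].
#'
#' @param path path to the TSV/CSV file.
#' @param column_map named character vector mapping canonical names
#'   (`snp`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `ncase`, `ncontrol`) to the file's column names. Canonical names
#'   already present in the file need not be mapped.
#' @param trait_id,trait_type,n,ncase,ncontrol trait metadata, as in
#'   [summaryStats()].
#' @return a [SummaryStats-class] object
#' @export
readSumstats <- function(path, column_map = NULL, trait_id,
                         trait_type = c("continuous", "binary"),
                         n = NULL, ncase = NULL, ncontrol = NULL) {
  .assert(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = .sniff_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src))
      stop("mapped column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    for (canon in names(column_map))
      names(df)[names(df) == column_map[[canon]]] <- canon
  }
  summaryStats(df, trait_id = trait_id, trait_type = trait_type,
               n = n, ncase = ncase, ncontrol = ncontrol)
}

#' Write a SummaryStats table to a TSV file
#'
#' @param x a [SummaryStats-class] object
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeSumstats <- function(x, path) {
  .assert(is(x, "SummaryStats"), "x must be a SummaryStats object")
  utils::write.table(x@stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns, for every SNP shared between the two tables, the outcome
#' association to the exposure's effect allele:
#' \itemize{
#'   \item identical allele pairs are kept as-is;
#'   \item swapped alleles flip the outcome beta's sign and replace its
#'     frequency by `1 - eaf` (status `flipped`);
#'   \item complementary-strand encodings are translated to the exposure
#'     strand first (status `strand_flipped`, with the sign flip folded in
#'     when the translated alleles are also swapped);
#'   \item palindromic SNPs (A/T or C/G) are dropped under
#'     `palindrome_policy = "drop"`; under `"infer_by_eaf"` they are aligned
#'     by frequency agreement and dropped when either frequency is missing
#'     or within `eaf_window` of 0.5;
#'   \item allele sets compatible under neither reading are dropped as
#'     incompatible.
#' }
#' Harmonization is idempotent: re-harmonizing an already-aligned set
#' changes nothing.
#'
#' @param exposure,outcome [SummaryStats-class] objects for different traits.
#' @param palindrome_policy `"drop"` (default) or `"infer_by_eaf"`.
#' @param eaf_window palindromic SNPs with both frequencies further than
#'   this from 0.5 may be strand-inferred (default 0.08).
#' @return a [HarmonizedSet-class]
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer_by_eaf"),
                      eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  .assert(is(exposure, "SummaryStats") && is(outcome, "SummaryStats"),
          "exposure and outcome must be SummaryStats objects")
  if (identical(traitId(exposure), traitId(outcome)))
    stop("exposure and outcome are the same trait", call. = FALSE)
  ex <- exposure@stats
  ou <- outcome@stats
  shared <- intersect(ex$snp, ou$snp)
  if (!length(shared)) stop("no shared SNPs to harmonize", call. = FALSE)
  ex <- ex[match(shared, ex$snp), ]
  ou <- ou[match(shared, ou$snp), ]

  status <- character(length(shared))
  reason <- rep(NA_character_, length(shared))
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  pal <- .is_palindromic(ex$ea, ex$oa)
  same <- ou$ea == ex$ea & ou$oa == ex$oa
  swap <- ou$ea == ex$oa & ou$oa == ex$ea
  comp_same <- .complement(ou$ea) == ex$ea & .complement(ou$oa) == ex$oa
  comp_swap <- .complement(ou$ea) == ex$oa & .complement(ou$oa) == ex$ea

  for (i in seq_along(shared)) {
    if (pal[i]) {
      ## For palindromic SNPs same/swap and strand readings are confounded;
      ## only frequency can orient them.
      if (palindrome_policy == "drop") {
        status[i] <- "dropped_palindromic"
        reason[i] <- "palindromic SNP under drop policy"
      } else if (is.na(ex$eaf[i]) || is.na(ou$eaf[i]) ||
                 abs(ex$eaf[i] - 0.5) < eaf_window ||
                 abs(ou$eaf[i] - 0.5) < eaf_window) {
        status[i] <- "dropped_palindromic"
        reason[i] <- "palindromic SNP with uninformative frequency"
      } else if (!(same[i] || swap[i] || comp_same[i] || comp_swap[i])) {
        status[i] <- "dropped_incompatible"
        reason[i] <- "allele sets incompatible"
      } else if ((ex$eaf[i] < 0.5) == (ou$eaf[i] < 0.5)) {
        status[i] <- "kept"
      } else {
        status[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else if (same[i]) {
      status[i] <- "kept"
    } else if (swap[i]) {
      status[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else if (comp_same[i]) {
      status[i] <- "strand_flipped"
    } else if (comp_swap[i]) {
      status[i] <- "strand_flipped"
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else {
      status[i] <- "dropped_incompatible"
      reason[i] <- "allele sets incompatible"
    }
  }

  keep <- status %in% c("kept", "flipped", "strand_flipped")
  pairs <- data.frame(
    snp = shared, chr = ex$chr, pos = ex$pos, ea = ex$ea, oa = ex$oa,
    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval, eaf_exp = ex$eaf,
    beta_out = beta_out, se_out = ou$se, pval_out = ou$pval,
    eaf_out = eaf_out, status = status, stringsAsFactors = FALSE)[keep, ]
  dropped <- data.frame(snp = shared, status = status, reason = reason,
                        stringsAsFactors = FALSE)[!keep, ]
  rownames(pairs) <- rownames(dropped) <- NULL
  new("HarmonizedSet",
      exposureId = traitId(exposure), outcomeId = traitId(outcome),
      exposureType = traitType(exposure), outcomeType = traitType(outcome),
      pairs = pairs, dropped = dropped,
      params = list(palindrome_policy = palindrome_policy,
                    eaf_window = eaf_window,
                    n_shared = length(shared),
                    n_dropped = sum(!keep)))
}

#' Write a harmonized set to a TSV audit file
#'
#' Writes the retained pairs followed by a `#`-commented accounting of the
#' dropped SNPs so the harmonization decisions are auditable.
#'
#' @param x a [HarmonizedSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeHarmonized <- function(x, path) {
  .assert(is(x, "HarmonizedSet"), "x must be a HarmonizedSet")
  utils::write.table(x@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(x@dropped)) {
    con <- file(path, open = "a")
    on.exit(close(con))
    writeLines(sprintf("# dropped\t%s\t%s\t%s", x@dropped$snp,
                       x@dropped$status, x@dropped$reason), con)
  }
  invisible(path)
}
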