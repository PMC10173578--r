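test_that("reading a well-formed delimited table round-trips", {
  df <- data.frame(snp = c("rs1", "rs2", "rs3"), chr = "1",
                   pos = c(1e6, 2e6, 3e6), ea = c("A", "C", "T"),
                   oa = c("G", "T", "C"), eaf = c(0.2, 0.4, NA),
                   beta = c(0.1, -0.05, 0.02), se = c(0.01, 0.02, 0.01),
                   pval = c(1e-20, 1e-3, 0.5), n = 1e4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- readSumstats(path, trait_id = "t1", trait_type = "continuous")
  expect_s4_class(ss, "SummaryStats")
  expect_equal(nSnps(ss), 3L)
  expect_equal(statsTable(ss)$beta, df$beta)
  expect_true(is.na(statsTable(ss)$eaf[3]))

  out <- withr::local_tempfile(fileext = ".tsv")
  writeSumstats(ss, out)
  back <- readSumstats(out, trait_id = "t1", trait_type = "continuous")
  expect_equal(statsTable(back)$beta, statsTable(ss)$beta)
  expect_equal(statsTable(back)$snp, statsTable(ss)$snp)
})

test_that("column_map renames arbitrary headers and CSV is sniffed", {
  df <- data.frame(RSID = c("rs1", "rs2"), CHR = "2", BP = c(1, 2) * 1e6,
                   A1 = c("a", "c"), A2 = c("g", "t"), FREQ = 0.3,
                   EFFECT = c(0.1, 0.2), STDERR = 0.01, P = 1e-10,
                   N = 5e4)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  ss <- readSumstats(path,
                     column_map = c(snp = "RSID", chr = "CHR", pos = "BP",
                                    ea = "A1", oa = "A2", eaf = "FREQ",
                                    beta = "EFFECT", se = "STDERR",
                                    pval = "P", n = "N"),
                     trait_id = "t2", trait_type = "continuous")
  expect_equal(nSnps(ss), 2L)
  # lowercase alleles are normalized to uppercase
  expect_equal(statsTable(ss)$ea, c("A", "C"))
  expect_equal(statsTable(ss)$oa, c("G", "T"))
  expect_error(readSumstats(path, column_map = c(beta = "NOPE"),
                            trait_id = "x", trait_type = "continuous"),
               "absent")
})

test_that("invariant-violating rows are rejected with reasons", {
  df <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4", "rs1"),
                   chr = "1", pos = 1:5 * 1e6,
                   ea = c("A", "A", "A", "A", "A"),
                   oa = c("G", "G", "A", "G", "G"),
                   eaf = c(0.2, 0.2, 0.2, 1.4, 0.2),
                   beta = 0.1, se = c(0.01, 0, 0.01, 0.01, 0.01),
                   pval = 1e-9, n = 1e4)
  ss <- summaryStats(df, "t3", "continuous")
  expect_equal(nSnps(ss), 1L)
  rej <- rejectedRows(ss)
  expect_setequal(rej$reason, c("nonpositive SE", "identical alleles",
                                "eaf outside [0,1]", "duplicate snp id"))
  expect_error(summaryStats(df[2, ], "t4", "continuous"), "zero valid rows")
})

test_that("harmonization aligns swapped, strand-flipped and palindromic SNPs", {
  expo <- toy_table(data.frame(
    snp = c("same", "swap", "strand", "strand_swap", "palin", "bad"),
    ea = c("A", "A", "C", "C", "A", "A"),
    oa = c("G", "G", "T", "T", "T", "G"),
    eaf = 0.3, beta = 0.10, se = 0.01, pval = 1e-10), "expo")
  outc <- toy_table(data.frame(
    snp = c("same", "swap", "strand", "strand_swap", "palin", "bad"),
    ea = c("A", "G", "G", "A", "A", "A"),
    oa = c("G", "A", "A", "G", "T", "C"),
    eaf = c(0.3, 0.7, 0.3, 0.7, 0.3, 0.3),
    beta = c(0.05, -0.05, 0.02, -0.02, 0.04, 0.04),
    se = 0.01, pval = 1e-4), "outc")
  h <- harmonize(expo, outc)
  p <- harmonizedPairs(h)
  expect_equal(p$status[match(c("same", "swap", "strand", "strand_swap"),
                              p$snp)],
               c("kept", "flipped", "strand_flipped", "strand_flipped"))
  # swapped alleles negate beta and complement-swap folds the sign flip in
  expect_equal(p$beta_out[match(c("same", "swap", "strand", "strand_swap"),
                                p$snp)],
               c(0.05, 0.05, 0.02, 0.02))
  expect_equal(p$eaf_out[p$snp == "swap"], 0.3)
  d <- droppedSnps(h)
  expect_equal(d$status[d$snp == "palin"], "dropped_palindromic")
  expect_equal(d$status[d$snp == "bad"], "dropped_incompatible")
  # count identity: retained + dropped = shared
  expect_equal(nrow(p) + nrow(d), 6L)
})

test_that("palindromic SNPs are inferable by eaf only away from 0.5", {
  expo <- toy_table(data.frame(
    snp = c("p1", "p2", "p3"), ea = "A", oa = "T",
    eaf = c(0.10, 0.10, 0.48), beta = 0.1, se = 0.01, pval = 1e-10),
    "expo")
  outc <- toy_table(data.frame(
    snp = c("p1", "p2", "p3"), ea = "A", oa = "T",
    eaf = c(0.12, 0.88, 0.47), beta = c(0.03, 0.03, 0.03), se = 0.01,
    pval = 1e-3), "outc")
  h <- harmonize(expo, outc, palindrome_policy = "infer_by_eaf")
  p <- harmonizedPairs(h)
  expect_equal(p$status[p$snp == "p1"], "kept")       # frequencies agree
  expect_equal(p$status[p$snp == "p2"], "flipped")    # frequencies oppose
  expect_equal(p$beta_out[p$snp == "p2"], -0.03)
  expect_equal(droppedSnps(h)$snp, "p3")              # too close to 0.5
  # missing eaf always drops a palindromic SNP
  outc2 <- toy_table(data.frame(snp = "p1", ea = "A", oa = "T",
                                eaf = NA, beta = 0.03, se = 0.01,
                                pval = 1e-3), "outc")
  h2 <- harmonize(expo, outc2, palindrome_policy = "infer_by_eaf")
  expect_equal(nrow(harmonizedPairs(h2)), 0L)
})

test_that("harmonization is idempotent and double swap restores beta", {
  set.seed(42)
  n <- 20
  expo <- toy_exposure(runif(n, 0.05, 0.2))
  outc <- toy_table(data.frame(snp = statsTable(expo)$snp,
                               ea = "G", oa = "A", eaf = 0.7,
                               beta = rnorm(n, 0, 0.05), se = 0.01,
                               pval = 0.5), "outc")
  h1 <- harmonize(expo, outc)
  expect_true(all(harmonizedPairs(h1)$status == "flipped"))
  expect_equal(harmonizedPairs(h1)$beta_out, -statsTable(outc)$beta)
  # feed the aligned outcome back in: nothing changes (idempotence)
  aligned <- statsTable(outc)
  aligned$ea <- "A"; aligned$oa <- "G"
  aligned$beta <- harmonizedPairs(h1)$beta_out
  aligned$eaf <- harmonizedPairs(h1)$eaf_out
  outc2 <- toy_table(aligned, "outc")
  h2 <- harmonize(expo, outc2)
  expect_true(all(harmonizedPairs(h2)$status == "kept"))
  expect_equal(harmonizedPairs(h2)$beta_out, harmonizedPairs(h1)$beta_out)
  # double swap: swapping the already-swapped table restores the original
  back <- aligned
  back$ea <- "G"; back$oa <- "A"
  back$beta <- -aligned$beta
  back$eaf <- 1 - aligned$eaf
  h3 <- harmonize(expo, toy_table(back, "outc"))
  expect_equal(harmonizedPairs(h3)$beta_out, statsTable(outc2)$beta)
})

test_that("harmonize rejects degenerate inputs", {
  expo <- toy_exposure(c(0.1, 0.2))
  other <- toy_table(data.frame(snp = c("zz1", "zz2"), ea = "A", oa = "G",
                                eaf = 0.3, beta = 0.1, se = 0.01,
                                pval = 0.1), "outc")
  expect_error(harmonize(expo, other), "no shared SNPs")
  expect_error(harmonize(expo, expo), "same trait")
})
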