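mk_mv <- function(X, y, sy, se_x = NULL, outcome_type = "binary") {
  n <- nrow(X)
  mvInstrumentSet(sprintf("rs%03d", seq_len(n)), X,
                  se_x %||% matrix(0.01, n, ncol(X)), y, sy,
                  exposure_ids = colnames(X) %||%
                    paste0("E", seq_len(ncol(X))),
                  outcome_type = outcome_type)
}

test_that("MVMR with a zeroed second column reduces to univariable IVW", {
  set.seed(31)
  n <- 8
  x <- runif(n, 0.05, 0.3); sy <- runif(n, 0.01, 0.03)
  y <- 0.3 * x + rnorm(n, 0, sy)
  X <- cbind(E1 = x, E2 = 0)
  # a zero column is rank-deficient; drop it and compare to univariable
  expect_error(mvmrIVW(mk_mv(X, y, sy)), "rank deficient")
  uni_mv <- mvmrIVW(mk_mv(cbind(E1 = x), y, sy))
  uni <- mrIVW(instrumentSet(x, rep(0.01, n), y, sy))
  expect_equal(unname(estimate(uni_mv)["E1"]), estimate(uni),
               tolerance = 1e-12)
  expect_equal(unname(stdError(uni_mv)["E1"]), stdError(uni),
               tolerance = 1e-12)
})

test_that("MVMR recovers an exact linear system and matches the normal-equations oracle", {
  X <- cbind(E1 = c(0.1, 0.2, 0.05, 0.15), E2 = c(0.05, 0.01, 0.2, 0.1))
  y <- drop(X %*% c(0.3, -0.1))
  r <- mvmrIVW(mk_mv(X, y, rep(0.01, 4)))
  expect_equal(unname(estimate(r)), c(0.3, -0.1), tolerance = 1e-10)

  set.seed(32)
  n <- 6
  X2 <- cbind(E1 = runif(n, 0.05, 0.3), E2 = runif(n, 0.05, 0.3))
  sy <- runif(n, 0.01, 0.03)
  y2 <- drop(X2 %*% c(0.25, -0.15)) + rnorm(n, 0, sy)
  r2 <- mvmrIVW(mk_mv(X2, y2, sy))
  o <- wls_oracle_mv(X2, y2, 1 / sy^2)
  expect_equal(unname(estimate(r2)), unname(o$coef), tolerance = 1e-10)
  sc <- max(1, sqrt(o$rss / (n - 2)))
  expect_equal(unname(stdError(r2)), unname(o$se) * sc, tolerance = 1e-10)
  expect_error(mvmrIVW(mk_mv(X2[1:2, ], y2[1:2], sy[1:2])), "more SNPs")
})

test_that("difference-method mediation preserves the exact decomposition identity", {
  total <- orToResult(0.711, 0.624, 0.810)
  direct <- orToResult(0.836, 0.707, 0.988)
  m <- mediationDifference(total, direct, "hypertension")
  expect_equal(m@indirect, m@total - m@direct)
  expect_equal(m@pm, 100 * m@indirect / m@total)
  expect_equal(m@pm, 47.48, tolerance = 1e-2)

  # degenerate decompositions
  same <- mediationDifference(total, total, "self")
  expect_equal(same@pm, 0)
  expect_equal(same@indirect, 0)
  null_dir <- orToResult(1, 0.9, 1.1)
  full <- mediationDifference(total, null_dir, "all")
  expect_equal(full@pm, 100)
  zero_tot <- orToResult(1, 0.9, 1.1)
  expect_error(mediationDifference(zero_tot, direct), "total effect is zero")
  # unbounded PM is flagged, not clipped
  over <- mediationDifference(total, orToResult(1.2, 1.0, 1.4), "over")
  expect_gt(over@pm, 100)
  expect_match(over@note, "outside")
})

test_that("product-method mediation applies the product delta method", {
  zc <- qnorm(0.975)
  a <- orToResult(exp(-0.46), exp(-0.46 - zc * 0.1),
                  exp(-0.46 + zc * 0.1))
  b <- orToResult(exp(0.2), exp(0.2 - zc * 0.05),
                  exp(0.2 + zc * 0.05))
  total <- orToResult(0.711, 0.624, 0.810)
  m <- mediationProduct(a, b, total, "m1")
  expect_equal(m@indirect, -0.46 * 0.2, tolerance = 1e-10)
  expect_equal(m@indirectSE,
               sqrt(0.46^2 * 0.05^2 + 0.2^2 * 0.1^2), tolerance = 1e-6)
  # broken path: a = 0 gives zero indirect effect
  a0 <- orToResult(1, exp(-1.96 * 0.1), exp(1.96 * 0.1))
  expect_equal(mediationProduct(a0, b, total, "m0")@indirect, 0)
  expect_error(mediationProduct(a, b), "total")
})

test_that("network decomposition returns per-mediator plus combined results", {
  total <- orToResult(0.711, 0.624, 0.810)
  singles <- list(hyp = orToResult(0.836, 0.707, 0.988),
                  bmi = orToResult(0.774, 0.650, 0.920))
  all_m <- orToResult(0.901, 0.733, 1.107)
  dec <- networkDecomposition(total, singles, all_m)
  expect_named(dec, c("hyp", "bmi", "combined"))
  expect_equal(dec$combined@pm, 69.44, tolerance = 1e-2)
  tab <- mediationTable(dec)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$or_total, rep(0.711, 3), tolerance = 1e-12)

  # null network: every single direct equals the total
  dec0 <- networkDecomposition(total, list(a = total, b = total), total)
  expect_true(all(vapply(dec0, proportionMediated, numeric(1)) == 0))
})

test_that("combined indirect effect adds over independent mediators in simulation", {
  # DAG with two independent mediators: combined indirect = sum of singles
  spec <- dagSpec(n_mediators = 2L, a = c(-0.5, -0.4), b = c(0.2, 0.15),
                  c_direct = -0.12, seed = 33)
  te <- trueEffects(spec)
  expect_equal(sum(te$indirect), te$total - te$direct)
  set.seed(33)
  reps <- 40
  diff <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- simulateStudy(dagSpec(n_mediators = 2L, a = c(-0.5, -0.4),
                                b = c(0.2, 0.15), c_direct = -0.12,
                                n_snps = 40L, seed = 1000 + r))
    tabs <- st@tables
    tot <- mrIVW(selectInstruments(harmonize(tabs$exposure, tabs$outcome)))
    d_all <- mvmrIVW(mvInstruments(list(exposure = tabs$exposure,
                                        M1 = tabs$M1, M2 = tabs$M2),
                                   tabs$outcome))
    d1 <- mvmrIVW(mvInstruments(list(exposure = tabs$exposure,
                                     M1 = tabs$M1), tabs$outcome))
    d2 <- mvmrIVW(mvInstruments(list(exposure = tabs$exposure,
                                     M2 = tabs$M2), tabs$outcome))
    ind_comb <- estimate(tot) - unname(estimate(d_all)["exposure"])
    ind_sum <- (estimate(tot) - unname(estimate(d1)["exposure"])) +
      (estimate(tot) - unname(estimate(d2)["exposure"]))
    diff[r] <- ind_comb - ind_sum
  }
  mc_se <- sd(diff) / sqrt(reps)
  expect_lt(abs(mean(diff)), 3 * mc_se + 0.005)
})

test_that("bootstrap PM uncertainty is reproducible and in a sane range", {
  spec <- dagSpec(seed = 34)
  st <- simulateStudy(spec)
  tabs <- st@tables
  uv <- selectInstruments(harmonize(tabs$exposure, tabs$outcome))
  mv <- mvInstruments(c(list(exposure = tabs$exposure),
                        tabs[paste0("M", 1:4)]), tabs$outcome)
  b1 <- pmBootstrap(uv, mv, exposure = "exposure", reps = 100, seed = 5)
  b2 <- pmBootstrap(uv, mv, exposure = "exposure", reps = 100, seed = 5)
  expect_identical(b1$pm_boot, b2$pm_boot)
  expect_true(b1$pm_ci[1] < b1$pm_ci[2])
  expect_gt(b1$pm_se, 0)
})
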