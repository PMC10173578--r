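test_that("Cochran's Q matches by-hand arithmetic and perfect fits give Q = 0", {
  s0 <- instrumentSet(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      0.2 * c(0.1, 0.2, 0.3), c(0.01, 0.02, 0.03))
  q0 <- cochranQ(s0)
  expect_equal(q0@Q, 0, tolerance = 1e-20)
  expect_equal(pValue(q0), 1)

  x <- c(0.1, 0.15, 0.25); y <- c(0.03, 0.02, 0.06)
  sy <- c(0.01, 0.012, 0.02)
  s <- instrumentSet(x, rep(0.01, 3), y, sy)
  w <- 1 / sy^2
  beta <- sum(w * x * y) / sum(w * x^2)
  q_hand <- sum(w * (y - beta * x)^2)
  q <- cochranQ(s)
  expect_equal(q@Q, q_hand, tolerance = 1e-10)
  expect_equal(q@df, 2)
  expect_equal(pValue(q), pchisq(q_hand, 2, lower.tail = FALSE))
  # Egger framework: df = n - 2, residuals from the free-intercept fit
  qe <- cochranQ(s, "Egger")
  o <- wls_oracle(x, y, w, icpt = TRUE)
  expect_equal(qe@Q, o$rss, tolerance = 1e-10)
  expect_equal(qe@df, 1)
  # shared code path: Q(IVW) equals the residual sum behind the
  # multiplicative-random scaling
  expect_identical(q@Q, mrExtras(mrIVW(s))$Q)
})

test_that("leave-one-out counts refits and pinpoints a planted outlier", {
  # identical ratios: every refit equals the full estimate
  x <- seq(0.1, 0.28, by = 0.02)
  s <- instrumentSet(x, rep(0.01, 10), 0.2 * x, rep(0.01, 10))
  loo <- leaveOneOut(s)
  expect_equal(nrow(loo), 10L)
  expect_true(all(abs(loo$beta - 0.2) < 1e-12))
  expect_false(any(loo$influential))

  # n = 3: exactly 3 refits, each on 2 SNPs
  s3 <- instrumentSet(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      c(0.02, 0.04, 0.06), rep(0.01, 3))
  expect_equal(nrow(leaveOneOut(s3)), 3L)

  # planted outlier: its omission is the (only) flagged one
  set.seed(21)
  n <- 15
  xr <- runif(n, 0.05, 0.2); sy <- rep(0.01, n)
  yr <- 0.2 * xr + rnorm(n, 0, sy)
  yr[7] <- yr[7] + 0.4  # large enough to move the pooled estimate
                        # outside the omitted-SNP refit interval
  sout <- instrumentSet(xr, rep(0.002, n), yr, sy)
  loo2 <- leaveOneOut(sout)
  expect_true(loo2$influential[7])
  expect_equal(which(loo2$influential), 7L)
})

test_that("PRESSO is deterministic, calibrated under the null, and finds planted outliers", {
  set.seed(22)
  n <- 15
  x <- runif(n, 0.05, 0.2); sy <- rep(0.01, n)
  y <- 0.2 * x + rnorm(n, 0, sy)
  s <- instrumentSet(x, rep(0.002, n), y, sy)
  r1 <- mrPresso(s, n_sim = 300, seed = 99)
  r2 <- mrPresso(s, n_sim = 300, seed = 99)
  expect_identical(r1@globalRSS, r2@globalRSS)
  expect_identical(r1@globalPval, r2@globalPval)
  expect_identical(r1@outlierIndices, r2@outlierIndices)
  expect_identical(estimate(r1@betaCorrected), estimate(r2@betaCorrected))
  # no outliers and non-significant global test: corrected == raw
  if (r1@globalPval > 0.05)
    expect_identical(estimate(r1@betaRaw), estimate(r1@betaCorrected))

  # planted 10-SE pleiotropic offset is flagged and corrected away
  y2 <- y; y2[3] <- y2[3] + 10 * sy[3]
  s2 <- instrumentSet(x, rep(0.002, n), y2, sy)
  r3 <- mrPresso(s2, n_sim = 500, seed = 7)
  expect_lt(r3@globalPval, 0.05)
  expect_true(3L %in% r3@outlierIndices)
  expect_lt(abs(estimate(r3@betaCorrected) - 0.2),
            abs(estimate(r3@betaRaw) - 0.2))
  expect_false(is.na(r3@distortionPval))
  expect_error(mrPresso(s, n_sim = 50, seed = 1), "at least 100")
  expect_error(mrPresso(instrumentSet(c(0.1, 0.2, 0.3), rep(0.01, 3),
                                      c(0.02, 0.04, 0.06), rep(0.01, 3)),
                        seed = 1), "at least 4")
})

test_that("Steiger compares instrument variance explained across samples", {
  # one SNP, overwhelming exposure signal: direction confirmed
  s <- instrumentSet(10 / sqrt(1000), 1 / sqrt(1000), 1 / sqrt(1000),
                     1 / sqrt(1000), outcome_type = "continuous")
  st <- mrSteiger(s, 1000, 1000, exposure_type = "continuous",
                  outcome_type = "continuous")
  expect_equal(st@r2Exposure, 100 / 1100, tolerance = 1e-10)  # z²/(z²+n)
  expect_equal(st@r2Outcome, 1 / 1001, tolerance = 1e-10)
  expect_true(st@directionCorrect)
  expect_lt(pValue(st), 0.05)

  # equal variance explained: direction not confirmed, p = 1
  s_eq <- instrumentSet(0.1, 0.02, 0.1, 0.02, outcome_type = "continuous")
  st_eq <- mrSteiger(s_eq, 5000, 5000, exposure_type = "continuous",
                     outcome_type = "continuous")
  expect_false(st_eq@directionCorrect)
  expect_equal(pValue(st_eq), 1)

  # binary outcome requires case/control counts (effective sample size)
  s_bin <- instrumentSet(0.1, 0.01, 0.02, 0.01)
  expect_error(mrSteiger(s_bin, 1e4, 1e4), "ncase")
  st_bin <- mrSteiger(s_bin, 1e4, 1e4, ncase_out = 2e3, ncontrol_out = 8e3)
  z_out <- 2
  neff <- 4 / (1 / 2e3 + 1 / 8e3)
  expect_equal(st_bin@r2Outcome, z_out^2 / (z_out^2 + neff),
               tolerance = 1e-10)

  # antisymmetry: swapping exposure and outcome flips the direction flag
  s_fwd <- instrumentSet(0.2, 0.01, 0.05, 0.01, outcome_type = "continuous")
  s_rev <- instrumentSet(0.05, 0.01, 0.2, 0.01, outcome_type = "continuous")
  fwd <- mrSteiger(s_fwd, 1e4, 1e4, exposure_type = "continuous",
                   outcome_type = "continuous")
  rev <- mrSteiger(s_rev, 1e4, 1e4, exposure_type = "continuous",
                   outcome_type = "continuous")
  expect_true(fwd@directionCorrect)
  expect_false(rev@directionCorrect)
  expect_equal(pValue(fwd), pValue(rev))
})

test_that("Steiger confirms true causal direction on simulated studies", {
  set.seed(23)
  hits <- 0L
  reps <- 100
  n <- 5e4
  for (r in seq_len(reps)) {
    m <- 20
    xt <- runif(m, 0.05, 0.15)
    sx <- rep(1 / sqrt(0.4 * n), m)
    sy <- sx
    theta <- 0.3
    s <- instrumentSet(xt + rnorm(m, 0, sx), sx,
                       theta * xt + rnorm(m, 0, sy), sy,
                       outcome_type = "continuous")
    st <- mrSteiger(s, n, n, exposure_type = "continuous",
                    outcome_type = "continuous")
    hits <- hits + st@directionCorrect
  }
  expect_gte(hits / reps, 0.95)
})

test_that("analytic binary-outcome power behaves at the null and in the limit", {
  expect_equal(powerBinary(5e4, 0.1, 0.02, 1), 0.05, tolerance = 1e-12)
  expect_gt(powerBinary(5e7, 0.1, 0.02, 1.1), 0.999)
  # monotone nondecreasing in n, r2 and |ln OR|
  ns <- c(1e4, 5e4, 2e5, 1e6)
  expect_true(all(diff(vapply(ns, powerBinary, numeric(1),
                              case_fraction = 0.1,
                              r2_instruments = 0.02,
                              true_or = 1.2)) >= 0))
  r2s <- c(0.005, 0.02, 0.05, 0.2)
  expect_true(all(diff(vapply(r2s, function(r2)
    powerBinary(5e4, 0.1, r2, 1.2), numeric(1))) >= 0))
  ors <- c(1.05, 1.1, 1.3, 1.6)
  expect_true(all(diff(vapply(ors, function(or)
    powerBinary(5e4, 0.1, 0.02, or), numeric(1))) >= 0))
  # protective ORs mirror risk ORs
  expect_equal(powerBinary(5e4, 0.1, 0.02, 1 / 1.3),
               powerBinary(5e4, 0.1, 0.02, 1.3), tolerance = 1e-12)
  expect_error(powerBinary(5e4, 1.2, 0.02, 1.3), "case_fraction")
})

test_that("the diagnostics table carries the forest-plot annotation columns", {
  set.seed(24)
  n <- 10
  x <- runif(n, 0.05, 0.2)
  s <- instrumentSet(x, rep(0.002, n), 0.2 * x + rnorm(n, 0, 0.01),
                     rep(0.01, n))
  tab <- sensitivitySuite(s, n_exp = 1e5, n_out = 5e4, presso_seed = 3,
                          n_sim = 200,
                          ncase_out = 5e3, ncontrol_out = 4.5e4,
                          power_args = list(case_fraction = 0.1,
                                            true_or = 1.3))
  expect_true(all(c("Q_ivw", "P_het_ivw", "egger_intercept", "P_intercept",
                    "P_steiger", "P_presso_global", "power", "mean_F")
                  %in% names(tab)))
  expect_equal(nrow(tab), 1L)
  expect_false(any(is.na(tab$power)))
})
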