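test_that("Wald ratio matches the delta-method arithmetic", {
  r <- waldRatio(beta_exp = 0.1, se_exp = 0.01, beta_out = 0.02,
                 se_out = 0.01)
  expect_equal(estimate(r), 0.2)
  expect_equal(stdError(r), 0.1)
  expect_equal(confInt(r), 0.2 + c(-1, 1) * qnorm(0.975) * 0.1)
  null <- waldRatio(beta_exp = 0.1, se_exp = 0.01, beta_out = 0,
                    se_out = 0.01)
  expect_equal(estimate(null), 0)
  expect_equal(pValue(null), 1)
  expect_error(waldRatio(beta_exp = 0, se_exp = 0.01, beta_out = 0.1,
                         se_out = 0.01), "zero")
})

test_that("IVW matches the closed-form weighted regression oracle", {
  s <- instrumentSet(c(0.1, 0.2), c(0.01, 0.01), c(0.01, 0.08),
                     c(0.01, 0.02))
  r <- mrIVW(s)
  expect_equal(estimate(r), (10 + 40) / (100 + 100))  # = 0.25
  o <- wls_oracle(c(0.1, 0.2), c(0.01, 0.08), c(1e4, 2.5e3))
  expect_equal(estimate(r), unname(o$coef), tolerance = 1e-10)
  # consistent ratios: exact estimate and Q = 0
  s2 <- instrumentSet(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      0.2 * c(0.1, 0.2, 0.3), c(0.01, 0.02, 0.03))
  r2 <- mrIVW(s2)
  expect_equal(estimate(r2), 0.2)
  expect_equal(mrExtras(r2)$Q, 0)
  # all-null outcome
  s3 <- instrumentSet(c(0.1, 0.2), c(0.01, 0.01), c(0, 0), c(0.01, 0.02))
  expect_equal(estimate(mrIVW(s3)), 0)
})

test_that("IVW invariants: single-SNP reduction, sign-flip invariance, SE ordering", {
  s1 <- instrumentSet(0.1, 0.01, 0.02, 0.01)
  expect_equal(estimate(mrIVW(s1)), estimate(waldRatio(s1)))
  expect_equal(stdError(mrIVW(s1)), stdError(waldRatio(s1)))

  set.seed(10)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    x <- runif(n, 0.05, 0.3); y <- 0.2 * x + rnorm(n, 0, 0.02)
    sy <- runif(n, 0.01, 0.03)
    s <- instrumentSet(x, rep(0.01, n), y, sy)
    flip <- sample(c(-1, 1), n, replace = TRUE)
    sflip <- instrumentSet(flip * x, rep(0.01, n), flip * y, sy)
    expect_equal(estimate(mrIVW(s)), estimate(mrIVW(sflip)),
                 tolerance = 1e-12)
    expect_lte(stdError(mrIVW(s, "fixed")), stdError(mrIVW(s)))
  }
})

test_that("Egger recovers exact linear data and matches the WLS oracle", {
  x <- c(0.1, 0.2, 0.3)
  y <- 0.01 + 0.2 * x
  s <- instrumentSet(x, rep(0.01, 3), y, rep(0.01, 3))
  r <- mrEgger(s)
  expect_equal(estimate(r), 0.2, tolerance = 1e-10)
  expect_equal(mrExtras(r)$intercept, 0.01, tolerance = 1e-10)
  expect_equal(mrExtras(r)$Q, 0, tolerance = 1e-12)

  set.seed(11)
  n <- 6
  x <- runif(n, 0.05, 0.3); sy <- runif(n, 0.01, 0.03)
  y <- 0.02 + 0.25 * x + rnorm(n, 0, sy)
  s2 <- instrumentSet(x, rep(0.01, n), y, sy)
  o <- wls_oracle(x, y, 1 / sy^2, icpt = TRUE)
  r2 <- mrEgger(s2)
  expect_equal(estimate(r2), unname(o$coef[2]), tolerance = 1e-10)
  expect_equal(mrExtras(r2)$intercept, unname(o$coef[1]), tolerance = 1e-10)
  # slope SE = unscaled WLS SE times the estimated residual scale
  sc <- sqrt(o$rss / (n - 2))
  expect_equal(stdError(r2), unname(o$se[2]) * sc, tolerance = 1e-10)
  expect_error(mrEgger(instrumentSet(c(0.1, 0.2), c(0.01, 0.01),
                                     c(0.01, 0.02), c(0.01, 0.01))),
               "at least 3")
})

test_that("maximum likelihood matches a dense grid search of the profile likelihood", {
  # exact-ratio data: theta = 0.2 exactly
  s0 <- instrumentSet(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      0.2 * c(0.1, 0.2, 0.3), rep(0.01, 3))
  expect_equal(estimate(mrMaxLik(s0)), 0.2, tolerance = 1e-6)

  x <- c(0.08, 0.15, 0.22); sx <- c(0.01, 0.012, 0.015)
  y <- c(0.020, 0.025, 0.050); sy <- c(0.008, 0.01, 0.012)
  s <- instrumentSet(x, sx, y, sy)
  th_pkg <- estimate(mrMaxLik(s))
  th_grid <- ml_grid_oracle(x, y, sx, sy, th_pkg - 0.01, th_pkg + 0.01)
  expect_equal(th_pkg, th_grid, tolerance = 1e-4)

  # se_exp -> 0: ML converges to the fixed-effect IVW estimate
  s_lim <- instrumentSet(x, rep(1e-8, 3), y, sy)
  ivw <- mrIVW(s_lim, "fixed")
  expect_equal(estimate(mrMaxLik(s_lim)), estimate(ivw), tolerance = 1e-6)
})

test_that("RAPS solves the profile score and resists outliers with the Huber loss", {
  s0 <- instrumentSet(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      0.2 * c(0.1, 0.2, 0.3), rep(0.01, 3))
  expect_equal(estimate(mrRAPS(s0)), 0.2, tolerance = 1e-6)

  set.seed(12)
  n <- 5
  x <- runif(n, 0.05, 0.3); sx <- runif(n, 0.008, 0.015)
  sy <- runif(n, 0.01, 0.03)
  y <- 0.2 * x + rnorm(n, 0, sy)
  s <- instrumentSet(x, sx, y, sy)
  th_pkg <- estimate(mrRAPS(s, loss = "l2"))
  th_grid <- raps_grid_oracle(x, y, sx, sy, th_pkg - 0.01, th_pkg + 0.01)
  expect_equal(th_pkg, th_grid, tolerance = 1e-4)

  # one gross outlier: huber beats l2 in absolute error on a seeded draw
  set.seed(13)
  n <- 30
  x <- runif(n, 0.05, 0.3); sx <- rep(0.005, n); sy <- rep(0.01, n)
  y <- 0.2 * x + rnorm(n, 0, sy)
  y[1] <- y[1] + 0.3  # 30 outcome-SEs of pleiotropy
  s_out <- instrumentSet(x, sx, y, sy)
  err_l2 <- abs(estimate(mrRAPS(s_out, loss = "l2")) - 0.2)
  err_hu <- abs(estimate(mrRAPS(s_out, loss = "huber")) - 0.2)
  expect_lt(err_hu, err_l2)
})

test_that("multi-SNP estimators recover the true effect without pleiotropy", {
  set.seed(14)
  theta <- -0.3
  reps <- 500
  n <- 20
  est <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("ivw", "egger", "ml", "raps")))
  for (r in seq_len(reps)) {
    xt <- runif(n, 0.05, 0.2)
    sx <- rep(0.002, n); sy <- rep(0.01, n)
    s <- instrumentSet(xt + rnorm(n, 0, sx), sx,
                       theta * xt + rnorm(n, 0, sy), sy)
    est[r, ] <- c(estimate(mrIVW(s)), estimate(mrEgger(s)),
                  estimate(mrMaxLik(s)), estimate(mrRAPS(s)))
  }
  for (m in colnames(est)) {
    mc_se <- sd(est[, m]) / sqrt(reps)
    expect_lt(abs(mean(est[, m]) - theta), 3 * mc_se,
              label = paste("bias of", m))
  }
})

test_that("OR scale is the exact exp transform of the log scale", {
  s <- instrumentSet(c(0.1, 0.2), c(0.01, 0.01), c(0.01, 0.08),
                     c(0.01, 0.02), outcome_type = "binary")
  r <- mrIVW(s)
  or <- orScale(r)
  expect_identical(unname(or), unname(exp(c(estimate(r), confInt(r)))))
  expect_equal(log(unname(or[1])), estimate(r), tolerance = 1e-12)
  cont <- instrumentSet(c(0.1, 0.2), c(0.01, 0.01), c(0.01, 0.08),
                        c(0.01, 0.02), outcome_type = "continuous")
  expect_error(orScale(mrIVW(cont)), "binary")
  tab <- mrTable(list(r, mrIVW(cont)))
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$or[2]))
})
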